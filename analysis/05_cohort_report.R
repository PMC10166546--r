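#!/usr/bin/env Rscript

# Stage 5 — cohort-level clinical summaries on the decomposed fields.
#
# Reproduces the analysis battery: severity strata per visit, archetype
# prevalence at presentation, AT1-PW/MD Spearman correlations, the
# mean-split prognosis groups with MD-over-time curves, and residual
# deficits in final-visit fields whose MD is in the normal range.

suppressPackageStartupMessages(library(vfarchetypes))

records <- read_vf_table("results/cohort.csv", dialect = "s1")
model <- read_model_json("results/model_k14.json")
dec <- decompose_table(records, model)
at1 <- paste0("pw_", model$normal_at)

## severity strata (Table-1 style)
sev <- cohort_summary(dec)
readr::write_csv(sev, "results/severity_by_visit.csv")
print(sev)

## archetype prevalence at presentation
prev <- at_prevalence(dec, scope = "presentation")
readr::write_csv(prev$prevalence, "results/at_prevalence_presentation.csv")
cat("\nMost prevalent abnormal archetypes at presentation:\n")
ab <- prev$prevalence[prev$prevalence$at != model$normal_at, ]
print(head(ab[order(-ab$n_meaningful), ], 4))
cat(sprintf("fields with no abnormal meaningful archetype: %.0f%%\n",
            prev$pct_no_abnormal))

## AT1 PW vs MD
pres <- dec[dec$visit_type == "presentation", ]
fin <- dec[dec$visit_type == "final", ]
rp <- pw_md_correlation(pres[[at1]], pres$md)
rf <- pw_md_correlation(fin[[at1]], fin$md)
cat(sprintf("\nSpearman AT1 PW ~ MD: presentation rho = %.2f (p = %.2g); final rho = %.2f (p = %.2g)\n",
            rp$rho, rp$p, rf$rho, rf$p))

## prognosis split on presentation AT1 PW
ps <- prognosis_split(dec)
print(ps)
readr::write_csv(ps$md_curve, "results/md_trajectories.csv")
ggplot2::ggsave("results/md_trajectories.png", plot_md_trajectories(ps),
                width = 6.5, height = 4, dpi = 150)

## residual deficits in MD-normal final fields
fin_norm <- fin[fin$md >= -2, ]
cat(sprintf("\nFinal fields with MD >= -2 dB: %d/%d (%.0f%%)\n",
            nrow(fin_norm), nrow(fin), 100 * nrow(fin_norm) / nrow(fin)))
cat(sprintf("of these, with residual deficit (>= 1 abnormal meaningful AT): %d (%.0f%%)\n",
            sum(fin_norm$n_abnormal_meaningful > 0),
            100 * mean(fin_norm$n_abnormal_meaningful > 0)))
readr::write_csv(fin_norm[, c("patient_id", "eye", "md", "n_abnormal_meaningful",
                              "residual_deficit")],
                 "results/residual_deficits_final_md_normal.csv")

## one case example: the eye with the largest MD swing
eye_id <- paste(dec$patient_id, dec$eye)
swing <- tapply(dec$md, eye_id, function(v) max(v) - min(v))
worst <- names(which.max(swing))
eye <- dec[eye_id == worst, ]
eye <- eye[order(eye$visit_day), ]
ggplot2::ggsave("results/case_example.png",
                plot_trajectory(eye, show_subcutoff = TRUE),
                width = 10, height = 3.2, dpi = 150)
cat("\nwrote results/md_trajectories.png and results/case_example.png\n")
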