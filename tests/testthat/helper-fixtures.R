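# Programmatic fixtures shared across test files.

# a tiny well-formed vf table with nr fields of plain numbers
tiny_vf_table <- function(nr = 3, md = NULL, seed = 42) {
  set.seed(seed)
  td <- matrix(round(stats::runif(nr * 52, -10, 5), 2), nr, 52)
  tb <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(nr)),
    eye = rep(c("OD", "OS"), length.out = nr),
    visit_day = rep(0L, nr),
    visit_type = rep("presentation", nr),
    fixation_loss_pct = NA_real_,
    false_pos_pct = NA_real_,
    false_neg_pct = NA_real_
  )
  td_tbl <- tibble::as_tibble(as.data.frame(td))
  names(td_tbl) <- sprintf("td_%02d", 1:52)
  tb <- dplyr::bind_cols(tb, td_tbl)
  tb$md <- if (is.null(md)) rowMeans(td) else md
  tb
}

# wrap a template matrix as a frozen archetype model (used when the truth
# basis itself, not a fit, should be the decomposition target)
as_frozen_model <- function(Z, normal_at = which.max(rowMeans(Z))) {
  k <- nrow(Z)
  rownames(Z) <- paste0("AT", seq_len(k))
  structure(
    list(k = k, archetypes = Z, A = NULL, B = NULL,
         rw = rep(100 / k, k), avg_td = rowMeans(Z),
         normal_at = as.integer(normal_at), rss = NA_real_, rss_trace = NULL,
         iterations = 0L, restart = 1L, ridge_events = 0L,
         opts = fit_options(k), mirrored = FALSE, d = ncol(Z)),
    class = "archetype_model"
  )
}

# the five well-separated patterns used for recovery benchmarks
recovery_patterns <- function() {
  c("normal", "enlarged_blind_spot", "superior_arcuate",
    "inferior_nasal_wedge", "global_depression_mild")
}

recovery_spec <- function(n_patients, noise_sd = 1, seed = 1,
                          visit_days = c(0, 45, 110, 230)) {
  pats <- recovery_patterns()
  cohort_spec(
    n_patients = n_patients, visit_days = visit_days, patterns = pats,
    mixing = stats::setNames(rep(0.4, length(pats)), pats),
    noise_sd = noise_sd, seed = seed
  )
}
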