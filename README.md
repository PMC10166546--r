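# vfarchetypes

Archetypal analysis of longitudinal 24-2 visual fields, built for cohorts of
papilledema / idiopathic intracranial hypertension (IIH) patients followed in
clinic: eyes present with anything from a normal field or an enlarged blind
spot through arcuate, nasal-wedge and altitudinal defects to severe global
loss, and mostly recover under treatment. Global indices like mean deviation
(MD) compress all of that into one number; archetypal analysis keeps the
*patterns* and makes them quantitative.

## The method

Collect one exam per row into a matrix `X` of total-deviation values (dB) at
the 52 non-blind-spot locations of the 24-2 grid. Archetypal analysis
factorizes

```
X ≈ A Z,   Z = B X,    rows of A and B on the probability simplex
```

so each of the k rows of `Z` — the archetypes (ATs) — is a convex
combination of observed fields sitting on the extremes of the data cloud,
and each field is a convex combination of archetypes. A field's coefficients
×100 are its percent weights (**PW**, summing to 100%); the mean PW of an
archetype across a dataset is its relative weight (**RW**); AT1 is the
normal archetype. The package fits this factorization by alternating
penalty-row constrained least squares (exact NNLS subproblems, condition-
guarded archetype updates, projected-gradient polish), selects the number of
archetypes by patient-grouped ten-fold cross-validated RSS over k = 2..20,
freezes the basis, and then:

* decomposes any field deterministically into PW on the frozen basis,
* applies the clinical rules: PW ≥ 9% is *meaningful*; meaningful non-AT1
  archetypes are *abnormal*; a field with MD ≥ −2.00 dB but at least one
  abnormal meaningful archetype carries a *residual deficit*,
* computes cohort summaries: RW and average TD per archetype, severity
  strata (−15 / −7 / −2 dB cutpoints), archetype prevalence, Spearman
  correlation of AT1 PW with MD, and the prognosis split of eyes at the mean
  presentation AT1 PW with MD-over-time group curves,
* simulates longitudinal cohorts with planted archetypal structure (nine
  canonical defect templates, sparse Dirichlet mixing, recovery drift,
  test–retest noise) so the whole pipeline is validated against known
  ground truth.

## Worked example

```r
library(vfarchetypes)

pats <- c("normal", "enlarged_blind_spot", "superior_arcuate",
          "inferior_nasal_wedge", "global_depression_mild")
spec <- cohort_spec(n_patients = 40, patterns = pats,
                    mixing = setNames(rep(0.4, 5), pats),
                    noise_sd = 1, seed = 7)
sim <- simulate_cohort(spec)                     # 320 fields, 80 eyes

fit <- fit_archetypes(td_matrix(sim$records),
                      fit_options(k = 5, n_restarts = 3, seed = 1))
print(fit)
#> Archetype model: k = 5 ( 52 dims ), RSS = 17546.3
#>   RW (%):     28.3 18.5 18.5 18.5 16.1
#>   avg TD (dB): 2.0 -2.8 -3.6 0.7 -1.2
#>   normal archetype: AT1; restart 2; iterations 58
```

RW is each archetype's share of the cohort (they sum to 100%); average TD
tells you how depressed the pattern is. Decomposing a single field:

```r
decompose(td_matrix(sim$records)[1, ], fit)
#> VF decomposition over 5 archetypes
#>   PW (%): 98.5 0.0 1.5 0.0 0.0
#>   dominant AT1; meaningful: 1
```

— this exam is 98.5% normal with no meaningful abnormal archetype. Because
the cohort is synthetic, recovery can be scored against the planted truth:

```r
dec <- decompose_table(sim$records, fit)
score_recovery(fit, sim$truth, dec)$matching
#>   pattern                archetype cosine
#> 1 normal                         1  0.986
#> 2 enlarged_blind_spot            4  0.991
#> 3 superior_arcuate               3  0.995
#> 4 inferior_nasal_wedge           5  0.978
#> 5 global_depression_mild         2  0.984
```

Every planted pattern is found (cosine similarity ≥ 0.98 after optimal
matching). The normal-archetype weight tracks MD, the basis of the
prognosis analysis:

```r
pres <- dec[dec$visit_type == "presentation", ]
pw_md_correlation(pres$pw_1, pres$md)
#> presentation AT1 PW ~ MD: Spearman rho = 0.64, p < 2e-10
```

The numbered scripts under `analysis/` run the full clinic-style study on
the default 118-patient cohort — simulate (`01`), cross-validated model-order
curve (`02`), frozen 14-archetype fit with Fig-1-style maps (`03`),
per-field decomposition table (`04`), and the cohort report with severity
strata, prevalence, prognosis split and residual-deficit rates (`05`) —
writing tables and figures under `results/`.

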