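---
title: "Archetypal analysis of longitudinal 24-2 visual fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetypal analysis of longitudinal 24-2 visual fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A 24-2 visual field is summarized here by its 52 total-deviation (TD) values
— the pointwise difference, in dB, between measured sensitivity and
age-normative sensitivity at each test location, with the two blind-spot
points excluded. Archetypal analysis (AA) factorizes a matrix `X` of `n`
such fields as

    X ≈ A Z,   Z = B X,

where the `k` rows of `Z` are *archetypes* (ATs): extreme, clinically
recognizable patterns of field loss lying on the convex hull of the data.
Rows of `A` (one per field) and rows of `B` (one per archetype) are
constrained to the probability simplex, so every archetype is a convex
combination of observed fields and every field is approximated by a convex
combination of archetypes. The coefficients of a field, times 100, are its
*percent weights* (PW), which sum to 100%; the mean PW of an archetype over
a dataset is its *relative weight* (RW), its overall representation. An
archetype's *average TD* is the unweighted mean of its 52 values. AT1
denotes the normal (least-depressed) archetype, identified as the archetype
with the highest average TD; in practice it is also the highest-RW
archetype, and the fit warns if the two identifications disagree.

In idiopathic intracranial hypertension (IIH), papilledema produces field
loss spanning enlarged blind spot, arcuate and nasal defects, altitudinal
loss, and global depression, usually superimposed on a large normal
component that grows during treatment. Decomposing each exam of an eye on a
frozen archetype basis turns qualitative pattern reading into a small
vector of interpretable percentages that can be tracked across visits,
correlated with the global mean deviation (MD), and used to detect residual
focal deficits in eyes whose MD has normalized.

## Fitting: alternating constrained least squares

`fit_archetypes()` minimizes `||X − A B X||²` by alternation:

1. **A-step.** Each field is projected onto the simplex span of the current
   archetypes. The sum-to-one constraint is imposed by appending a penalty
   row of magnitude `penalty_weight` (default 200) to the design; the
   augmented problem is solved by exact non-negative least squares
   (Lawson–Hanson, compiled), and coefficients are renormalized to sum
   exactly to one. The penalty-row-plus-NNLS device keeps every subproblem
   an ordinary constrained regression.
2. **Archetype update.** The unconstrained optimum `Ẑ = (AᵀA)⁻¹AᵀX` is
   computed with a condition guard: if the condition number of `AᵀA`
   exceeds `max_kappa` (default 1000), the smallest diagonal ridge that
   restores the bound is added and recorded in the fit metadata.
3. **B-step.** Each ideal archetype `ẑⱼ` is expressed as a simplex
   combination of fields by the same penalty-row solver, and `Z = B X`.

Iterations stop when the relative RSS improvement falls below
`min_improvement` (default `sqrt(.Machine$double.eps)`) or after
`max_iterations` (default 100). A non-improving step restores the previous
iterate and stops with a warning, so the recorded RSS trace is
non-increasing by construction.

The classical B-step targets the *ideal* archetypes rather than the true
objective, and its fixed points can sit measurably above the constrained
optimum on small problems. After the alternation converges, a
projected-gradient **polish** therefore descends `||X − A B X||²` directly:
gradient steps in `B` with Euclidean row-wise simplex projection and
backtracking line search, interleaved with exact A-steps, accepting only
improving steps (cap `max_polish`, default 100). On brute-force-checkable
instances (two archetypes in two dimensions) the polished solution matches
or beats a dense 0.05-step grid search over the generators.

`B` is initialized with indicator rows of `k` distinct fields sampled
without replacement; `n_restarts` initializations (default 5) are run from
a single user seed and the lowest-RSS fit wins, ties to the lowest restart
index. Per-observation weights are deliberately not supported (the API
rejects non-uniform weights). Archetypes are reordered by descending RW
before the model is frozen; RW is computed by decomposing the training
fields on the frozen basis, not by reusing the training coefficients.

## Decomposition and the clinical rules

`decompose()` / `decompose_table()` solve the same simplex-constrained
regression for any field against a frozen basis; results are deterministic.
The clinical annotations follow fixed conventions, applied to unrounded PW:

* **Meaningful archetype**: PW ≥ 9% (inclusive at 9; a PW of 8% is below
  the cutoff). Displays round to integer percent, logic never does.
* **Abnormal meaningful set**: meaningful archetypes other than AT1.
* **Residual deficit**: a field with MD ≥ −2.00 dB whose abnormal
  meaningful set is non-empty. Fields with MD < −2 dB are never flagged —
  the notion only applies to fields called normal by MD.
* **Severity**: severe MD < −15; moderate −15 ≤ MD < −7; mild −7 ≤ MD < −2;
  normal MD ≥ −2 dB (closed/open boundaries exactly as written).
* **Reliability**: keep a field iff every available index is strictly below
  threshold (fixation losses < 33%, false positives/negatives < 15%);
  fields without reliability metadata are kept and flagged "unverified"
  rather than dropped, since deposited tables often omit these indices.
* **Dominant archetype**: argmax PW, ties to the lower index.

## Model-order selection

`assign_folds()` shuffles patients (not fields) by seed and deals them
round-robin into ten folds, so both eyes and all visits of a patient share
a fold and fold sizes differ by at most one patient. `rss_curve()` fits
each candidate `k` on nine folds, freezes the basis, decomposes the
held-out fields (coefficients are *not* refitted — exactly how a new
clinical field is scored), and aggregates train and test RSS.
`suggest_elbow()` makes the visual "where the curve flattens" judgment
explicit: the smallest `k` whose relative improvement in mean test RSS over
`k−1` falls below 2% and stays below for all larger `k`. It is a suggestion
printed with the full curve, never auto-applied; a fixed published model
size is reproduced by pinning `k` (the clinic-style fit here pins k = 14).
Note the rule's semantics on planted-rank data: if the true rank is `r`,
the drop *into* `r` is large and the first flat improvement is at `r + 1`,
so the suggestion lands one above the planted rank while the curve's
last informative point is the rank itself.

## The synthetic cohort generator

No patient-level clinic data are distributable, so the package generates
cohorts with known archetypal structure; every pipeline stage is validated
against that ground truth.

**Templates.** Nine planted TD patterns on the 24-2 grid, built from
coordinate masks in right-eye orientation: normal (+2.4 dB baseline),
enlarged blind spot (−15 dB on the six points adjacent to the blind spot),
superior arcuate (−20 dB, superior rows), inferior/superior nasal wedge
(−18 dB), inferior altitudinal (−25 dB), mild global depression (−6 dB
scaled by an eccentricity gradient plus an accentuated blind-spot region —
its clinical presentation, and the shape that keeps it affinely independent
of the healthy and severe-loss templates), severe global loss (−34 dB), and
a peripheral rim defect (−28 dB at eccentricity ≥ 15°). The nine templates
are affinely independent (rank 8 of centered differences), which is what
makes planted mixture weights identifiable.

**Cohort defaults** (chosen once to emulate a clinic IIH population):
118 patients × 2 eyes, exams at days 0/45/110/230 (presentation, two
interims, final inside the 150–365-day window); presentation mixing
weights drawn from a sparse Dirichlet (concentration 0.9 on normal, 0.9/8
on each defect; mean normal weight 0.5) so that most fields are dominated
by one or two patterns, as clinic fields are — and so that the data's
convex hull actually approaches the planted vertices, without which
"ground truth" would be unrecoverable by any method; multiplicative
recovery drift of the non-normal mass (rate 0.12 per 75 days), which also
plants the prognosis effect: eyes presenting with more normal weight end
follow-up with higher MD; i.i.d. Gaussian test–retest noise of 1.5 dB per
point, clamped to the valid TD range [−40, +15] dB. MD is defined as the
unweighted mean of the 52 TD values — the device's proprietary
normative-variance weighting is not emulated, and MD is otherwise always
taken from the input table verbatim, never recomputed.

**What the generator does not emulate:** eccentricity-dependent and
floor-dependent noise, learning and fatigue effects, lens artifacts, the
SITA staircase, irregular visit schedules, and recurrence. Passing
recovery benchmarks therefore demonstrates correctness of the machinery on
data with planted convex structure, not clinical performance on real
perimetry.

## Benchmark sizes and numerical choices

* Recovery benchmark: 5 well-separated patterns, symmetric Dirichlet(0.4),
  1 dB noise, 400 fields; fitted archetypes must match templates at cosine
  similarity > 0.95 under optimal (Hungarian) assignment and mean absolute
  PW error < 5 points; the cross-validated curve must flatten exactly
  beyond k = 5.
* Noise-floor check: at the planted rank, held-out RSS per field
  approaches `52 σ²`; the excess is archetype estimation error and shrinks
  with the training size (within 10% at ~600 training fields). The
  convexity constraint keeps the residual slightly above the floor for
  vertex-adjacent fields — noise pointing out of the hull cannot be
  absorbed.
* Oracles in the test suite are brute force by design: 0.01-step simplex
  grid search for decompositions, 0.05-step generator grid search for tiny
  fits, permutation enumeration for assignment, naive rank arithmetic for
  Spearman.
* Solver tolerances: NNLS active-set tolerance 1e-10 (scaled by the
  gradient magnitude so the penalty row does not swamp it); simplex rows
  renormalized to sum exactly 1; decomposition PW sums hold to 1e-6.
* Tie-breaks are deterministic everywhere: restarts with equal RSS to the
  lower index, dominant archetypes to the lower index, same-day visits by
  row order, eyes exactly at the prognosis-split mean to the "above" group.

## Known limitations

* With model order above the planted pattern count (k = 14 on a 9-pattern
  cohort — the configuration that mirrors a clinic-style fit), the normal
  mass splits across several near-normal archetypes and the split is
  seed-dependent: AT1's individual RW can vary by several percentage
  points between equally good fits, while its average TD is stable. RW
  values of single archetypes from one fit should be read with that
  caveat; RSS, decompositions against a *frozen* basis, and cohort-level
  statistics are reproducible.
* Comparing fitted RW to planted mixture mass is biased low near vertices:
  non-negativity means noise at a vertex can only be fitted by adding
  other archetypes.
* Left-eye mirroring (off by default) is an approximation: the 24-2 layout
  is not horizontally symmetric once blind-spot points are removed, so the
  two nasal-extension points and the two points whose mirror is the blind
  spot keep their values.
* Both eyes of a patient are analyzed without inter-eye correlation
  adjustment, following common practice for this design; patient
  identifiers are retained so users can cluster-bootstrap if desired.
* XLSX input is read; the writer emits CSV in the same column layout.

## Reproducing the pipeline

The numbered scripts under `analysis/` run the full story — simulate,
select k, fit k = 14, decompose, report — writing tables and figures under
`results/`. `scripts/acceptance.R --seed 1 --out results/acceptance.json`
recomputes the headline numbers from scratch in one pass.
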