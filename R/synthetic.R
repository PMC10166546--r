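NORMAL_TD <- 2.4  # baseline TD of the healthy template, dB

#' Library of planted visual-field defect patterns
#'
#' Nine TD templates on the 52 active points of the 24-2 grid, built from
#' coordinate masks in right-eye orientation (negative x nasal): a healthy
#' pattern plus eight canonical papilledema defect geometries. Each template
#' is the healthy baseline (+2.4 dB) with its region mask depressed by the
#' pattern's depth. Templates are deterministic.
#'
#' @param depth_overrides optional named numeric vector of depth overrides
#'   (dB, negative = depression), names from the pattern set.
#' @return named list of patterns; each has `name`, `td` (52 values),
#'   `mask` (logical 52), `depth`.
#' @export
#' @examples
#' lib <- make_pattern_library()
#' names(lib)
#' mean(lib$normal$td)   # about +2 dB
make_pattern_library <- function(depth_overrides = NULL) {
  g <- grid242_active()
  x <- g$x; y <- g$y
  near_bs <- (x == 9 & abs(y) == 3) | (x == 21 & abs(y) == 3) | (x == 15 & abs(y) == 9)
  # per-point depression weight w: td = baseline + depth * w. The mild
  # global depression carries an accentuated blind-spot region (its clinical
  # presentation in papilledema), which also keeps it off the straight line
  # between the healthy and severe-loss templates.
  defs <- list(
    normal              = list(w = rep(0, 52),                depth = 0),
    enlarged_blind_spot = list(w = as.numeric(near_bs),       depth = -15),
    superior_arcuate    = list(w = as.numeric(y >= 9),        depth = -20),
    inferior_nasal_wedge = list(w = as.numeric(x <= -9 & y < 0), depth = -18),
    superior_nasal_wedge = list(w = as.numeric(x <= -9 & y > 0), depth = -18),
    inferior_altitudinal = list(w = as.numeric(y < 0),        depth = -25),
    global_depression_mild = list(w = 0.55 + 0.02 * pmax(abs(x), abs(y)) + 1.5 * near_bs,
                                  depth = -6),
    global_loss_severe  = list(w = rep(1, 52),                depth = -34),
    peripheral_rim      = list(w = as.numeric(pmax(abs(x), abs(y)) >= 15), depth = -28)
  )
  if (!is.null(depth_overrides)) {
    unknown <- setdiff(names(depth_overrides), names(defs))
    if (length(unknown) > 0) {
      stop("unknown pattern name(s) in depth overrides: ",
           paste(unknown, collapse = ", "))
    }
    for (nm in names(depth_overrides)) defs[[nm]]$depth <- depth_overrides[[nm]]
  }
  lapply(stats::setNames(names(defs), names(defs)), function(nm) {
    d <- defs[[nm]]
    td <- pmax(rep(NORMAL_TD, 52) + d$depth * d$w, -40)
    list(name = nm, td = td, mask = d$w > 0, depth = d$depth)
  })
}

#' Specification of a synthetic longitudinal cohort
#'
#' Defaults emulate a papilledema clinic cohort: 118 patients, both eyes,
#' exams at presentation and roughly 6 weeks, 4 months and 8 months; each
#' eye's presentation field is a convex (Dirichlet) mixture of the planted
#' patterns, dominated on average by the healthy pattern (mean weight 0.5);
#' mixture mass drifts multiplicatively toward the healthy pattern over
#' follow-up (recovery), and each point receives i.i.d. Gaussian test-retest
#' noise. MD is defined as the unweighted mean of the 52 TD values (the
#' device's proprietary normative weighting is not emulated).
#'
#' @param n_patients number of patients.
#' @param eyes_per_patient 1 or 2.
#' @param visit_days exam schedule in days since presentation (starts at 0).
#' @param patterns pattern names to mix (default: full library).
#' @param mixing named Dirichlet concentrations per pattern; default gives
#'   the healthy pattern mean weight 0.5.
#' @param recovery_drift per-75-day multiplicative decay of non-healthy
#'   mixture mass (negative values model progression).
#' @param noise_sd per-point additive noise SD in dB.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 118,
                        eyes_per_patient = 2,
                        visit_days = c(0, 45, 110, 230),
                        patterns = NULL,
                        mixing = NULL,
                        recovery_drift = 0.12,
                        noise_sd = 1.5,
                        seed = 1L) {
  lib_names <- names(make_pattern_library())
  if (is.null(patterns)) patterns <- lib_names
  stopifnot(all(patterns %in% lib_names), "normal" %in% patterns)
  if (is.null(mixing)) {
    # sparse mixture: most fields dominated by one or two patterns, the
    # healthy pattern carrying half the mass on average
    mixing <- stats::setNames(rep(0.9 / (length(patterns) - 1), length(patterns)),
                              patterns)
    mixing[["normal"]] <- 0.9
  }
  stopifnot(all(names(mixing) %in% patterns), all(mixing > 0),
            length(mixing) == length(patterns))
  stopifnot(noise_sd >= 0, visit_days[1] == 0, all(diff(visit_days) > 0),
            n_patients >= 1, eyes_per_patient %in% c(1, 2))
  structure(
    list(n_patients = as.integer(n_patients),
         eyes_per_patient = as.integer(eyes_per_patient),
         visit_days = visit_days,
         patterns = patterns,
         mixing = mixing[patterns],
         recovery_drift = recovery_drift,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @keywords internal
rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha  # numerically degenerate draw
  g / sum(g)
}

#' @keywords internal
drift_weights <- function(w, normal_idx, rate, days) {
  f <- (1 - rate)^(days / 75)
  others <- setdiff(seq_along(w), normal_idx)
  wo <- w[others] * f
  if (sum(wo) >= 0.999) wo <- wo * (0.999 / sum(wo))
  w[others] <- wo
  w[normal_idx] <- 1 - sum(wo)
  w / sum(w)
}

#' Simulate a longitudinal visual-field cohort with known structure
#'
#' Generates one field per eye per scheduled visit: a Dirichlet mixture over
#' the planted templates, drifting toward the healthy pattern between visits,
#' plus i.i.d. per-point noise (clamped to the valid TD range
#' \[-40, +15\] dB). Visit types follow the usual convention (presentation =
#' day 0, final = last exam in the 150-365-day window, interim otherwise).
#' The returned truth object holds the mixing weights of every field and the
#' template matrix, for recovery scoring.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (a visual-field table) and `truth`
#'   (`templates` p x 52 matrix, `weights` n_fields x p matrix aligned with
#'   the record rows, `patterns`, `normal_idx`, `spec`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  lib <- make_pattern_library()[spec$patterns]
  Tm <- do.call(rbind, lapply(lib, `[[`, "td"))
  rownames(Tm) <- spec$patterns
  p <- nrow(Tm)
  normal_idx <- match("normal", spec$patterns)
  n_visits <- length(spec$visit_days)
  n_eyes <- spec$n_patients * spec$eyes_per_patient
  n_fields <- n_eyes * n_visits

  set.seed(spec$seed)
  W <- matrix(NA_real_, n_fields, p)
  meta <- vector("list", n_fields)
  row <- 0L
  final_window <- c(150, 365)
  in_final <- spec$visit_days >= final_window[1] & spec$visit_days <= final_window[2]
  final_day <- if (any(in_final)) max(spec$visit_days[in_final]) else NA_real_

  for (pat in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", pat)
    for (e in seq_len(spec$eyes_per_patient)) {
      eye <- c("OD", "OS")[e]
      w <- rdirichlet_one(spec$mixing)
      for (v in seq_len(n_visits)) {
        day <- spec$visit_days[v]
        if (v > 1) {
          w <- drift_weights(w, normal_idx, spec$recovery_drift,
                             day - spec$visit_days[v - 1])
        }
        row <- row + 1L
        W[row, ] <- w
        vtype <- if (day == 0) "presentation"
                 else if (!is.na(final_day) && day == final_day) "final"
                 else "interim"
        meta[[row]] <- list(patient_id = pid, eye = eye,
                            visit_day = day, visit_type = vtype)
      }
    }
  }

  TD <- W %*% Tm
  if (spec$noise_sd > 0) {
    TD <- TD + matrix(stats::rnorm(length(TD), sd = spec$noise_sd),
                      nrow = nrow(TD))
  }
  TD <- pmin(pmax(TD, -40), 15)

  records <- tibble::tibble(
    patient_id = vapply(meta, `[[`, character(1), "patient_id"),
    eye = vapply(meta, `[[`, character(1), "eye"),
    visit_day = as.integer(vapply(meta, `[[`, numeric(1), "visit_day")),
    visit_type = vapply(meta, `[[`, character(1), "visit_type"),
    fixation_loss_pct = NA_real_,
    false_pos_pct = NA_real_,
    false_neg_pct = NA_real_
  )
  td_tbl <- tibble::as_tibble(as.data.frame(TD))
  names(td_tbl) <- td_cols()
  records <- dplyr::bind_cols(records, td_tbl)
  records$md <- rowMeans(TD)

  list(
    records = records,
    truth = list(templates = Tm, weights = W, patterns = spec$patterns,
                 normal_idx = normal_idx, spec = spec)
  )
}

#' Score how well a fitted model recovers the planted structure
#'
#' Matches fitted archetypes to planted templates one-to-one by minimizing
#' total correlation distance (1 - cosine similarity) over assignments, and
#' reports the cosine similarity of each matched pair. When a decomposition
#' of the generated fields is supplied, also reports the mean absolute error
#' between estimated percent weights and 100 x the planted mixing weights
#' under the same matching.
#'
#' @param model an `archetype_model` fitted to the generated fields.
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @param decompositions optional [decompose_table()] result on the same
#'   records, against `model`.
#' @return list: `matching` tibble `(pattern, archetype, cosine)`,
#'   `min_cosine`, `mean_cosine`, `pw_mae` (NA without decompositions),
#'   `partial` (TRUE when model k differs from the planted count).
#' @export
score_recovery <- function(model, truth, decompositions = NULL) {
  stopifnot(inherits(model, "archetype_model"))
  Z <- model$archetypes
  Tm <- truth$templates
  k <- nrow(Z); p <- nrow(Tm)
  m <- min(k, p)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  S <- matrix(0, p, k)
  for (i in seq_len(p)) for (j in seq_len(k)) S[i, j] <- cosine(Tm[i, ], Z[j, ])

  if (k == p) {
    match_cols <- assignment_min(1 - S)
  } else {
    # partial matching: pad the cost matrix square with zero-cost dummies
    n <- max(k, p)
    C <- matrix(0, n, n)
    C[seq_len(p), seq_len(k)] <- 1 - S
    full <- assignment_min(C)
    match_cols <- full[seq_len(p)]
    match_cols[match_cols > k] <- NA_integer_
  }
  matching <- tibble::tibble(
    pattern = rownames(Tm),
    archetype = match_cols,
    cosine = vapply(seq_len(p), function(i) {
      if (is.na(match_cols[i])) NA_real_ else S[i, match_cols[i]]
    }, numeric(1))
  )

  pw_mae <- NA_real_
  if (!is.null(decompositions)) {
    kk <- attr(decompositions, "model_k")
    stopifnot(kk == k, nrow(decompositions) == nrow(truth$weights))
    pw <- as.matrix(decompositions[, paste0("pw_", seq_len(k))])
    ok <- !is.na(match_cols)
    pw_mae <- mean(abs(pw[, match_cols[ok], drop = FALSE] -
                         100 * truth$weights[, ok, drop = FALSE]))
  }
  list(matching = matching,
       min_cosine = min(matching$cosine, na.rm = TRUE),
       mean_cosine = mean(matching$cosine, na.rm = TRUE),
       pw_mae = pw_mae,
       partial = (k != p))
}
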