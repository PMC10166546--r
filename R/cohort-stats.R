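#' Relative weights of the archetypes over a decomposed dataset
#'
#' RW of archetype j is the mean percent weight of archetype j across all
#' fields of the dataset — its overall representation, in percent. RWs sum
#' to 100 (up to renormalization residue well below 0.1).
#'
#' @param decompositions a table produced by [decompose_table()] (all rows
#'   against the same model).
#' @return named numeric vector `RW_1..RW_k`, in percent.
#' @export
relative_weights <- function(decompositions) {
  k <- attr(decompositions, "model_k")
  if (is.null(k)) stop("decompositions must come from decompose_table()")
  pw_cols <- paste0("pw_", seq_len(k))
  stopifnot(all(pw_cols %in% names(decompositions)))
  rw <- colMeans(as.matrix(decompositions[, pw_cols]))
  names(rw) <- paste0("AT", seq_len(k))
  rw
}

#' Average total deviation of an archetype
#'
#' The unweighted mean of the archetype's TD values, in dB.
#'
#' @param z numeric vector of TD values (52 for the 24-2 grid).
#' @return scalar dB.
#' @export
average_td <- function(z) mean(as.numeric(z))

#' Archetype prevalence table
#'
#' For each archetype: the number and percentage of fields in which it is
#' meaningful (unrounded PW at or above the cutoff). Also returns the
#' distribution of abnormal-meaningful-archetype counts per field and the
#' share of fields with none.
#'
#' @param decompositions a [decompose_table()] result, optionally filtered to
#'   one visit type beforehand.
#' @param scope optional visit type (`"presentation"`, `"interim"`,
#'   `"final"`) to filter on.
#' @return list with `prevalence` tibble `(at, n_meaningful, pct)`,
#'   `abnormal_count_distribution` tibble `(n_abnormal, n_fields, pct)`, and
#'   `pct_no_abnormal`.
#' @export
at_prevalence <- function(decompositions, scope = NULL) {
  k <- attr(decompositions, "model_k")
  cutoff <- attr(decompositions, "cutoff_pct")
  if (is.null(k)) stop("decompositions must come from decompose_table()")
  d <- decompositions
  if (!is.null(scope)) d <- d[d$visit_type %in% scope, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no fields in scope '", paste(scope, collapse = ","), "'")
    return(list(prevalence = tibble::tibble(at = integer(), n_meaningful = integer(),
                                            pct = numeric()),
                abnormal_count_distribution = tibble::tibble(n_abnormal = integer(),
                                                             n_fields = integer(),
                                                             pct = numeric()),
                pct_no_abnormal = NA_real_))
  }
  pw <- as.matrix(d[, paste0("pw_", seq_len(k))])
  meaningful <- pw >= cutoff
  prevalence <- tibble::tibble(
    at = seq_len(k),
    n_meaningful = unname(colSums(meaningful)),
    pct = unname(100 * colSums(meaningful) / nrow(d))
  )
  dist <- table(factor(d$n_abnormal_meaningful, levels = 0:k))
  list(
    prevalence = prevalence,
    abnormal_count_distribution = tibble::tibble(
      n_abnormal = as.integer(names(dist)),
      n_fields = as.integer(dist),
      pct = 100 * as.integer(dist) / nrow(d)
    ),
    pct_no_abnormal = 100 * mean(d$n_abnormal_meaningful == 0)
  )
}

#' Spearman correlation between an archetype PW and MD
#'
#' Rank correlation with average ranks for ties and a two-sided p-value.
#'
#' @param pw numeric vector of percent weights.
#' @param md numeric vector of mean deviations (same length, >= 3 pairs).
#' @return list `(rho, p)`.
#' @export
pw_md_correlation <- function(pw, md) {
  stopifnot(length(pw) == length(md), length(pw) >= 3)
  if (stats::sd(pw) == 0 || stats::sd(md) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- suppressWarnings(stats::cor.test(pw, md, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-group comparison (rank-sum or chi-square)
#'
#' Standard two-sided tests at the 0.05 level: Mann-Whitney/Wilcoxon rank sum
#' for numeric samples, chi-square for a contingency table (passed as `a`,
#' with `b` omitted).
#'
#' @param a numeric sample, or a contingency table/matrix for `"chisq"`.
#' @param b numeric sample (ranksum only).
#' @param kind `"ranksum"` or `"chisq"`.
#' @return list `(statistic, p)`.
#' @export
compare_groups <- function(a, b = NULL, kind = c("ranksum", "chisq")) {
  kind <- match.arg(kind)
  if (kind == "ranksum") {
    stopifnot(length(a) > 0, length(b) > 0)
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    list(statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    tab <- as.matrix(a)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts == 0)) stop("chi-square undefined: expected cell count of 0")
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(statistic = unname(ct$statistic), p = ct$p.value)
  }
}

#' @keywords internal
t_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Prognosis split on the presentation normal-archetype percent weight
#'
#' Computes the cohort mean presentation AT1 PW (AT1 = the model's normal
#' archetype), splits eyes into an above-mean and a below-mean group (an eye
#' exactly at the mean goes to the above group), and summarizes each group's
#' MD over the visit windows (presentation, day 1-75, day 75-150, final)
#' with t-based 95% confidence intervals, plus each group's final-visit AT1
#' PW. Group differences at each window are tested by rank sum.
#'
#' @param decompositions a [decompose_table()] result covering all visits,
#'   with `visit_type` and `visit_day` present.
#' @param windows list of named numeric length-2 day ranges for the interim
#'   curve; presentation and final visits are taken from `visit_type`.
#' @return list of class `prognosis_split`: `mean_at1_pw`, `groups` (eye
#'   assignment tibble), `md_curve` (per window/group mean MD + CI),
#'   `final_at1_pw` (per group mean + CI), `tests` (per window rank-sum p).
#' @export
prognosis_split <- function(decompositions,
                            windows = list(interim_1_75 = c(1, 75),
                                           interim_75_150 = c(75.0001, 150))) {
  k <- attr(decompositions, "model_k")
  normal_at <- attr(decompositions, "normal_at")
  if (is.null(k)) stop("decompositions must come from decompose_table()")
  d <- decompositions
  d$eye_id <- paste(d$patient_id, d$eye, sep = "/")
  at1 <- paste0("pw_", normal_at)

  pres <- d[d$visit_type == "presentation", , drop = FALSE]
  if (nrow(pres) == 0) stop("no presentation fields")
  if (anyDuplicated(pres$eye_id)) stop("multiple presentation fields for one eye")
  mean_at1 <- mean(pres[[at1]])
  if (stats::sd(pres[[at1]]) == 0) {
    stop("degenerate split: all eyes share presentation AT1 PW = ", mean_at1)
  }
  groups <- tibble::tibble(
    eye_id = pres$eye_id,
    presentation_at1_pw = pres[[at1]],
    group = ifelse(pres[[at1]] >= mean_at1, "above", "below")
  )
  if (length(unique(groups$group)) < 2) {
    stop("degenerate split: one group is empty at mean AT1 PW = ", mean_at1)
  }
  d <- dplyr::left_join(d, groups[, c("eye_id", "group")], by = "eye_id")
  d <- d[!is.na(d$group), , drop = FALSE]

  window_of <- function(df) {
    w <- rep(NA_character_, nrow(df))
    w[df$visit_type == "presentation"] <- "presentation"
    w[df$visit_type == "final"] <- "final"
    for (nm in names(windows)) {
      rng <- windows[[nm]]
      sel <- is.na(w) & df$visit_day >= rng[1] & df$visit_day <= rng[2]
      w[sel] <- nm
    }
    w
  }
  d$window <- window_of(d)
  dw <- d[!is.na(d$window), , drop = FALSE]
  window_levels <- c("presentation", names(windows), "final")

  md_curve <- dw |>
    dplyr::group_by(.data$window, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_md = mean(.data$md),
      ci_lo = t_ci(.data$md)[["lo"]],
      ci_hi = t_ci(.data$md)[["hi"]],
      .groups = "drop"
    ) |>
    dplyr::mutate(window = factor(.data$window, levels = window_levels)) |>
    dplyr::arrange(.data$window, .data$group)

  tests <- lapply(window_levels, function(wname) {
    sub <- dw[dw$window == wname, , drop = FALSE]
    a <- sub$md[sub$group == "above"]
    b <- sub$md[sub$group == "below"]
    if (length(a) == 0 || length(b) == 0) return(NULL)
    tibble::tibble(window = wname, p_md = compare_groups(a, b, "ranksum")$p)
  })
  tests <- dplyr::bind_rows(tests)

  fin <- dw[dw$window == "final", , drop = FALSE]
  final_at1 <- fin |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_at1_pw = mean(.data[[at1]]),
      ci_lo = t_ci(.data[[at1]])[["lo"]],
      ci_hi = t_ci(.data[[at1]])[["hi"]],
      .groups = "drop"
    )
  p_final_at1 <- if (nrow(final_at1) == 2) {
    compare_groups(fin[[at1]][fin$group == "above"],
                   fin[[at1]][fin$group == "below"], "ranksum")$p
  } else NA_real_

  structure(
    list(mean_at1_pw = mean_at1, groups = groups, md_curve = md_curve,
         final_at1_pw = final_at1, p_final_at1_pw = p_final_at1, tests = tests),
    class = "prognosis_split"
  )
}

#' @export
print.prognosis_split <- function(x, ...) {
  cat("Prognosis split at mean presentation AT1 PW =",
      sprintf("%.1f%%", x$mean_at1_pw), "\n")
  cat("  above:", sum(x$groups$group == "above"),
      "eyes; below:", sum(x$groups$group == "below"), "eyes\n")
  print(x$md_curve)
  invisible(x)
}
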