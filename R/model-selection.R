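#' Assign patients to cross-validation folds
#'
#' Patient-grouped folds: every record of a patient (both eyes, all visits)
#' shares one fold, so no patient contributes to both a training and a test
#' split. Patients are shuffled by the seed and dealt round-robin, so fold
#' sizes differ by at most one patient and the assignment does not depend on
#' record order.
#'
#' @param records visual-field table with `patient_id`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return tibble `(patient_id, fold)`.
#' @export
assign_folds <- function(records, n_folds = 10, seed = 1) {
  patients <- sort(unique(records$patient_id))
  if (length(patients) < n_folds) {
    stop("need at least ", n_folds, " patients for ", n_folds,
         "-fold assignment; have ", length(patients))
  }
  set.seed(seed)
  shuffled <- sample(patients)
  tibble::tibble(
    patient_id = shuffled,
    fold = rep_len(seq_len(n_folds), length(shuffled))
  )
}

#' Cross-validated RSS curve over candidate archetype counts
#'
#' For each fold and each `k`: fit on the training split, freeze the basis,
#' decompose the held-out fields on it (the same simplex decomposition used
#' for new clinical fields — held-out coefficients are not re-fitted), and
#' record train and test RSS. A failed fold fit is flagged (`ok = FALSE`)
#' rather than dropped.
#'
#' @param records visual-field table.
#' @param k_range candidate archetype counts (default 2:20).
#' @param folds fold assignment from [assign_folds()].
#' @param opts_base an [fit_options()] whose `k` is overridden per curve
#'   point; reduce `n_restarts`/`max_iterations` here to bound compute.
#' @return object of class `rss_curve`: `per_fold` tibble
#'   `(k, fold, n_train, n_test, train_rss, test_rss, ok)`, `summary` tibble
#'   `(k, mean_train_rss, mean_test_rss, sd_test_rss)`, and `chosen_k` from
#'   [suggest_elbow()] (a suggestion to confirm against the plotted curve,
#'   never auto-applied).
#' @export
rss_curve <- function(records, k_range = 2:20, folds = NULL, opts_base = fit_options(k = 2)) {
  stopifnot(all(diff(k_range) > 0), length(k_range) >= 1)
  if (is.null(folds)) folds <- assign_folds(records, seed = opts_base$seed)
  recs <- dplyr::left_join(records, folds, by = "patient_id")
  if (any(is.na(recs$fold))) stop("records contain patients absent from the fold assignment")
  n_folds <- max(folds$fold)
  min_train <- min(vapply(seq_len(n_folds),
                          function(f) sum(recs$fold != f), integer(1)))
  if (max(k_range) >= min_train) {
    stop("k_max (", max(k_range), ") must be smaller than the smallest training split (",
         min_train, ")")
  }

  rows <- list()
  for (f in seq_len(n_folds)) {
    train <- recs[recs$fold != f, , drop = FALSE]
    test <- recs[recs$fold == f, , drop = FALSE]
    X_train <- td_matrix(train)
    X_test <- td_matrix(test)
    for (k in k_range) {
      opts <- opts_base
      opts$k <- as.integer(k)
      entry <- tryCatch({
        fit <- suppressWarnings(fit_archetypes(X_train, opts))
        W <- simplex_lsq(t(fit$archetypes), t(X_test), opts$penalty_weight)
        test_rss <- sum((X_test - t(W) %*% fit$archetypes)^2)
        tibble::tibble(k = k, fold = f, n_train = nrow(train), n_test = nrow(test),
                       train_rss = fit$rss, test_rss = test_rss, ok = TRUE)
      }, error = function(e) {
        warning("fold ", f, ", k = ", k, " failed: ", conditionMessage(e))
        tibble::tibble(k = k, fold = f, n_train = nrow(train), n_test = nrow(test),
                       train_rss = NA_real_, test_rss = NA_real_, ok = FALSE)
      })
      rows[[length(rows) + 1L]] <- entry
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  summary <- per_fold |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      mean_train_rss = mean(.data$train_rss, na.rm = TRUE),
      mean_test_rss = mean(.data$test_rss, na.rm = TRUE),
      sd_test_rss = stats::sd(.data$test_rss, na.rm = TRUE),
      n_failed = sum(!.data$ok),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$k)
  curve <- structure(list(per_fold = per_fold, summary = summary), class = "rss_curve")
  elbow <- suggest_elbow(curve)
  curve$chosen_k <- elbow$chosen_k
  curve$no_plateau <- elbow$no_plateau
  curve$rationale <- elbow$rationale
  curve
}

#' Suggest the flattening point of an RSS curve
#'
#' The visual "where the curve begins to flatten" judgment made explicit:
#' the smallest `k` whose relative improvement in mean test RSS over the
#' previous `k` falls below the threshold and stays below it for all larger
#' `k`. Returned as a suggestion with the full curve; pin `k` explicitly to
#' reproduce a fixed published choice.
#'
#' @param curve an `rss_curve`, or a numeric vector of mean test RSS values
#'   with `k` taken from `names()` or `k_values`.
#' @param rel_improvement_threshold sustained relative improvement below
#'   which the curve counts as flat (default 0.02).
#' @param k_values optional k values when `curve` is a bare numeric vector.
#' @return list `(chosen_k, no_plateau, rationale)`; when no k satisfies the
#'   rule, `chosen_k` is the largest k with `no_plateau = TRUE`.
#' @export
suggest_elbow <- function(curve, rel_improvement_threshold = 0.02, k_values = NULL) {
  if (inherits(curve, "rss_curve")) {
    ks <- curve$summary$k
    rss <- curve$summary$mean_test_rss
  } else {
    rss <- as.numeric(curve)
    ks <- if (!is.null(k_values)) k_values else
      if (!is.null(names(curve))) as.numeric(names(curve)) else seq_along(rss) + 1
  }
  stopifnot(length(rss) >= 3, length(ks) == length(rss))
  imp <- (head(rss, -1) - tail(rss, -1)) / head(rss, -1)   # improvement at ks[-1]
  flat <- imp < rel_improvement_threshold
  sustained <- rev(cumprod(rev(flat))) == 1
  if (any(sustained)) {
    i <- which(sustained)[1]
    list(chosen_k = ks[i + 1], no_plateau = FALSE,
         rationale = sprintf(
           "first k with sustained relative test-RSS improvement < %g%%",
           100 * rel_improvement_threshold))
  } else {
    list(chosen_k = ks[length(ks)], no_plateau = TRUE,
         rationale = "no plateau: improvement never stays below threshold; returning k_max")
  }
}

#' @export
print.rss_curve <- function(x, ...) {
  cat("Cross-validated RSS curve (", nrow(x$summary), " k values)\n", sep = "")
  print(x$summary, n = nrow(x$summary))
  cat("suggested k:", x$chosen_k,
      if (isTRUE(x$no_plateau)) "(no plateau)" else "", "\n")
  invisible(x)
}
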