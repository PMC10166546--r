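#' Decompose a field onto a frozen archetype basis
#'
#' Solves `min || td - Z' w ||^2` subject to `w >= 0, sum(w) = 1` (the same
#' penalty-row device used in fitting) and reports percent weights
#' `pw = 100 w`, the residual RSS of the reconstruction, the dominant
#' archetype (largest PW, ties toward the lower index), the meaningful set
#' (unrounded PW at or above the cutoff, 9% by default) and the abnormal
#' meaningful set (meaningful archetypes other than the model's normal
#' archetype).
#'
#' @param td numeric vector of TD values (length `model$d`), or a one-row
#'   visual-field table.
#' @param model an `archetype_model`.
#' @param cutoff_pct meaningfulness cutoff in percent (inclusive).
#' @return list of class `vf_decomposition` with elements `pw`, `rss`,
#'   `dominant_at`, `meaningful_set`, `abnormal_meaningful_set`, `cutoff_pct`.
#' @export
decompose <- function(td, model, cutoff_pct = 9) {
  stopifnot(inherits(model, "archetype_model"))
  if (is.data.frame(td)) {
    stopifnot(nrow(td) == 1L)
    td <- as.numeric(td_matrix(td)[1L, ])
  }
  td <- as.numeric(td)
  if (length(td) != model$d) {
    stop("field has ", length(td), " values but the model basis has ", model$d)
  }
  pw <- drop(decompose_matrix(matrix(td, nrow = 1), model))
  annotate_decomposition(pw, model, cutoff_pct,
                         rss = sum((td - drop(pw %*% model$archetypes) / 100)^2))
}

#' @keywords internal
annotate_decomposition <- function(pw, model, cutoff_pct, rss) {
  stopifnot(cutoff_pct > 0, cutoff_pct < 100)
  meaningful <- which(pw >= cutoff_pct)
  structure(
    list(
      pw = pw,
      rss = rss,
      dominant_at = which.max(pw),
      meaningful_set = meaningful,
      abnormal_meaningful_set = setdiff(meaningful, model$normal_at),
      cutoff_pct = cutoff_pct,
      normal_at = model$normal_at
    ),
    class = "vf_decomposition"
  )
}

#' @keywords internal
decompose_matrix <- function(X, model) {
  W <- simplex_lsq(t(model$archetypes), t(X), model$opts$penalty_weight)
  100 * t(W)   # n x k percent weights
}

#' Decompose every field of a table onto a frozen basis
#'
#' @param records visual-field table.
#' @param model an `archetype_model` fitted on the 52-point grid.
#' @param cutoff_pct meaningfulness cutoff in percent.
#' @return the input table with added columns `pw_1..pw_k`, `rss`,
#'   `dominant_at`, `n_meaningful`, `n_abnormal_meaningful`,
#'   `residual_deficit`; the model reference is stored in
#'   `attr(x, "model_k")` / `attr(x, "model_id")`.
#' @export
decompose_table <- function(records, model, cutoff_pct = 9) {
  stopifnot(inherits(model, "archetype_model"))
  X <- td_matrix(records)
  pw <- decompose_matrix(X, model)
  resid <- X - (pw / 100) %*% model$archetypes
  out <- records
  for (j in seq_len(model$k)) out[[paste0("pw_", j)]] <- pw[, j]
  out$rss <- rowSums(resid^2)
  out$dominant_at <- apply(pw, 1L, which.max)
  meaningful <- pw >= cutoff_pct
  out$n_meaningful <- rowSums(meaningful)
  abn <- meaningful
  abn[, model$normal_at] <- FALSE
  out$n_abnormal_meaningful <- rowSums(abn)
  out$residual_deficit <- out$md >= -2 & out$n_abnormal_meaningful > 0
  attr(out, "model_k") <- model$k
  attr(out, "model_id") <- model_id(model)
  attr(out, "normal_at") <- model$normal_at
  attr(out, "cutoff_pct") <- cutoff_pct
  out
}

#' @keywords internal
model_id <- function(model) {
  # cheap content fingerprint so mixed-model aggregation can be refused
  z <- model$archetypes
  paste0("k", model$k, "-", format(sum(z * seq_along(z)), digits = 12))
}

#' Meaningful archetypes of a decomposition
#'
#' Indices whose unrounded percent weight is at or above the cutoff
#' (inclusive at the cutoff; applied before any display rounding).
#'
#' @param dec a `vf_decomposition`.
#' @param cutoff_pct cutoff in percent, in (0, 100).
#' @return integer vector of archetype indices.
#' @export
meaningful_ats <- function(dec, cutoff_pct = 9) {
  stopifnot(inherits(dec, "vf_decomposition"), cutoff_pct > 0, cutoff_pct < 100)
  which(dec$pw >= cutoff_pct)
}

#' Number of abnormal meaningful archetypes
#'
#' Counts meaningful archetypes other than the model's normal archetype
#' (the archetype with the highest average TD).
#'
#' @param dec a `vf_decomposition`.
#' @return integer count.
#' @export
count_abnormal <- function(dec) {
  stopifnot(inherits(dec, "vf_decomposition"))
  length(dec$abnormal_meaningful_set)
}

#' Residual-deficit flag for an MD-normal field
#'
#' `TRUE` iff the field's MD is in the normal range (>= -2.00 dB) and its
#' decomposition contains at least one abnormal archetype of meaningful
#' percent weight. Fields with MD < -2 dB are never flagged: the concept is
#' defined only for fields called "normal" by MD.
#'
#' @param md the field's mean deviation (dB).
#' @param dec the field's `vf_decomposition`.
#' @return logical flag.
#' @export
residual_deficit <- function(md, dec) {
  stopifnot(is.finite(md), inherits(dec, "vf_decomposition"))
  md >= -2 && length(dec$abnormal_meaningful_set) > 0
}

#' @export
print.vf_decomposition <- function(x, ...) {
  cat("VF decomposition over", length(x$pw), "archetypes\n")
  cat("  PW (%):", paste(sprintf("%.1f", x$pw), collapse = " "), "\n")
  cat("  dominant AT", x$dominant_at, "; meaningful: ",
      paste(x$meaningful_set, collapse = ","), "\n", sep = "")
  invisible(x)
}
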