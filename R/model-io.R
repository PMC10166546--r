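#' Write an archetype model to JSON
#'
#' Serializes the frozen basis plus the metadata needed to decompose new
#' fields against it later: grid layout tag, archetype vectors, RW and
#' average TD, normal-archetype index, fit options, seed and mirroring flag.
#' Training coefficient matrices (`A`, `B`) are not stored; the archetypes
#' are the frozen artifact.
#'
#' @param model an `archetype_model`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "archetype_model"))
  payload <- list(
    format = "vfarchetypes-model",
    version = 1L,
    grid = if (model$d == 52L) "24-2-active-52" else paste0("generic-", model$d),
    k = model$k,
    d = model$d,
    archetypes = unname(apply(model$archetypes, 1L, as.numeric, simplify = FALSE)),
    rw = as.numeric(model$rw),
    avg_td = as.numeric(model$avg_td),
    normal_at = model$normal_at,
    rss = model$rss,
    iterations = model$iterations,
    restart = model$restart,
    mirrored = model$mirrored,
    opts = unclass(model$opts)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an archetype model from JSON
#'
#' @param path path written by [write_model_json()].
#' @return an `archetype_model` (without training coefficients).
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "vfarchetypes-model") {
    stop("not a vfarchetypes model file: ", path)
  }
  Z <- if (is.matrix(p$archetypes)) {
    p$archetypes   # read_json simplifies equal-length rows to a matrix
  } else {
    do.call(rbind, lapply(p$archetypes, as.numeric))
  }
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  dimnames(Z) <- NULL
  rownames(Z) <- paste0("AT", seq_len(p$k))
  opts <- p$opts
  structure(
    list(
      k = as.integer(p$k),
      archetypes = Z,
      A = NULL, B = NULL,
      rw = as.numeric(p$rw),
      avg_td = as.numeric(p$avg_td),
      normal_at = as.integer(p$normal_at),
      rss = p$rss,
      rss_trace = NULL,
      iterations = p$iterations,
      restart = p$restart,
      ridge_events = NULL,
      opts = structure(opts, class = "aa_fit_options"),
      mirrored = isTRUE(p$mirrored),
      d = as.integer(p$d)
    ),
    class = "archetype_model"
  )
}
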