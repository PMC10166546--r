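#' The 24-2 test-point grid
#'
#' Coordinates and ordering of the 54 locations of the standard 24-2 perimetry
#' pattern, in right-eye (OD) chart orientation: positive x temporal, positive
#' y superior, raster order (superior row first, left to right within each
#' row) as on a standard printout. Two points fall on the physiologic blind
#' spot (indices 26 and 35, at 15 degrees temporal, +/-3 degrees vertical) and
#' are excluded from analysis; the remaining 52 "active" points carry the TD
#' values, always in the order given by [grid242_active()].
#'
#' @return A tibble with columns `index` (1-54), `x`, `y` (degrees), and
#'   `blind_spot` (logical).
#' @export
#' @examples
#' g <- grid242()
#' sum(g$blind_spot)          # 2
#' g$index[g$blind_spot]      # 26, 35
grid242 <- function() {
  rows <- list(
    list(y = 21,  x = c(-9, -3, 3, 9)),
    list(y = 15,  x = seq(-15, 15, by = 6)),
    list(y = 9,   x = seq(-21, 21, by = 6)),
    list(y = 3,   x = seq(-27, 21, by = 6)),
    list(y = -3,  x = seq(-27, 21, by = 6)),
    list(y = -9,  x = seq(-21, 21, by = 6)),
    list(y = -15, x = seq(-15, 15, by = 6)),
    list(y = -21, x = c(-9, -3, 3, 9))
  )
  x <- unlist(lapply(rows, `[[`, "x"))
  y <- unlist(lapply(rows, function(r) rep(r$y, length(r$x))))
  tibble::tibble(
    index = seq_along(x),
    x = x,
    y = y,
    blind_spot = (x == 15 & abs(y) == 3)
  )
}

#' Blind-spot indices of the 24-2 grid
#' @return Integer vector `c(26, 35)`.
#' @export
blind_spot_indices <- function() {
  g <- grid242()
  g$index[g$blind_spot]
}

#' Active (non-blind-spot) points of the 24-2 grid
#'
#' @return A tibble of the 52 active points with columns `index` (original
#'   1-54 index), `active_index` (1-52, the TD vector position), `x`, `y`.
#' @export
grid242_active <- function() {
  g <- grid242()[!grid242()$blind_spot, c("index", "x", "y")]
  g$active_index <- seq_len(nrow(g))
  g[, c("index", "active_index", "x", "y")]
}

#' Mirror a TD vector horizontally (OS to OD orientation)
#'
#' Swaps the values of active points at (x, y) and (-x, y) wherever both
#' exist. The 24-2 layout is not symmetric once the blind-spot points are
#' removed: the two nasal-extension points (x = -27) and the two points whose
#' mirror image is the excluded blind spot keep their values. Applying the
#' mirror twice returns the input.
#'
#' @param td numeric vector of 52 TD values in active order, or a matrix with
#'   52 columns (one field per row).
#' @return The mirrored vector or matrix.
#' @export
mirror_td <- function(td) {
  g <- grid242_active()
  perm <- vapply(seq_len(nrow(g)), function(i) {
    j <- which(g$x == -g$x[i] & g$y == g$y[i])
    if (length(j) == 1) j else i
  }, integer(1))
  if (is.matrix(td)) {
    stopifnot(ncol(td) == 52L)
    td[, perm, drop = FALSE]
  } else {
    stopifnot(length(td) == 52L)
    td[perm]
  }
}
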