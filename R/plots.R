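#' Render the archetype maps of a model
#'
#' One 24-2 map per archetype, faceted in descending-RW order, each annotated
#' with its RW (%) and average TD (dB). The fill scale is a continuous dB
#' ramp clipped to the conventional display range (-41 to +7 dB by default).
#'
#' @param model an `archetype_model` fitted on the 52-point grid.
#' @param limits fill scale bounds in dB.
#' @return a ggplot object.
#' @export
plot_archetypes <- function(model, limits = c(-41, 7)) {
  stopifnot(inherits(model, "archetype_model"), model$d == 52L,
            limits[1] < limits[2])
  g <- grid242_active()
  df <- do.call(rbind, lapply(seq_len(model$k), function(j) {
    tibble::tibble(
      at = sprintf("AT%d\nRW %.1f%% | TD %.1f dB", j, model$rw[j], model$avg_td[j]),
      ord = j, x = g$x, y = g$y,
      td = pmin(pmax(model$archetypes[j, ], limits[1]), limits[2])
    )
  }))
  df$at <- stats::reorder(df$at, df$ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$td)) +
    ggplot2::geom_tile(width = 5.6, height = 5.6) +
    ggplot2::facet_wrap(~at) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = limits, name = "TD (dB)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "eccentricity (deg)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Render one visual field as a grayscale map
#'
#' @param td 52 TD values in grid active order.
#' @param title optional title.
#' @param limits fill scale bounds in dB.
#' @return a ggplot object.
#' @export
plot_field <- function(td, title = NULL, limits = c(-41, 7)) {
  stopifnot(length(td) == 52)
  g <- grid242_active()
  df <- tibble::tibble(x = g$x, y = g$y,
                       td = pmin(pmax(as.numeric(td), limits[1]), limits[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$td)) +
    ggplot2::geom_tile(width = 5.6, height = 5.6) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = limits, name = "TD (dB)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "eccentricity (deg)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Render the per-visit decomposition of one eye
#'
#' One row per visit: the TD grayscale map with a label listing the
#' meaningful archetypes and their integer percent weights; archetypes below
#' the cutoff appear in parentheses when `show_subcutoff` is set (display
#' rounding only — all logic elsewhere uses unrounded PW).
#'
#' @param decomposed_eye rows of a [decompose_table()] result for one eye.
#' @param show_subcutoff show the largest below-cutoff abnormal PW too.
#' @param limits fill scale bounds in dB.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(decomposed_eye, show_subcutoff = FALSE, limits = c(-41, 7)) {
  stopifnot(nrow(decomposed_eye) >= 1)
  k <- attr(decomposed_eye, "model_k")
  cutoff <- attr(decomposed_eye, "cutoff_pct")
  g <- grid242_active()
  X <- td_matrix(decomposed_eye)
  pw <- as.matrix(decomposed_eye[, paste0("pw_", seq_len(k))])
  panels <- lapply(seq_len(nrow(decomposed_eye)), function(i) {
    lab <- sprintf("AT%d %d%%", which(pw[i, ] >= cutoff),
                   round(pw[i, pw[i, ] >= cutoff]))
    if (show_subcutoff) {
      below <- which(pw[i, ] < cutoff & pw[i, ] >= 1)
      if (length(below) > 0) {
        b <- below[which.max(pw[i, below])]
        lab <- c(lab, sprintf("(AT%d %d%%)", b, round(pw[i, b])))
      }
    }
    tibble::tibble(
      visit = sprintf("day %d (MD %.1f dB)\n%s", decomposed_eye$visit_day[i],
                      decomposed_eye$md[i], paste(lab, collapse = "  ")),
      ord = i, x = g$x, y = g$y,
      td = pmin(pmax(X[i, ], limits[1]), limits[2])
    )
  })
  df <- do.call(rbind, panels)
  df$visit <- stats::reorder(df$visit, df$ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$td)) +
    ggplot2::geom_tile(width = 5.6, height = 5.6) +
    ggplot2::facet_wrap(~visit, nrow = 1) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = limits, name = "TD (dB)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "eccentricity (deg)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a cross-validated RSS curve
#'
#' Mean train and test RSS against the number of archetypes, with per-fold
#' test spread and the suggested flattening point marked.
#'
#' @param curve an `rss_curve`.
#' @return a ggplot object.
#' @export
plot_rss_curve <- function(curve) {
  stopifnot(inherits(curve, "rss_curve"))
  s <- curve$summary
  long <- tidyr::pivot_longer(
    s[, c("k", "mean_train_rss", "mean_test_rss")],
    cols = c("mean_train_rss", "mean_test_rss"),
    names_to = "split", values_to = "rss"
  )
  long$split <- ifelse(long$split == "mean_train_rss", "train", "test (CV)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$rss,
                                     colour = .data$split)) +
    ggplot2::geom_point(data = curve$per_fold,
                        mapping = ggplot2::aes(x = .data$k, y = .data$test_rss),
                        colour = "grey70", alpha = 0.5, size = 0.8,
                        inherit.aes = FALSE) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = curve$chosen_k, linetype = "dashed") +
    ggplot2::labs(x = "number of archetypes (k)", y = "RSS",
                  colour = NULL,
                  subtitle = paste0("suggested k = ", curve$chosen_k,
                                    if (isTRUE(curve$no_plateau)) " (no plateau)" else "")) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot group MD trajectories from a prognosis split
#'
#' Mean MD with 95% confidence intervals per visit window, one line per
#' presentation-AT1-PW group.
#'
#' @param split a `prognosis_split`.
#' @return a ggplot object.
#' @export
plot_md_trajectories <- function(split) {
  stopifnot(inherits(split, "prognosis_split"))
  ggplot2::ggplot(split$md_curve,
                  ggplot2::aes(x = .data$window, y = .data$mean_md,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "mean MD (dB)",
                  colour = "presentation AT1 PW") +
    ggplot2::theme_minimal(base_size = 10)
}
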