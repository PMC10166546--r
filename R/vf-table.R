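#' @keywords internal
td_cols <- function() sprintf("td_%02d", 1:52)

#' Extract the TD matrix from a visual-field table
#'
#' @param records a visual-field table as returned by [read_vf_table()] or
#'   [simulate_cohort()].
#' @return numeric matrix, one row per field, 52 columns in grid active order.
#' @export
td_matrix <- function(records) {
  stopifnot(all(td_cols() %in% names(records)))
  m <- as.matrix(records[, td_cols()])
  storage.mode(m) <- "double"
  unname(m)
}

meta_cols <- function() {
  c("patient_id", "eye", "visit_day", "visit_type",
    "fixation_loss_pct", "false_pos_pct", "false_neg_pct")
}

#' Read a table of visual-field records
#'
#' Reads delimited text (`.csv`) or spreadsheet (`.xlsx`, `.xls`) files.
#' Two layouts are supported:
#'
#' * `"s1"`: positional layout with 7 leading metadata columns, then exactly
#'   52 TD columns (the 54-point 24-2 grid minus the two blind-spot points,
#'   left to right in printout raster order), then a trailing MD column.
#' * `"generic"`: column-name based; requires `td_01`..`td_52` (or
#'   `td_1`..`td_52`) and `md`, with any of the metadata columns
#'   (`patient_id`, `eye`, `visit_day`, `visit_type`, `fixation_loss_pct`,
#'   `false_pos_pct`, `false_neg_pct`) picked up when present.
#'
#' Rows with non-numeric or out-of-range TD cells (outside \[-40, +15\] dB)
#' are rejected, not silently coerced; the returned table carries a parse
#' report (rows read / kept / rejected with row numbers and reasons) in
#' `attr(x, "parse_report")`.
#'
#' @param path file to read.
#' @param dialect `"s1"` (default) or `"generic"`.
#' @return A tibble with the metadata columns, `td_01`..`td_52`, and `md`.
#' @export
read_vf_table <- function(path, dialect = c("s1", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read visual-field table: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    readxl::read_excel(path, col_types = "text")
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    show_col_types = FALSE, progress = FALSE)
  }
  parse_vf_table(raw, dialect)
}

#' @keywords internal
parse_vf_table <- function(raw, dialect) {
  n_raw <- nrow(raw)
  if (dialect == "s1") {
    n_td <- ncol(raw) - 7L - 1L
    if (n_td != 52L) {
      stop("S1 layout requires 7 metadata columns, 52 TD columns and a trailing MD column: ",
           "expected 52 TD columns, found ", n_td)
    }
    td_raw <- raw[, 8:59]
    md_raw <- raw[[ncol(raw)]]
    meta <- raw[, 1:7]
    names(meta) <- meta_cols()
  } else {
    nm <- names(raw)
    td_names <- td_cols()
    if (!all(td_names %in% nm)) {
      alt <- sprintf("td_%d", 1:52)
      if (all(alt %in% nm)) {
        td_names <- alt
      } else {
        found <- sum(td_names %in% nm) + sum(sprintf("td_%d", 1:52) %in% nm)
        stop("generic layout requires TD columns td_01..td_52: expected 52 TD columns, found ",
             min(found, 52L))
      }
    }
    if (!"md" %in% nm) stop("generic layout requires an 'md' column")
    td_raw <- raw[, td_names]
    md_raw <- raw[["md"]]
    meta <- tibble::tibble(.rows = n_raw)
    for (m in meta_cols()) meta[[m]] <- if (m %in% nm) raw[[m]] else NA
  }

  suppressWarnings({
    td_num <- vapply(td_raw, function(v) as.numeric(v), numeric(n_raw))
    if (n_raw == 1L) td_num <- matrix(td_num, nrow = 1L)
    md_num <- as.numeric(md_raw)
  })
  bad_numeric <- apply(td_num, 1L, function(r) any(is.na(r))) | is.na(md_num)
  in_range <- apply(td_num, 1L, function(r) all(r >= -40 & r <= 15, na.rm = TRUE))
  reject <- bad_numeric | !in_range
  reason <- ifelse(bad_numeric, "non-numeric TD/MD cell",
                   ifelse(!in_range, "TD outside [-40, 15] dB", NA_character_))

  out <- tibble::as_tibble(meta)
  out$patient_id <- as.character(out$patient_id)
  out$eye <- as.character(out$eye)
  out$visit_day <- suppressWarnings(as.integer(as.numeric(out$visit_day)))
  out$visit_type <- as.character(out$visit_type)
  for (m in c("fixation_loss_pct", "false_pos_pct", "false_neg_pct")) {
    out[[m]] <- suppressWarnings(as.numeric(out[[m]]))
  }
  td_tbl <- tibble::as_tibble(as.data.frame(td_num))
  names(td_tbl) <- td_cols()
  out <- dplyr::bind_cols(out, td_tbl)
  out$md <- md_num
  kept <- out[!reject, , drop = FALSE]

  attr(kept, "parse_report") <- list(
    rows_read = n_raw,
    rows_kept = nrow(kept),
    rows_rejected = sum(reject),
    rejected = tibble::tibble(row = which(reject), reason = reason[reject])
  )
  kept
}

#' Write a table of visual-field records
#'
#' Writes CSV in the selected layout. The `"s1"` layout emits the 7 metadata
#' columns, the 52 TD columns, then MD — the same positional layout
#' [read_vf_table()] reads, so a write/read round trip preserves TD values
#' exactly (doubles are serialized with shortest round-trip decimal text).
#'
#' @param records visual-field table.
#' @param path output path (`.csv`).
#' @param dialect `"s1"` or `"generic"`.
#' @return `path`, invisibly.
#' @export
write_vf_table <- function(records, path, dialect = c("s1", "generic")) {
  dialect <- match.arg(dialect)
  if (tolower(tools::file_ext(path)) %in% c("xlsx", "xls")) {
    stop("write_vf_table writes CSV; use path ending in .csv")
  }
  cols <- c(meta_cols(), td_cols(), "md")
  stopifnot(all(cols %in% names(records)))
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(path)
}

#' Apply the standard reliability filter
#'
#' A field is kept iff every available reliability index is strictly below its
#' threshold (fixation losses < 33%, false positives < 15%, false negatives
#' < 15% by default). Fields with no reliability metadata cannot be verified:
#' they are kept, flagged `"unverified"` in a `reliability_status` column, and
#' counted separately in the report.
#'
#' @param records visual-field table.
#' @param fl_max,fp_max,fn_max thresholds in percent (strict `<`).
#' @return list with `kept` (includes unverified rows), `excluded`, and
#'   `report` (counts).
#' @export
reliability_filter <- function(records, fl_max = 33, fp_max = 15, fn_max = 15) {
  stopifnot(fl_max > 0, fp_max > 0, fn_max > 0)
  fl <- records$fixation_loss_pct
  fp <- records$false_pos_pct
  fn <- records$false_neg_pct
  unverified <- is.na(fl) & is.na(fp) & is.na(fn)
  fails <- (!is.na(fl) & fl >= fl_max) |
           (!is.na(fp) & fp >= fp_max) |
           (!is.na(fn) & fn >= fn_max)
  kept <- records[!fails, , drop = FALSE]
  kept$reliability_status <- ifelse(unverified[!fails], "unverified", "verified")
  list(
    kept = kept,
    excluded = records[fails, , drop = FALSE],
    report = list(
      n_input = nrow(records),
      n_kept = nrow(kept),
      n_excluded = sum(fails),
      n_unverified = sum(unverified & !fails)
    )
  )
}

#' Classify mean deviation into severity strata
#'
#' Severe: MD < -15 dB; moderate: -15 <= MD < -7 dB; mild: -7 <= MD < -2 dB;
#' normal: MD >= -2 dB. The four classes partition the MD line.
#'
#' @param md numeric vector of MD values in dB.
#' @param cutpoints named numeric vector `c(severe = -15, moderate = -7,
#'   mild = -2)`; MD below `severe` is severe, below `moderate` is moderate,
#'   below `mild` is mild, else normal.
#' @return factor with levels `severe < moderate < mild < normal`.
#' @export
#' @examples
#' classify_severity(c(-16, -15, -7.0, -2.0, 1))
classify_severity <- function(md, cutpoints = c(severe = -15, moderate = -7, mild = -2)) {
  if (any(!is.finite(md))) stop("classify_severity requires finite MD values")
  stopifnot(all(c("severe", "moderate", "mild") %in% names(cutpoints)))
  cls <- ifelse(md < cutpoints[["severe"]], "severe",
         ifelse(md < cutpoints[["moderate"]], "moderate",
         ifelse(md < cutpoints[["mild"]], "mild", "normal")))
  factor(cls, levels = c("severe", "moderate", "mild", "normal"), ordered = TRUE)
}

#' Severity summary of a cohort, by visit group
#'
#' Per visit group: n, mean and SD of MD, MD quartiles and inter-quartile
#' range, and counts/percentages per severity class.
#'
#' @param records visual-field table with `md` and the grouping column.
#' @param by grouping column name (default `"visit_type"`).
#' @return tibble, one row per group.
#' @export
cohort_summary <- function(records, by = "visit_type") {
  stopifnot(nrow(records) > 0, by %in% names(records))
  present <- unique(records[[by]])
  if (any(is.na(present))) warning("records with missing '", by, "' omitted from summary")
  records <- records[!is.na(records[[by]]), , drop = FALSE]
  records$severity <- classify_severity(records$md)
  records |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_md = mean(.data$md),
      sd_md = stats::sd(.data$md),
      q1_md = stats::quantile(.data$md, 0.25, names = FALSE),
      median_md = stats::quantile(.data$md, 0.5, names = FALSE),
      q3_md = stats::quantile(.data$md, 0.75, names = FALSE),
      iqr_md = .data$q3_md - .data$q1_md,
      n_severe = sum(.data$severity == "severe"),
      n_moderate = sum(.data$severity == "moderate"),
      n_mild = sum(.data$severity == "mild"),
      n_normal = sum(.data$severity == "normal"),
      pct_severe = 100 * .data$n_severe / .data$n,
      pct_moderate = 100 * .data$n_moderate / .data$n,
      pct_mild = 100 * .data$n_mild / .data$n,
      pct_normal = 100 * .data$n_normal / .data$n,
      .groups = "drop"
    )
}

#' Assign presentation / interim / final visit labels
#'
#' Presentation is the first exam of an eye (its `visit_day` is rebased to 0);
#' final is the last exam falling inside the final-visit window (150-365 days
#' after presentation by default, i.e. roughly five to twelve months); all
#' other exams are interim. Same-day ties are broken by row order.
#'
#' @param records visual-field table with `patient_id`, `eye`, `visit_day`.
#' @param final_window numeric length-2, days since presentation.
#' @return the table with `visit_type` filled in and `visit_day` rebased.
#' @export
assign_visit_types <- function(records, final_window = c(150, 365)) {
  stopifnot(length(final_window) == 2, final_window[1] < final_window[2])
  records$.row <- seq_len(nrow(records))
  out <- records |>
    dplyr::group_by(.data$patient_id, .data$eye) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$visit_day, df$.row), , drop = FALSE]
      df$visit_day <- df$visit_day - df$visit_day[1]
      type <- rep("interim", nrow(df))
      type[1] <- "presentation"
      in_window <- which(df$visit_day >= final_window[1] & df$visit_day <= final_window[2])
      in_window <- setdiff(in_window, 1L)
      if (length(in_window) > 0) type[max(in_window)] <- "final"
      df$visit_type <- type
      df
    }) |>
    dplyr::ungroup()
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  out
}
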