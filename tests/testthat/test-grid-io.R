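test_that("S1-layout CSV round-trips TD values exactly", {
  tb <- tiny_vf_table(5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_vf_table(tb, f, dialect = "s1")
  back <- read_vf_table(f, dialect = "s1")
  rep <- attr(back, "parse_report")
  expect_equal(rep$rows_read, 5)
  expect_equal(rep$rows_rejected, 0)
  expect_identical(td_matrix(back), td_matrix(tb))
  expect_identical(back$md, tb$md)
})

test_that("well-formed rows parse one-to-one and TD length is 52", {
  tb <- tiny_vf_table(3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_vf_table(tb, f)
  back <- read_vf_table(f)
  expect_equal(nrow(back), 3)
  expect_equal(ncol(td_matrix(back)), 52L)
})

test_that("wrong TD column count is a format error naming the count", {
  tb <- tiny_vf_table(2)
  tb$td_52 <- NULL   # 51 TD columns in the positional block
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tb, f)
  expect_error(read_vf_table(f, dialect = "s1"), "expected 52.*found 51")
})

test_that("rows with non-numeric or out-of-range TD cells are rejected with diagnostics", {
  tb <- tiny_vf_table(4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_vf_table(tb, f)
  lines <- readLines(f)
  lines[3] <- sub("^([^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*),[^,]*",
                  "\\1,not-a-number", lines[3])   # corrupt first TD cell of row 2
  writeLines(lines, f)
  back <- read_vf_table(f)
  rep <- attr(back, "parse_report")
  expect_equal(rep$rows_read, 4)
  expect_equal(rep$rows_rejected, 1)
  expect_equal(rep$rejected$row, 2)
  expect_match(rep$rejected$reason, "non-numeric")

  tb2 <- tiny_vf_table(2)
  tb2$td_10[1] <- 99  # outside [-40, 15] dB
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_vf_table(tb2, f2)
  back2 <- read_vf_table(f2)
  expect_equal(nrow(back2), 1)
  expect_match(attr(back2, "parse_report")$rejected$reason, "outside")
})

test_that("generic dialect reads by column name, s1 by position", {
  tb <- tiny_vf_table(3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_vf_table(tb, f, dialect = "generic")
  back <- read_vf_table(f, dialect = "generic")
  expect_identical(td_matrix(back), td_matrix(tb))
  expect_error(read_vf_table(withr::local_tempfile(fileext = ".csv")), "no such file")
})

test_that("reliability filter keeps strict-< passes and flags unverified", {
  tb <- tiny_vf_table(4)
  tb$fixation_loss_pct <- c(32.9, 33.0, NA, 10)
  tb$false_pos_pct     <- c(14,   5,   NA, 15)   # row 4 fails FP (15 is not < 15)
  tb$false_neg_pct     <- c(14,   5,   NA, 3)
  fr <- reliability_filter(tb)
  expect_equal(fr$report$n_excluded, 2)      # rows 2 and 4
  expect_equal(fr$report$n_unverified, 1)    # row 3
  expect_equal(fr$kept$patient_id, c("P01", "P03"))
  expect_equal(fr$kept$reliability_status, c("verified", "unverified"))
  # partition: kept + excluded = input, disjoint
  expect_equal(nrow(fr$kept) + nrow(fr$excluded), nrow(tb))
  expect_length(intersect(fr$kept$patient_id, fr$excluded$patient_id), 0)
})

test_that("severity classification uses the printed closed/open boundaries", {
  expect_equal(as.character(classify_severity(c(-16, -15, -7, -2, 0))),
               c("severe", "moderate", "mild", "normal", "normal"))
  # partition property over a dense MD grid including the exact cutpoints
  md <- c(seq(-40, 15, by = 0.25), -15, -7, -2)
  cls <- classify_severity(md)
  expect_false(any(is.na(cls)))
  expect_true(all(md[cls == "severe"] < -15))
  expect_true(all(md[cls == "moderate"] >= -15 & md[cls == "moderate"] < -7))
  expect_true(all(md[cls == "mild"] >= -7 & md[cls == "mild"] < -2))
  expect_true(all(md[cls == "normal"] >= -2))
  expect_error(classify_severity(NaN), "finite")
})

test_that("cohort summary counts strata and percentages per visit group", {
  tb <- tiny_vf_table(4, md = c(-16, -8, -3, 0))
  s <- cohort_summary(tb)
  expect_equal(nrow(s), 1)
  expect_equal(unlist(s[1, c("n_severe", "n_moderate", "n_mild", "n_normal")],
                      use.names = FALSE), c(1L, 1L, 1L, 1L))
  expect_equal(s$pct_severe + s$pct_moderate + s$pct_mild + s$pct_normal, 100)

  all_norm <- tiny_vf_table(6, md = rep(0, 6))
  s2 <- cohort_summary(all_norm)
  expect_equal(s2$pct_normal, 100)
  expect_equal(s2$n_severe + s2$n_moderate + s2$n_mild, 0L)

  tb$visit_type[2] <- NA
  expect_warning(cohort_summary(tb), "omitted")
})

test_that("visit typing: first exam presentation, last in-window exam final", {
  tb <- tiny_vf_table(5)
  tb$patient_id <- rep("P01", 5)
  tb$eye <- rep("OD", 5)
  tb$visit_day <- c(10L, 50L, 160L, 300L, 400L)  # first rebased to 0
  out <- assign_visit_types(tb)
  expect_equal(out$visit_day, c(0L, 40L, 150L, 290L, 390L))
  expect_equal(out$visit_type,
               c("presentation", "interim", "interim", "final", "interim"))
  # an eye with no exam in the window has no final visit
  tb2 <- tiny_vf_table(2)
  tb2$patient_id <- rep("P01", 2); tb2$eye <- rep("OS", 2)
  tb2$visit_day <- c(0L, 30L)
  expect_equal(assign_visit_types(tb2)$visit_type, c("presentation", "interim"))
})
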