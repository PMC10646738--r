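test_that("CSV records parse with correct totals and defaults", {
  csv <- textConnection(paste(
    "patient_id,procedure,units_crossmatched,units_transfused",
    "a,vsd,2,1", "b, VSD ,2,2", "c,TOF,2,0", sep = "\n"))
  rec <- read_records(csv)
  expect_s3_class(rec, "transfusion_records")
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$units_crossmatched), 6)
  expect_equal(sum(rec$units_transfused), 3)
  # normalization: trimmed and upper-cased
  expect_equal(rec$procedure, c("VSD", "VSD", "TOF"))
  # defaults: not excluded, issued = crossmatched, zero wastage
  expect_false(any(rec$excluded))
  expect_equal(rec$units_issued, rec$units_crossmatched)
  expect_equal(sum(rec$wastage_other), 0)
})

test_that("invalid input is rejected with informative errors", {
  bad <- data.frame(patient_id = "a", procedure = "VSD",
                    units_crossmatched = 2, units_transfused = -1)
  expect_error(validate_records(bad), "row 1")
  frac <- data.frame(patient_id = "a", procedure = "VSD",
                     units_crossmatched = 1.5, units_transfused = 1)
  expect_error(validate_records(frac), "non-integer")
  nocol <- data.frame(patient_id = "a", units_transfused = 1)
  expect_error(validate_records(nocol), "procedure")
  expect_error(validate_records(nocol), "units_crossmatched")
})

test_that("column-name dialects and procedure aliases are applied", {
  csv <- textConnection(paste(
    "mrn,op,xm,tx", "a,VENTSD,2,1", "b,TOF,2,2", sep = "\n"))
  rec <- read_records(csv,
                      dialect = c(patient_id = "mrn", procedure = "op",
                                  units_crossmatched = "xm",
                                  units_transfused = "tx"),
                      aliases = c(VENTSD = "VSD"))
  expect_equal(rec$procedure, c("VSD", "TOF"))
  expect_equal(rec$units_crossmatched, c(2L, 2L))
})

test_that("write then read is the identity on validated record lists", {
  set.seed(11)
  for (case in list(list(n = 205, w = TRUE), list(n = 12, w = FALSE))) {
    rec <- random_records(case$n, p_excluded = 0.1, with_wastage = case$w)
    path <- withr::local_tempfile(fileext = ".csv")
    write_records(rec, path)
    back <- read_records(path)
    expect_equal(as.data.frame(back), as.data.frame(rec))
  }
  # empty list -> header-only file, re-readable
  empty <- validate_records(data.frame(
    patient_id = character(), procedure = character(),
    units_crossmatched = integer(), units_transfused = integer()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_records(path)), 0L)
})

test_that("summarize_cohort matches the printed VSD cohort aggregates", {
  rec <- exact_cohort_from_histogram(c(`3` = 1, `2` = 43, `1` = 12, `0` = 8),
                                     crossmatch_per_patient = 2,
                                     procedure = "VSD")
  sm <- summarize_cohort(rec)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$n_patients, 64L)
  expect_equal(sm$n_transfused_patients, 56L)
  expect_equal(sm$units_crossmatched, 128L)
  expect_equal(sm$units_transfused, 101L)
})

test_that("summarize_cohort agrees with a naive per-row accumulation", {
  set.seed(23)
  rec <- random_records(50, p_excluded = 0.15, with_wastage = TRUE)
  sm <- summarize_cohort(rec, include_overall = TRUE)
  for (i in seq_len(nrow(sm))) {
    oracle <- naive_summary(rec, sm$procedure[i])
    expect_equal(sm$n_patients[i], oracle$n)
    expect_equal(sm$n_transfused_patients[i], oracle$ntx)
    expect_equal(sm$units_crossmatched[i], oracle$xm)
    expect_equal(sm$units_transfused[i], oracle$tx)
    expect_equal(sm$units_issued[i], oracle$issued)
    expect_equal(sm$units_wasted[i], oracle$wasted)
    hist <- sm$histogram[[i]]
    expect_equal(hist[order(names(hist))],
                 oracle$hist[order(names(oracle$hist))])
  }
})

test_that("excluded records contribute to no aggregate", {
  rec <- transfusion_records(
    patient_id = c("a", "b", "c"), procedure = "VSD",
    units_crossmatched = c(2, 2, 10), units_transfused = c(1, 1, 9),
    excluded = c(FALSE, FALSE, TRUE))
  sm <- summarize_cohort(rec)
  expect_equal(sm$n_patients, 2L)
  expect_equal(sm$units_crossmatched, 4L)
  expect_equal(sm$units_transfused, 2L)
  all_excluded <- transfusion_records(
    patient_id = "a", procedure = "VSD", units_crossmatched = 2,
    units_transfused = 1, excluded = TRUE)
  expect_equal(nrow(summarize_cohort(all_excluded)), 0L)
})

test_that("summary invariants hold on random cohorts", {
  set.seed(37)
  for (rep in 1:5) {
    rec <- random_records(80, p_excluded = 0.1, with_wastage = TRUE)
    sm <- summarize_cohort(rec, include_overall = TRUE)
    per <- sm[sm$procedure != "ALL", ]
    all_row <- sm[sm$procedure == "ALL", ]
    # per-procedure totals add up to the pooled row
    expect_equal(sum(per$n_patients), all_row$n_patients)
    expect_equal(sum(per$units_crossmatched), all_row$units_crossmatched)
    expect_equal(sum(per$units_transfused), all_row$units_transfused)
    for (i in seq_len(nrow(sm))) {
      hist <- sm$histogram[[i]]
      k <- as.numeric(names(hist))
      expect_lte(sm$n_transfused_patients[i], sm$n_patients[i])
      expect_equal(sum(hist), sm$n_patients[i])
      expect_equal(sum(k * hist), sm$units_transfused[i])
      expect_equal(sum(hist[k >= 1]), sm$n_transfused_patients[i])
    }
  }
})
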