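test_that("blood_audit assembles indices, schedule and exclusions", {
  rec <- example_cardiac_cohort()
  fit <- blood_audit(rec)
  expect_s3_class(fit, "blood_audit")
  expect_equal(fit$n_excluded, 0)
  expect_setequal(fit$indices$procedure,
                  c(names(example_cardiac_histograms()), "ALL"))
  ov <- coef(fit)
  expect_equal(unname(ov["ctr"]), 292 / 191, tolerance = 1e-12)
  expect_equal(unname(ov["ti"]), 191 / 146, tolerance = 1e-12)
  expect_equal(unname(ov["wapi"]), 0)
  expect_error(blood_audit(rec[0, ]), "no included records")
})

test_that("print and summary render the audit without error", {
  fit <- blood_audit(example_cardiac_cohort())
  out <- capture.output(print(fit))
  expect_true(any(grepl("146 patients", out)))
  out2 <- capture.output(print(summary(fit)))
  expect_true(any(grepl("MSBOS|Schedule", out2)))
  expect_true(any(grepl("ctr_inefficient", out2)))  # COA row
})

test_that("predict returns the fitted recommendation per procedure", {
  fit <- blood_audit(example_cardiac_cohort(), overrides = c(COA = 2))
  p <- predict(fit, c("vsd", "PDA", "COA"))
  expect_equal(p$recommendation, c("crossmatch", "T&S", "crossmatch"))
  expect_equal(p$recommended_units, c(2L, 0L, 2L))
  expect_warning(p2 <- predict(fit, "UNKNOWN"), "unknown procedure")
  expect_true(is.na(p2$recommended_units))
})

test_that("simulate draws cohorts of the fitted size and practice", {
  fit <- blood_audit(example_cardiac_cohort())
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  for (s in sims) {
    expect_s3_class(s, "transfusion_records")
    expect_equal(nrow(s), 146)
    expect_true(all(s$units_crossmatched == 2))
  }
  sims2 <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sims, sims2)
})

test_that("render_table styles differ only in undefined/T% conventions", {
  fit <- blood_audit(example_cardiac_cohort())
  full <- render_table(fit, "full")
  paper <- render_table(fit, "paper")
  # zero-transfusion procedures: undefined CTR in full style, 0 in paper style
  pda_full <- grep("^\\s*PDA", strsplit(full, "\n")[[1]], value = TRUE)
  pda_paper <- grep("^\\s*PDA", strsplit(paper, "\n")[[1]], value = TRUE)
  expect_match(pda_full, "undef")
  expect_false(grepl("undef", pda_paper))
  # ASD transfused every patient: T% 100 in full, fraction 1 in paper style
  asd_paper <- grep("^\\s*ASD", strsplit(paper, "\n")[[1]], value = TRUE)
  expect_match(asd_paper, "\\b1\\b")
  expect_match(grep("T_pct", full, value = TRUE), "T_pct")
})

test_that("run_audit writes its artifacts and honours the config", {
  rec_path <- withr::local_tempfile(fileext = ".csv")
  write_records(example_cardiac_cohort(), rec_path)
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(overrides = list(COA = 2), paper_style = TRUE),
                   cfg_path)
  out_dir <- withr::local_tempdir()
  expect_message(fit <- run_audit(rec_path, out_dir, config_path = cfg_path),
                 "excluded records: 0")
  for (f in c("indices.csv", "msbos.csv", "msbos.json", "report.txt"))
    expect_true(file.exists(file.path(out_dir, f)))
  tab <- read.csv(file.path(out_dir, "msbos.csv"))
  expect_equal(tab$recommended_units[tab$procedure == "COA"], 2L)
  # undefined values: empty CSV cell, null JSON
  idx_lines <- readLines(file.path(out_dir, "indices.csv"))
  expect_true(any(grepl("\"PDA\",,", idx_lines)))
  js <- jsonlite::read_json(file.path(out_dir, "msbos.json"))
  pda <- Filter(function(r) r$procedure == "PDA", js)[[1]]
  expect_null(pda$recommended_units)
  expect_match(readLines(file.path(out_dir, "report.txt"))[1], "paper")
  # an empty record file is a hard error
  empty_path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,procedure,units_crossmatched,units_transfused",
             empty_path)
  expect_error(run_audit(empty_path, out_dir), "no included records")
})

test_that("audit runs cleanly on any generated cohort (round trip)", {
  set.seed(61)
  pmfs <- list(c(`0` = 1),
               c(`0` = 0.2, `1` = 0.5, `2` = 0.3),
               c(`0` = 0.05, `1` = 0.1, `2` = 0.7, `3` = 0.15))
  for (rep in 1:5) {
    blocks <- lapply(seq_len(sample(1:3, 1)), function(i)
      cohort_block(paste0("P", i), sample(1:40, 1), pmfs[[sample(3, 1)]],
                   wastage_rate = runif(1, 0, 0.1)))
    spec <- do.call(cohort_spec, c(blocks, list(seed = rep)))
    path <- withr::local_tempfile(fileext = ".csv")
    write_records(generate_cohort(spec), path)
    out_dir <- withr::local_tempdir()
    expect_no_error(suppressMessages(run_audit(path, out_dir)))
    expect_true(file.exists(file.path(out_dir, "report.txt")))
  }
})

test_that("regenerating a report from the same inputs is byte-identical", {
  rec_path <- withr::local_tempfile(fileext = ".csv")
  write_records(example_cardiac_cohort(), rec_path)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(run_audit(rec_path, d1))
  suppressMessages(run_audit(rec_path, d2))
  for (f in c("indices.csv", "msbos.csv", "msbos.json", "report.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("plot method draws without error", {
  fit <- blood_audit(example_cardiac_cohort())
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(fit))
  grDevices::dev.off()
  expect_true(file.size(path) > 0)
})
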