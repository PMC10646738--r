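# Shared fixtures and independent oracles for the test suite.

# Random valid record table; deliberately simple so tests stay independent
# of the package's own generator.
random_records <- function(n, procedures = c("VSD", "TOF", "ASD"),
                           max_units = 3, p_excluded = 0,
                           with_wastage = FALSE) {
  transfused <- sample(0:max_units, n, replace = TRUE)
  xm <- pmax(transfused, sample(1:3, n, replace = TRUE))
  wast <- NULL
  if (with_wastage) {
    wast <- data.frame(
      wastage_expired_after_issue = rbinom(n, 1, 0.1),
      wastage_improper_storage = rbinom(n, 1, 0.05),
      wastage_late_return = rbinom(n, 1, 0.05),
      wastage_other = rbinom(n, 1, 0.02)
    )
    wast[] <- lapply(wast, function(col) pmin(col, xm))
  }
  transfusion_records(
    patient_id = sprintf("p%03d", seq_len(n)),
    procedure = sample(procedures, n, replace = TRUE),
    units_crossmatched = xm,
    units_transfused = transfused,
    excluded = runif(n) < p_excluded,
    wastage = wast
  )
}

# Naive per-row accumulation: the brute-force oracle for summarize_cohort.
naive_summary <- function(records, code) {
  acc <- list(n = 0L, ntx = 0L, xm = 0L, tx = 0L, issued = 0L, wasted = 0L,
              hist = integer())
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$excluded) next
    if (code != "ALL" && r$procedure != code) next
    acc$n <- acc$n + 1L
    if (r$units_transfused > 0) acc$ntx <- acc$ntx + 1L
    acc$xm <- acc$xm + r$units_crossmatched
    acc$tx <- acc$tx + r$units_transfused
    acc$issued <- acc$issued + r$units_issued
    acc$wasted <- acc$wasted + r$wastage_expired_after_issue +
      r$wastage_improper_storage + r$wastage_late_return + r$wastage_other
    k <- as.character(r$units_transfused)
    acc$hist[k] <- if (k %in% names(acc$hist)) acc$hist[[k]] + 1L else 1L
  }
  acc
}
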