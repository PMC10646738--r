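#' Audit blood ordering and derive an MSBOS
#'
#' The central fitting function of the package. Given patient-level
#' transfusion records it drops excluded episodes, aggregates the rest per
#' procedure, computes the five utilization indices (CTR, T\%, TI, NUP,
#' WAPI) per procedure and for the pooled cohort, flags them against the
#' efficiency thresholds, and derives the Maximum Surgical Blood Order
#' Schedule. The per-procedure transfused-unit histograms it estimates are
#' also the basis of [predict.blood_audit()] (recommended order for a
#' procedure) and [simulate.blood_audit()] (parametric-bootstrap cohorts).
#'
#' @param records a `transfusion_records` data frame (or a plain data frame
#'   with the same columns; see [read_records()]).
#' @param thresholds an [audit_thresholds()] object.
#' @param multiplier TI multiplier for the schedule, default 1 (see
#'   [round_msbos()]).
#' @param overrides named vector of per-procedure minimum crossmatch units
#'   (see [recommend_msbos()]).
#' @param strict flag CTR against the stricter 2.0 cut-off instead of 2.5.
#' @return An object of class `blood_audit`: a list with components
#'   `summaries`, `indices` (per procedure plus pooled `"ALL"` row),
#'   `msbos`, `thresholds`, `multiplier`, `strict`, `n_excluded`, `call`.
#' @seealso [run_audit()] for the file-in, files-out wrapper.
#' @export
#' @examples
#' fit <- blood_audit(example_cardiac_cohort())
#' fit
#' coef(fit)
#' predict(fit, c("VSD", "PDA"))
blood_audit <- function(records, thresholds = audit_thresholds(),
                        multiplier = 1, overrides = NULL, strict = FALSE) {
  records <- validate_records(as.data.frame(records))
  n_excluded <- sum(records$excluded)
  summaries <- summarize_cohort(records, by_procedure = TRUE,
                                include_overall = TRUE)
  if (!nrow(summaries)) stop("no included records", call. = FALSE)
  indices <- compute_indices(summaries, thresholds = thresholds,
                             strict = strict)
  msbos <- build_msbos_table(summaries, multiplier = multiplier,
                             overrides = overrides)
  structure(list(summaries = summaries, indices = indices, msbos = msbos,
                 thresholds = thresholds, multiplier = multiplier,
                 strict = strict, n_excluded = n_excluded,
                 call = match.call()),
            class = "blood_audit")
}

#' @export
print.blood_audit <- function(x, ...) {
  per <- x$summaries$procedure != "ALL"
  ov <- x$indices[x$indices$procedure == "ALL", ]
  cat("Blood utilization audit\n")
  cat(sprintf("  %d patients, %d procedures (%d excluded record%s)\n",
              sum(x$summaries$n_patients[per]), sum(per), x$n_excluded,
              if (x$n_excluded == 1) "" else "s"))
  cat(sprintf("  overall CTR %s, T%% %s, TI %s\n",
              format_index(ov$ctr), format_index(ov$t_pct),
              format_index(ov$ti)))
  nflag <- sum(x$indices$ctr_inefficient[x$indices$procedure != "ALL"])
  if (nflag > 0)
    cat(sprintf("  %d procedure(s) flagged for inefficient ordering (CTR > %g)\n",
                nflag,
                if (x$strict) x$thresholds$ctr_strict_max
                else x$thresholds$ctr_max))
  invisible(x)
}

format_index <- function(x, digits = 2) {
  ifelse(is.na(x), "undef", as.character(round_half_up(x, digits)))
}

#' @export
summary.blood_audit <- function(object, ...) {
  structure(list(fit = object), class = "summary.blood_audit")
}

#' @export
print.summary.blood_audit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-procedure indices:\n")
  idx <- x$fit$indices
  disp <- data.frame(procedure = idx$procedure,
                     ctr = round_half_up(idx$ctr, 2),
                     t_pct = round_half_up(idx$t_pct, 1),
                     ti = round_half_up(idx$ti, 2),
                     nup = round_half_up(idx$nup, 3),
                     wapi = round_half_up(idx$wapi, 2),
                     flags = apply(idx[, c("ctr_inefficient", "t_low",
                                           "ti_low")], 1, function(fl)
                       paste(names(fl)[fl], collapse = ",")))
  print(disp, row.names = FALSE)
  cat("\n")
  print(x$fit$msbos)
  invisible(x)
}

#' Overall utilization indices of a fitted audit
#'
#' @param object a [blood_audit()] fit.
#' @param ... unused.
#' @return Named numeric vector `c(ctr, t_pct, ti, nup, wapi)` for the
#'   pooled cohort (`NA` where undefined).
#' @export
coef.blood_audit <- function(object, ...) {
  ov <- object$indices[object$indices$procedure == "ALL", ]
  c(ctr = ov$ctr, t_pct = ov$t_pct, ti = ov$ti, nup = ov$nup,
    wapi = ov$wapi)
}

#' Recommended preoperative order for procedures
#'
#' Looks up the fitted schedule: the number of units to crossmatch, or 0
#' with recommendation `"T&S"` when a type and screen suffices.
#'
#' @param object a [blood_audit()] fit.
#' @param newdata character vector of procedure codes (normalized as in
#'   [transfusion_records()]). Defaults to every fitted procedure.
#' @param ... unused.
#' @return A data frame with columns `procedure`, `recommendation`,
#'   `recommended_units` (0 for T&S rows; `NA` for unknown procedures,
#'   with a warning).
#' @export
predict.blood_audit <- function(object, newdata = NULL, ...) {
  tab <- object$msbos
  if (is.null(newdata)) newdata <- tab$procedure
  newdata <- normalize_procedure(newdata)
  i <- match(newdata, tab$procedure)
  if (anyNA(i))
    warning("unknown procedure(s): ",
            paste(unique(newdata[is.na(i)]), collapse = ", "), call. = FALSE)
  data.frame(
    procedure = newdata,
    recommendation = tab$recommendation[i],
    recommended_units = ifelse(tab$recommendation[i] == "T&S", 0L,
                               tab$recommended_units[i]),
    stringsAsFactors = FALSE
  )
}

#' Simulate cohorts from a fitted audit
#'
#' Parametric bootstrap: treats each procedure's empirical transfused-unit
#' histogram as a categorical distribution and draws new cohorts of the
#' same size and crossmatch practice. Crossmatch units per patient are set
#' to the procedure's observed mean rounded to the nearest integer (exact
#' under a fixed-units-per-patient practice).
#'
#' @param object a [blood_audit()] fit.
#' @param nsim number of cohorts to draw.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param ... unused.
#' @return A list of `nsim` `transfusion_records` data frames.
#' @importFrom stats simulate
#' @export
simulate.blood_audit <- function(object, nsim = 1, seed = NULL, ...) {
  per <- object$summaries[object$summaries$procedure != "ALL", ,
                          drop = FALSE]
  blocks <- lapply(seq_len(nrow(per)), function(i) {
    hist <- per$histogram[[i]]
    cohort_block(per$procedure[i], per$n_patients[i],
                 transfusion_pmf = hist / sum(hist),
                 crossmatch_per_patient =
                   round(per$units_crossmatched[i] / per$n_patients[i]))
  })
  spec <- cohort_spec(blocks)
  with_seed(seed, lapply(seq_len(nsim), function(k) generate_cohort(spec,
                                                                    seed = NULL)))
}

#' Plot a fitted blood audit
#'
#' Bar chart of per-procedure CTR with the efficiency cut-off drawn as a
#' dashed line; procedures with undefined CTR (no transfusions) are shown
#' as zero-height bars and marked.
#'
#' @param x a [blood_audit()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.blood_audit <- function(x, ...) {
  idx <- x$indices[x$indices$procedure != "ALL", ]
  h <- ifelse(is.na(idx$ctr), 0, idx$ctr)
  cut <- if (x$strict) x$thresholds$ctr_strict_max else x$thresholds$ctr_max
  bp <- graphics::barplot(h, names.arg = idx$procedure, las = 2,
                          ylab = "CTR",
                          ylim = c(0, max(h, cut) * 1.15),
                          main = "Cross-match-to-transfusion ratio", ...)
  graphics::abline(h = cut, lty = 2)
  if (any(is.na(idx$ctr)))
    graphics::text(bp[is.na(idx$ctr)], 0.05, "undef", srt = 90, adj = 0,
                   cex = 0.8)
  invisible(x)
}
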