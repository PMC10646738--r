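#' Blood-ordering efficiency thresholds
#'
#' The conventional efficiency cut-offs used in blood utilization review:
#' a cross-match-to-transfusion ratio (CTR) of 2.5 or below indicates
#' efficient ordering (with a stricter school of practice using 2.0);
#' a transfusion probability (T\%) of at least 30\% indicates blood was
#' genuinely needed; a transfusion index (TI) of at least 0.5 units per
#' patient indicates meaningful utilization.
#'
#' @param ctr_max CTR above which ordering is flagged inefficient
#'   (default 2.5).
#' @param ctr_strict_max stricter CTR cut-off used when flagging in strict
#'   mode (default 2.0); must not exceed `ctr_max`.
#' @param t_pct_min minimum transfusion probability, in percent
#'   (default 30).
#' @param ti_min minimum transfusion index, units per crossmatched patient
#'   (default 0.5).
#' @return A list of class `audit_thresholds`.
#' @export
audit_thresholds <- function(ctr_max = 2.5, ctr_strict_max = 2.0,
                             t_pct_min = 30, ti_min = 0.5) {
  vals <- c(ctr_max = ctr_max, ctr_strict_max = ctr_strict_max,
            t_pct_min = t_pct_min, ti_min = ti_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be positive and finite", call. = FALSE)
  if (ctr_strict_max > ctr_max)
    stop("ctr_strict_max must not exceed ctr_max", call. = FALSE)
  structure(as.list(vals), class = "audit_thresholds")
}

.check_counts <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("'%s' must be non-negative and finite", nm), call. = FALSE)
  }
  invisible(NULL)
}

#' Cross-match-to-transfusion ratio (CTR)
#'
#' CTR = units crossmatched / units transfused. A value near 1 indicates
#' efficient ordering. When units were crossmatched but none transfused the
#' ratio is undefined (returned as `NA`); when both counts are zero the
#' ratio is 0 by convention.
#'
#' @param units_crossmatched,units_transfused non-negative unit counts
#'   (vectorized).
#' @return Numeric ratio, `NA` where undefined.
#' @export
#' @examples
#' compute_ctr(410, 262)  # 1.56 overall
#' compute_ctr(58, 30)    # 1.93
compute_ctr <- function(units_crossmatched, units_transfused) {
  .check_counts(units_crossmatched = units_crossmatched,
                units_transfused = units_transfused)
  out <- ifelse(units_transfused > 0, units_crossmatched / units_transfused,
                ifelse(units_crossmatched == 0, 0, NA_real_))
  as.numeric(out)
}

#' Transfusion probability (T\%)
#'
#' T\% = 100 x (patients transfused / patients crossmatched): the
#' percentage of crossmatched patients who actually received blood.
#'
#' @param n_transfused_patients,n_patients non-negative patient counts
#'   (vectorized); `n_transfused_patients` must not exceed `n_patients`.
#' @return Percentage in \[0, 100\]; `NA` where `n_patients` is zero.
#' @export
#' @examples
#' compute_t_pct(157, 205)  # 76.6
compute_t_pct <- function(n_transfused_patients, n_patients) {
  .check_counts(n_transfused_patients = n_transfused_patients,
                n_patients = n_patients)
  if (any(n_transfused_patients > n_patients))
    stop("n_transfused_patients must not exceed n_patients", call. = FALSE)
  as.numeric(ifelse(n_patients > 0,
                    100 * n_transfused_patients / n_patients, NA_real_))
}

#' Transfusion index (TI)
#'
#' TI = units transfused / patients crossmatched: the mean number of units
#' transfused per crossmatched patient. The MSBOS derived here equals the
#' ceiling of this quantity per procedure.
#'
#' @param units_transfused non-negative unit count (vectorized).
#' @param n_patients non-negative patient count (vectorized).
#' @return Mean units per patient; `NA` where `n_patients` is zero.
#' @export
#' @examples
#' compute_ti(262, 205)  # 1.28
compute_ti <- function(units_transfused, n_patients) {
  .check_counts(units_transfused = units_transfused, n_patients = n_patients)
  as.numeric(ifelse(n_patients > 0, units_transfused / n_patients, NA_real_))
}

#' Non-usage probability (NUP)
#'
#' NUP = (units crossmatched - units transfused) / units crossmatched: the
#' fraction of requested units never transfused. Algebraically
#' NUP = 1 - 1/CTR whenever any unit was transfused. High values indicate
#' inefficient ordering.
#'
#' @param units_crossmatched,units_transfused non-negative unit counts
#'   (vectorized). Transfused counts exceeding crossmatched counts are
#'   clamped with a warning.
#' @return Fraction in \[0, 1\]; `NA` where nothing was crossmatched.
#' @export
#' @examples
#' compute_nup(410, 262)  # 0.361
compute_nup <- function(units_crossmatched, units_transfused) {
  .check_counts(units_crossmatched = units_crossmatched,
                units_transfused = units_transfused)
  over <- units_transfused > units_crossmatched
  if (any(over)) {
    warning("units_transfused exceeds units_crossmatched; clamping",
            call. = FALSE)
    units_transfused <- pmin(units_transfused, units_crossmatched)
  }
  as.numeric(ifelse(units_crossmatched > 0,
                    (units_crossmatched - units_transfused) /
                      units_crossmatched,
                    NA_real_))
}

#' Wastage as a percentage of issue (WAPI)
#'
#' WAPI = 100 x (wasted units / issued units), with wastage summed over the
#' four standard categories (expired after issue, improper
#' storage/transport, late return, other).
#'
#' @param units_wasted,units_issued non-negative unit counts (vectorized);
#'   wasted must not exceed issued.
#' @return Percentage in \[0, 100\]; `NA` where nothing was issued.
#' @export
compute_wapi <- function(units_wasted, units_issued) {
  .check_counts(units_wasted = units_wasted, units_issued = units_issued)
  if (any(units_wasted > units_issued))
    stop("units_wasted must not exceed units_issued", call. = FALSE)
  as.numeric(ifelse(units_issued > 0,
                    100 * units_wasted / units_issued, NA_real_))
}

#' Flag utilization indices against efficiency thresholds
#'
#' Applies the standard cut-offs: `ctr_inefficient` when CTR is defined and
#' exceeds the configured maximum (2.5 by default; 2.0 in strict mode),
#' `t_low` when T\% falls below its minimum (30\%), `ti_low` when TI falls
#' below its minimum (0.5). Undefined (`NA`) indices are never flagged.
#'
#' @param ctr,t_pct,ti numeric index values (vectorized; `NA` allowed).
#' @param thresholds an [audit_thresholds()] object.
#' @param strict use the stricter CTR cut-off (`ctr_strict_max`).
#' @return A data frame of logicals with columns `ctr_inefficient`,
#'   `t_low`, `ti_low`.
#' @export
#' @examples
#' flag_indices(ctr = 2.6, t_pct = 69, ti = 0.77)  # CTR flagged
flag_indices <- function(ctr, t_pct, ti, thresholds = audit_thresholds(),
                         strict = FALSE) {
  stopifnot(inherits(thresholds, "audit_thresholds"))
  cut <- if (strict) thresholds$ctr_strict_max else thresholds$ctr_max
  data.frame(
    ctr_inefficient = !is.na(ctr) & ctr > cut,
    t_low = !is.na(t_pct) & t_pct < thresholds$t_pct_min,
    ti_low = !is.na(ti) & ti < thresholds$ti_min
  )
}

#' Compute all utilization indices for procedure summaries
#'
#' Computes CTR, T\%, TI, NUP and WAPI for every row of a
#' [summarize_cohort()] result and attaches threshold flags.
#'
#' @param summaries a `procedure_summary` data frame.
#' @param thresholds an [audit_thresholds()] object.
#' @param strict use the stricter CTR cut-off when flagging.
#' @return A `data.frame` of class `utilization_indices` with one row per
#'   summary row; undefined indices are `NA`.
#' @export
compute_indices <- function(summaries, thresholds = audit_thresholds(),
                            strict = FALSE) {
  stopifnot(inherits(summaries, "procedure_summary"))
  out <- data.frame(
    procedure = summaries$procedure,
    ctr = compute_ctr(summaries$units_crossmatched,
                      summaries$units_transfused),
    t_pct = compute_t_pct(summaries$n_transfused_patients,
                          summaries$n_patients),
    ti = compute_ti(summaries$units_transfused, summaries$n_patients),
    nup = compute_nup(summaries$units_crossmatched,
                      summaries$units_transfused),
    wapi = compute_wapi(summaries$units_wasted, summaries$units_issued),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, flag_indices(out$ctr, out$t_pct, out$ti,
                                 thresholds = thresholds, strict = strict))
  class(out) <- c("utilization_indices", "data.frame")
  out
}

# Round-half-up at `digits` decimal places, the convention of printed audit
# tables (base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
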