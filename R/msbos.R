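#' Raw MSBOS: mean transfused units per patient from a unit-count histogram
#'
#' The raw schedule value for a procedure is the weighted mean of
#' transfused-unit counts, sum(k * histogram\[k\]) / n_patients — identical
#' to the transfusion index computed on the same cohort.
#'
#' @param histogram named integer vector mapping transfused-unit count to
#'   number of patients, e.g. `c("3" = 1, "2" = 43, "1" = 12, "0" = 8)`.
#' @param n_patients total number of patients; must equal
#'   `sum(histogram)`.
#' @return Mean units per patient (non-negative numeric scalar).
#' @export
#' @examples
#' raw_msbos(c(`3` = 1, `2` = 43, `1` = 12, `0` = 8), 64)  # 1.578
raw_msbos <- function(histogram, n_patients = sum(histogram)) {
  if (!length(histogram))
    stop("histogram must be non-empty", call. = FALSE)
  counts <- as.numeric(names(histogram))
  if (anyNA(counts) || any(counts < 0) || any(counts %% 1 != 0))
    stop("histogram names must be non-negative integer unit counts",
         call. = FALSE)
  if (any(histogram < 0) || any(histogram %% 1 != 0))
    stop("histogram values must be non-negative integer patient counts",
         call. = FALSE)
  if (n_patients <= 0)
    stop("n_patients must be positive", call. = FALSE)
  if (sum(histogram) != n_patients)
    stop("histogram patient counts must sum to n_patients", call. = FALSE)
  sum(counts * histogram) / n_patients
}

#' Rounded MSBOS: ceiling of the raw value times a multiplier
#'
#' Schedules round the raw mean *up* to the next whole unit so that the
#' order covers the typical demand: `ceiling(raw * multiplier)`. Exact
#' integers map to themselves. The multiplier defaults to 1 (schedule
#' based on TI directly); sites following the 1.5 x TI convention can set
#' `multiplier = 1.5`.
#'
#' @param raw non-negative raw schedule value (vectorized).
#' @param multiplier positive TI multiplier, default 1.
#' @return Non-negative integer unit count(s).
#' @export
#' @examples
#' round_msbos(1.03)  # 2
#' round_msbos(0.77)  # 1
#' round_msbos(2.0)   # 2
round_msbos <- function(raw, multiplier = 1) {
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("multiplier must be positive", call. = FALSE)
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("raw must be non-negative and finite", call. = FALSE)
  # tiny guard so floating noise cannot push an exact integer up a unit
  as.integer(ceiling(raw * multiplier - 1e-9))
}

#' Crossmatch versus type-and-screen recommendation
#'
#' A rounded schedule of zero units means no blood need be reserved:
#' a type and screen (`"T&S"`) suffices. One or more units means
#' preoperative crossmatch of that many units. A per-procedure override map
#' can raise the crossmatch floor where clinical judgement demands more
#' than the computed value (overrides never turn a T&S into a crossmatch,
#' and are applied only when configured).
#'
#' @param rounded non-negative integer unit count(s) from [round_msbos()].
#' @param procedure procedure code(s), used to look up overrides; optional
#'   when `overrides` is `NULL`.
#' @param overrides named numeric vector of per-procedure minimum
#'   crossmatch units, e.g. `c(COA = 2)`.
#' @return A data frame with columns `recommendation` (`"crossmatch"` or
#'   `"T&S"`) and `recommended_units` (integer; `NA` for T&S rows).
#' @export
#' @examples
#' recommend_msbos(c(2, 0, 1), c("VSD", "PDA", "COA"), overrides = c(COA = 2))
recommend_msbos <- function(rounded, procedure = NULL, overrides = NULL) {
  if (any(rounded < 0) || any(rounded %% 1 != 0))
    stop("rounded must be non-negative integers", call. = FALSE)
  rounded <- as.integer(rounded)
  units <- rounded
  if (!is.null(overrides) && !is.null(procedure)) {
    names(overrides) <- normalize_procedure(names(overrides))
    hit <- rounded >= 1L & procedure %in% names(overrides)
    units[hit] <- pmax(rounded[hit],
                       as.integer(overrides[procedure[hit]]))
  }
  data.frame(
    recommendation = ifelse(rounded == 0L, "T&S", "crossmatch"),
    recommended_units = ifelse(rounded == 0L, NA_integer_, units),
    stringsAsFactors = FALSE
  )
}

#' Build a Maximum Surgical Blood Order Schedule table
#'
#' For each procedure summary, computes the raw schedule value (mean units
#' per patient), rounds it up, and attaches the crossmatch /
#' type-and-screen recommendation. Rows are ordered by decreasing number of
#' patients; output is a pure function of its inputs.
#'
#' @param summaries a [summarize_cohort()] result. Any pooled `"ALL"` row
#'   is dropped — a schedule is per procedure.
#' @param multiplier TI multiplier, default 1 (see [round_msbos()]).
#' @param overrides per-procedure minimum crossmatch units (see
#'   [recommend_msbos()]).
#' @return A `data.frame` of class `msbos_table` with columns `procedure`,
#'   `n_patients`, `raw_msbos`, `rounded_msbos`, `recommendation`,
#'   `recommended_units`, `multiplier`.
#' @export
#' @examples
#' rec <- example_cardiac_cohort()
#' build_msbos_table(summarize_cohort(rec))
build_msbos_table <- function(summaries, multiplier = 1, overrides = NULL) {
  stopifnot(inherits(summaries, "procedure_summary"))
  summaries <- summaries[summaries$procedure != "ALL", , drop = FALSE]
  if (!nrow(summaries))
    stop("no per-procedure summaries to schedule", call. = FALSE)
  raw <- vapply(seq_len(nrow(summaries)), function(i) {
    tryCatch(
      raw_msbos(summaries$histogram[[i]], summaries$n_patients[i]),
      error = function(e) stop(sprintf("procedure %s: %s",
                                       summaries$procedure[i],
                                       conditionMessage(e)), call. = FALSE)
    )
  }, numeric(1))
  rounded <- round_msbos(raw, multiplier)
  rec <- recommend_msbos(rounded, summaries$procedure, overrides)
  out <- data.frame(
    procedure = summaries$procedure,
    n_patients = summaries$n_patients,
    raw_msbos = raw,
    rounded_msbos = rounded,
    recommendation = rec$recommendation,
    recommended_units = rec$recommended_units,
    multiplier = multiplier,
    stringsAsFactors = FALSE
  )
  ord <- order(-out$n_patients, out$procedure)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msbos_table", "data.frame")
  out
}

#' @export
print.msbos_table <- function(x, digits = 2, ...) {
  cat("Maximum Surgical Blood Order Schedule",
      sprintf("(multiplier %g)\n", x$multiplier[1]))
  disp <- data.frame(
    procedure = x$procedure,
    patients = x$n_patients,
    raw = round_half_up(x$raw_msbos, digits),
    rounded = x$rounded_msbos,
    recommended = ifelse(x$recommendation == "T&S", "T&S",
                         as.character(x$recommended_units)),
    stringsAsFactors = FALSE
  )
  print(disp, row.names = FALSE, ...)
  invisible(x)
}
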