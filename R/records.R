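#' @keywords internal
"_PACKAGE"

# Wastage categories recognised in transfusion records. These are the four
# standard areas blood banks track: units expired after issue, units wasted
# through improper transport/storage, non-stored units returned late
# (> 30 minutes from issue), and everything else (breakage, contamination,
# tube-system failure, ...).
WASTAGE_CATEGORIES <- c("expired_after_issue", "improper_storage",
                        "late_return", "other")

.wastage_cols <- function() paste0("wastage_", WASTAGE_CATEGORIES)

#' Construct a validated set of transfusion records
#'
#' A transfusion record describes one patient-procedure episode: how many
#' red-blood-cell (RBC) units were crossmatched (reserved) for the patient
#' preoperatively, how many were actually transfused, optionally how many
#' were issued, and any wastage events. Records flagged `excluded` (for
#' example massive transfusion or a transfusion reaction) are retained in
#' the table but contribute to no aggregate.
#'
#' @param patient_id character vector of opaque patient identifiers.
#'   Repeated identifiers are allowed and treated as distinct episodes.
#' @param procedure character vector of procedure codes (e.g. `"VSD"`,
#'   `"TOF"`). Codes are normalized by trimming whitespace and upper-casing.
#' @param units_crossmatched,units_transfused non-negative integer counts
#'   of whole RBC units.
#' @param excluded logical; defaults to `FALSE`.
#' @param units_issued non-negative integer count of units issued from the
#'   blood bank. Defaults to `units_crossmatched` when not recorded, so that
#'   wastage-as-percentage-of-issue is computable from minimal input.
#' @param wastage a data frame with one column per wastage category
#'   (`wastage_expired_after_issue`, `wastage_improper_storage`,
#'   `wastage_late_return`, `wastage_other`), or `NULL` for no wastage.
#' @param aliases optional named character vector folding procedure-code
#'   synonyms, e.g. `c(VENTSD = "VSD")`.
#' @return A `data.frame` of class `transfusion_records`.
#' @seealso [read_records()], [summarize_cohort()], [blood_audit()]
#' @export
#' @examples
#' transfusion_records(
#'   patient_id = c("p1", "p2", "p3"),
#'   procedure = c("VSD", "VSD", "TOF"),
#'   units_crossmatched = c(2, 2, 2),
#'   units_transfused = c(1, 2, 0)
#' )
transfusion_records <- function(patient_id, procedure,
                                units_crossmatched, units_transfused,
                                excluded = FALSE, units_issued = NULL,
                                wastage = NULL, aliases = NULL) {
  n <- length(patient_id)
  procedure <- rep_len(normalize_procedure(procedure, aliases), n)
  excluded <- rep_len(as.logical(excluded), n)
  if (is.null(units_issued)) units_issued <- units_crossmatched

  df <- data.frame(
    patient_id = as.character(patient_id),
    procedure = procedure,
    units_crossmatched = units_crossmatched,
    units_transfused = units_transfused,
    units_issued = units_issued,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  wcols <- .wastage_cols()
  if (is.null(wastage)) {
    for (w in wcols) df[[w]] <- 0L
  } else {
    missing_w <- setdiff(wcols, names(wastage))
    for (w in missing_w) wastage[[w]] <- 0L
    for (w in wcols) df[[w]] <- wastage[[w]]
  }
  validate_records(df)
}

#' @rdname transfusion_records
#' @param x a data frame holding record columns.
#' @export
validate_records <- function(x) {
  required <- c("patient_id", "procedure", "units_crossmatched",
                "units_transfused")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(x$units_issued)) x$units_issued <- x$units_crossmatched
  if (is.null(x$excluded)) x$excluded <- rep(FALSE, nrow(x))
  for (w in .wastage_cols()) if (is.null(x[[w]])) x[[w]] <- rep(0L, nrow(x))

  count_cols <- c("units_crossmatched", "units_transfused", "units_issued",
                  .wastage_cols())
  for (cc in count_cols) {
    v <- x[[cc]]
    bad <- which(is.na(v) | !is.finite(as.numeric(v)) |
                   as.numeric(v) < 0 | as.numeric(v) %% 1 != 0)
    if (length(bad))
      stop(sprintf("column '%s': negative or non-integer unit count at row %s",
                   cc, paste(bad, collapse = ", ")), call. = FALSE)
    x[[cc]] <- as.integer(v)
  }
  x$excluded <- as.logical(x$excluded)
  if (anyNA(x$excluded))
    stop("column 'excluded' contains values not interpretable as logical",
         call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  x$procedure <- normalize_procedure(x$procedure)
  keep <- c("patient_id", "procedure", "units_crossmatched",
            "units_transfused", "units_issued", "excluded", .wastage_cols())
  x <- x[, keep]
  rownames(x) <- NULL
  class(x) <- c("transfusion_records", "data.frame")
  x
}

normalize_procedure <- function(x, aliases = NULL) {
  x <- toupper(trimws(as.character(x)))
  if (!is.null(aliases)) {
    names(aliases) <- toupper(trimws(names(aliases)))
    aliases[] <- toupper(trimws(aliases))
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  x
}

#' Read transfusion records from a delimited file
#'
#' Expects a header row naming at least `patient_id`, `procedure`,
#' `units_crossmatched` and `units_transfused` (possibly under site-specific
#' names remapped via `dialect`). Optional columns: `units_issued`,
#' `excluded`, and the four `wastage_*` columns. Unknown columns are
#' ignored.
#'
#' @param source path to a CSV file, or a connection.
#' @param dialect named character vector mapping canonical column names to
#'   the names used in the file, e.g.
#'   `c(patient_id = "mrn", units_crossmatched = "xm_units")`.
#' @param aliases optional procedure-code alias map (see
#'   [transfusion_records()]).
#' @param sep field separator, default comma.
#' @return A `transfusion_records` data frame.
#' @export
read_records <- function(source, dialect = NULL, aliases = NULL, sep = ",") {
  df <- utils::read.csv(source, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      site <- dialect[[canon]]
      if (site %in% names(df)) names(df)[names(df) == site] <- canon
    }
  }
  if (!is.null(df$excluded) && is.character(df$excluded))
    df$excluded <- toupper(trimws(df$excluded)) %in% c("TRUE", "T", "1", "YES")
  rec <- validate_records(df)
  if (!is.null(aliases)) rec$procedure <- normalize_procedure(rec$procedure, aliases)
  rec
}

#' Write transfusion records to a delimited file
#'
#' Emits a UTF-8 CSV with a header row re-readable by [read_records()];
#' writing then reading is the identity on validated record tables.
#'
#' @param records a `transfusion_records` data frame (or coercible).
#' @param sink path or connection to write to.
#' @return `sink`, invisibly.
#' @export
write_records <- function(records, sink) {
  records <- validate_records(as.data.frame(records))
  utils::write.csv(records, sink, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(sink)
}

#' Aggregate transfusion records into per-procedure summaries
#'
#' Drops excluded records and computes, per procedure (and optionally for
#' the pooled cohort under procedure code `"ALL"`): the number of
#' crossmatched patients, the number transfused (at least one unit), the
#' summed crossmatched / transfused / issued / wasted units, and the
#' histogram of transfused-unit counts per patient. The histogram is the
#' quantity the MSBOS calculation consumes.
#'
#' @param records a `transfusion_records` data frame.
#' @param by_procedure if `TRUE` (default) one summary row per distinct
#'   procedure; if `FALSE` only the pooled `"ALL"` row.
#' @param include_overall append the pooled `"ALL"` row after the
#'   per-procedure rows (default `FALSE`; ignored when
#'   `by_procedure = FALSE`).
#' @return A `data.frame` of class `procedure_summary` with a list column
#'   `histogram` (named integer vectors, names = transfused-unit counts).
#'   Rows are ordered by decreasing number of patients. Empty included set
#'   gives a zero-row summary.
#' @export
#' @examples
#' rec <- exact_cohort_from_histogram(c(`3` = 1, `2` = 43, `1` = 12, `0` = 8),
#'                                    crossmatch_per_patient = 2,
#'                                    procedure = "VSD")
#' summarize_cohort(rec)
summarize_cohort <- function(records, by_procedure = TRUE,
                             include_overall = FALSE) {
  records <- validate_records(as.data.frame(records))
  inc <- records[!records$excluded, , drop = FALSE]

  one <- function(sub, code) {
    hist_tab <- table(sub$units_transfused)
    hist <- stats::setNames(as.integer(hist_tab), names(hist_tab))
    data.frame(
      procedure = code,
      n_patients = nrow(sub),
      n_transfused_patients = sum(sub$units_transfused > 0),
      units_crossmatched = sum(sub$units_crossmatched),
      units_transfused = sum(sub$units_transfused),
      units_issued = sum(sub$units_issued),
      units_wasted = sum(as.matrix(sub[, .wastage_cols()])),
      histogram = I(list(hist)),
      stringsAsFactors = FALSE
    )
  }

  rows <- list()
  if (by_procedure && nrow(inc) > 0) {
    for (code in unique(inc$procedure))
      rows[[code]] <- one(inc[inc$procedure == code, , drop = FALSE], code)
  }
  if ((!by_procedure || include_overall) && nrow(inc) > 0)
    rows[["ALL"]] <- one(inc, "ALL")

  if (!length(rows)) {
    out <- data.frame(procedure = character(), n_patients = integer(),
                      n_transfused_patients = integer(),
                      units_crossmatched = integer(),
                      units_transfused = integer(), units_issued = integer(),
                      units_wasted = integer(), stringsAsFactors = FALSE)
    out$histogram <- list()
  } else {
    out <- do.call(rbind, rows)
    per <- out$procedure != "ALL"
    ord <- order(-out$n_patients[per], out$procedure[per])
    out <- rbind(out[per, , drop = FALSE][ord, , drop = FALSE],
                 out[!per, , drop = FALSE])
  }
  rownames(out) <- NULL
  class(out) <- c("procedure_summary", "data.frame")
  out
}
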