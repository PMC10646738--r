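#' Render an audit as a plain-text table
#'
#' Produces a text report joining the per-procedure indices and the
#' schedule, in one of two conventions. Style `"full"` renders undefined
#' indices as `"undef"` and T\% as a percentage. Style `"paper"` follows
#' the conventions of printed audit tables: a zero-transfusion procedure's
#' CTR is printed as 0 rather than undefined, and T\% is printed as a
#' fraction of 1.
#'
#' @param fit a [blood_audit()] object.
#' @param style `"full"` (default) or `"paper"`.
#' @return A character scalar (the rendered table, newline-separated).
#' @export
#' @examples
#' cat(render_table(blood_audit(example_cardiac_cohort()), style = "paper"))
render_table <- function(fit, style = c("full", "paper")) {
  style <- match.arg(style)
  stopifnot(inherits(fit, "blood_audit"))
  idx <- fit$indices
  sm <- fit$summaries
  tab <- fit$msbos
  i <- match(idx$procedure, tab$procedure)

  fmt <- function(x, digits = 2) {
    ifelse(is.na(x), if (style == "paper") "0" else "undef",
           as.character(round_half_up(x, digits)))
  }
  t_col <- if (style == "paper") fmt(idx$t_pct / 100, 2) else fmt(idx$t_pct, 1)

  disp <- data.frame(
    procedure = idx$procedure,
    patients = sm$n_patients,
    transfused_patients = sm$n_transfused_patients,
    units_xm = sm$units_crossmatched,
    units_tx = sm$units_transfused,
    CTR = fmt(idx$ctr),
    `T` = t_col,
    TI = fmt(idx$ti),
    raw_msbos = ifelse(is.na(i), "", fmt(tab$raw_msbos[i])),
    rounded = ifelse(is.na(i), "", as.character(tab$rounded_msbos[i])),
    recommended = ifelse(is.na(i), "",
                         ifelse(tab$recommendation[i] == "T&S", "T&S",
                                as.character(tab$recommended_units[i]))),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(disp)[names(disp) == "T"] <- if (style == "paper") "T_frac" else "T_pct"
  header <- sprintf("Blood utilization audit (%s style, CTR cut-off %g)",
                    style,
                    if (fit$strict) fit$thresholds$ctr_strict_max
                    else fit$thresholds$ctr_max)
  body <- utils::capture.output(print(disp, row.names = FALSE))
  paste(c(header, body, ""), collapse = "\n")
}

read_audit_config <- function(path) {
  if (is.null(path)) return(list())
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format: ", ext, call. = FALSE))
  if (!is.null(cfg$column_map)) cfg$column_map <- unlist(cfg$column_map)
  if (!is.null(cfg$procedure_aliases))
    cfg$procedure_aliases <- unlist(cfg$procedure_aliases)
  if (!is.null(cfg$overrides)) cfg$overrides <- unlist(cfg$overrides)
  cfg
}

#' Run a file-in, files-out blood-ordering audit
#'
#' Reads patient-level records (and an optional YAML/JSON config), fits
#' [blood_audit()], and writes four artifacts into `output_dir`:
#' `indices.csv` (per-procedure and pooled indices with flags),
#' `msbos.csv` and `msbos.json` (the schedule), and `report.txt` (the
#' rendered table). Undefined indices are serialized as empty CSV cells,
#' JSON `null`, and `"undef"` in text (unless `paper_style`). The count of
#' excluded records and any threshold flags are reported via `message()`.
#'
#' Config keys (all optional): `column_map` (canonical -> site column
#' names), `procedure_aliases`, `thresholds` (any of `ctr_max`,
#' `ctr_strict_max`, `t_pct_min`, `ti_min`), `multiplier`, `overrides`
#' (per-procedure minimum units), `paper_style`. Arguments given directly
#' to `run_audit()` override the config.
#'
#' @param records_path CSV of transfusion records (see [read_records()]).
#' @param output_dir directory for the artifacts; created if absent.
#' @param config_path optional YAML or JSON config file.
#' @param paper_style render `report.txt` in the printed-table convention
#'   (see [render_table()]).
#' @param multiplier optional TI multiplier overriding the config.
#' @param strict flag CTR against the stricter cut-off.
#' @return The fitted `blood_audit`, invisibly.
#' @export
run_audit <- function(records_path, output_dir, config_path = NULL,
                      paper_style = NULL, multiplier = NULL,
                      strict = FALSE) {
  cfg <- read_audit_config(config_path)
  records <- read_records(records_path, dialect = cfg$column_map,
                          aliases = cfg$procedure_aliases)
  if (!any(!records$excluded)) stop("no included records", call. = FALSE)

  thr_args <- cfg$thresholds
  thresholds <- if (is.null(thr_args)) audit_thresholds()
                else do.call(audit_thresholds, thr_args)
  if (is.null(multiplier)) multiplier <- cfg$multiplier
  if (is.null(multiplier)) multiplier <- 1
  if (is.null(paper_style)) paper_style <- isTRUE(cfg$paper_style)

  fit <- blood_audit(records, thresholds = thresholds,
                     multiplier = multiplier, overrides = cfg$overrides,
                     strict = strict)

  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)

  idx <- fit$indices
  utils::write.csv(idx, file.path(output_dir, "indices.csv"),
                   row.names = FALSE, na = "")
  tab <- fit$msbos
  utils::write.csv(tab, file.path(output_dir, "msbos.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(tab, file.path(output_dir, "msbos.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  writeLines(render_table(fit, style = if (paper_style) "paper" else "full"),
             file.path(output_dir, "report.txt"))

  message(sprintf("excluded records: %d", fit$n_excluded))
  flagged <- idx$procedure[idx$procedure != "ALL" &
                             (idx$ctr_inefficient | idx$t_low | idx$ti_low)]
  if (length(flagged))
    message("flagged procedures: ", paste(flagged, collapse = ", "))
  invisible(fit)
}
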