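#' Specify a synthetic transfusion cohort
#'
#' A cohort specification is a list of per-procedure blocks. Each block
#' gives the number of patients, the fixed number of units crossmatched
#' per patient (2 is common practice for elective pediatric cardiac
#' surgery), a probability mass function over transfused-unit counts
#' 0..K, and optionally a per-issued-unit wastage probability with a
#' distribution over wastage categories.
#'
#' @param ... one or more blocks built with [cohort_block()].
#' @param seed integer RNG seed stored with the spec; [generate_cohort()]
#'   uses it unless given its own.
#' @return A list of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(
#'   cohort_block("VSD", n_patients = 64, crossmatch_per_patient = 2,
#'                transfusion_pmf = c(`0` = 8, `1` = 12, `2` = 43, `3` = 1) / 64),
#'   seed = 42
#' )
cohort_spec <- function(..., seed = NULL) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1]]) &&
      !inherits(blocks[[1]], "cohort_block") && is.null(blocks[[1]]$procedure))
    blocks <- blocks[[1]]
  if (!length(blocks)) stop("cohort_spec needs at least one block",
                            call. = FALSE)
  blocks <- lapply(blocks, function(b) {
    if (!inherits(b, "cohort_block")) b <- do.call(cohort_block, b)
    b
  })
  structure(list(blocks = blocks, seed = seed), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param procedure procedure code.
#' @param n_patients positive integer number of patients.
#' @param crossmatch_per_patient non-negative integer units crossmatched
#'   for every patient (default 2).
#' @param transfusion_pmf named numeric vector of probabilities over unit
#'   counts (names `"0"`, `"1"`, ...); must sum to 1 within 1e-9.
#' @param wastage_rate probability, per issued unit, of a wastage event
#'   (default 0).
#' @param wastage_category_probs probabilities over the four wastage
#'   categories (defaults to uniform); used only when `wastage_rate > 0`.
#' @export
cohort_block <- function(procedure, n_patients, transfusion_pmf,
                         crossmatch_per_patient = 2, wastage_rate = 0,
                         wastage_category_probs = NULL) {
  if (!is.numeric(n_patients) || n_patients < 1 || n_patients %% 1 != 0)
    stop("n_patients must be a positive integer", call. = FALSE)
  if (crossmatch_per_patient < 0 || crossmatch_per_patient %% 1 != 0)
    stop("crossmatch_per_patient must be a non-negative integer",
         call. = FALSE)
  pmf <- transfusion_pmf
  if (is.null(names(pmf)))
    names(pmf) <- seq_along(pmf) - 1L
  counts <- suppressWarnings(as.numeric(names(pmf)))
  if (anyNA(counts) || any(counts < 0) || any(counts %% 1 != 0))
    stop("transfusion_pmf names must be non-negative integer unit counts",
         call. = FALSE)
  if (any(pmf < 0) || any(pmf > 1) || abs(sum(pmf) - 1) > 1e-9)
    stop("transfusion_pmf must be probabilities summing to 1 (tol 1e-9)",
         call. = FALSE)
  if (wastage_rate < 0 || wastage_rate > 1)
    stop("wastage_rate must be a probability", call. = FALSE)
  if (is.null(wastage_category_probs))
    wastage_category_probs <- stats::setNames(
      rep(1 / length(WASTAGE_CATEGORIES), length(WASTAGE_CATEGORIES)),
      WASTAGE_CATEGORIES)
  if (!setequal(names(wastage_category_probs), WASTAGE_CATEGORIES) ||
      abs(sum(wastage_category_probs) - 1) > 1e-9)
    stop("wastage_category_probs must cover the four wastage categories ",
         "and sum to 1", call. = FALSE)
  structure(list(procedure = normalize_procedure(procedure),
                 n_patients = as.integer(n_patients),
                 crossmatch_per_patient = as.integer(crossmatch_per_patient),
                 transfusion_pmf = pmf,
                 wastage_rate = wastage_rate,
                 wastage_category_probs =
                   wastage_category_probs[WASTAGE_CATEGORIES]),
            class = "cohort_block")
}

#' Read a cohort specification from YAML or JSON
#'
#' The file holds a `seed` (optional) and a `blocks` list whose entries
#' carry the [cohort_block()] fields, with `transfusion_pmf` as a mapping
#' from unit count to probability.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = FALSE),
                stop("unsupported spec format: ", ext, call. = FALSE))
  blocks <- lapply(raw$blocks, function(b) {
    b <- lapply(b, function(el) if (is.list(el)) unlist(el) else el)
    do.call(cohort_block, b)
  })
  cohort_spec(blocks, seed = unlist(raw$seed))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards; no global side effects.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic transfusion cohort
#'
#' Draws exactly `n_patients` records per block, with transfused-unit
#' counts i.i.d. from the block's probability mass function and optional
#' per-unit wastage events. Record order is generation order; output is
#' deterministic given the seed and leaves the caller's RNG state
#' untouched.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to the seed stored in `spec`.
#' @return A `transfusion_records` data frame.
#' @export
#' @examples
#' spec <- cohort_spec(
#'   cohort_block("VSD", 64, c(`0` = 8, `1` = 12, `2` = 43, `3` = 1) / 64),
#'   seed = 1
#' )
#' rec <- generate_cohort(spec)
#' summarize_cohort(rec)
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    parts <- lapply(spec$blocks, function(b) {
      counts <- as.integer(names(b$transfusion_pmf))
      transfused <- sample(counts, b$n_patients, replace = TRUE,
                           prob = b$transfusion_pmf)
      issued <- rep(b$crossmatch_per_patient, b$n_patients)
      wast <- matrix(0L, nrow = b$n_patients,
                     ncol = length(WASTAGE_CATEGORIES),
                     dimnames = list(NULL, .wastage_cols()))
      if (b$wastage_rate > 0) {
        for (i in seq_len(b$n_patients)) {
          n_events <- stats::rbinom(1, issued[i], b$wastage_rate)
          if (n_events > 0) {
            cats <- sample(WASTAGE_CATEGORIES, n_events, replace = TRUE,
                           prob = b$wastage_category_probs)
            tab <- table(factor(cats, levels = WASTAGE_CATEGORIES))
            wast[i, ] <- as.integer(tab)
          }
        }
      }
      data.frame(
        patient_id = sprintf("%s-%04d", b$procedure, seq_len(b$n_patients)),
        procedure = b$procedure,
        units_crossmatched = rep(b$crossmatch_per_patient, b$n_patients),
        units_transfused = transfused,
        units_issued = issued,
        excluded = FALSE,
        wast,
        stringsAsFactors = FALSE
      )
    })
    validate_records(do.call(rbind, parts))
  })
}

#' Deterministically reconstruct a cohort from a unit-count histogram
#'
#' Produces the exact set of patient records realizing a histogram of
#' transfused-unit counts — no sampling involved. Summarizing the result
#' recovers the histogram, and running the full pipeline on it reproduces
#' the schedule values the histogram implies.
#'
#' @param histogram named integer vector mapping transfused-unit count to
#'   number of patients.
#' @param crossmatch_per_patient units crossmatched for every patient
#'   (default 2).
#' @param procedure procedure code for the records (default `"ALL"`).
#' @return A `transfusion_records` data frame with `sum(histogram)` rows.
#' @export
#' @examples
#' rec <- exact_cohort_from_histogram(c(`3` = 1, `2` = 43, `1` = 12, `0` = 8),
#'                                    procedure = "VSD")
#' nrow(rec)  # 64
exact_cohort_from_histogram <- function(histogram, crossmatch_per_patient = 2,
                                        procedure = "ALL") {
  if (!length(histogram))
    stop("histogram must be non-empty", call. = FALSE)
  counts <- as.integer(names(histogram))
  transfused <- rep(counts, times = as.integer(histogram))
  # descending unit count, the order the printed calculations list
  transfused <- sort(transfused, decreasing = TRUE)
  n <- length(transfused)
  transfusion_records(
    patient_id = sprintf("%s-%04d", normalize_procedure(procedure),
                         seq_len(n)),
    procedure = rep(procedure, n),
    units_crossmatched = rep(as.integer(crossmatch_per_patient), n),
    units_transfused = transfused
  )
}

#' Bundled example cohort: elective pediatric cardiac surgeries
#'
#' The package ships the per-procedure transfused-unit histograms of an
#' audited six-month cohort of elective pediatric cardiac surgeries (146
#' episodes over eight procedure types, each patient crossmatched 2 adult
#' RBC units). `example_cardiac_histograms()` returns the histograms;
#' `example_cardiac_cohort()` deterministically reconstructs the
#' patient-level records via [exact_cohort_from_histogram()].
#'
#' Procedures: ventricular septal defect (VSD), tetralogy of Fallot (TOF),
#' dextro-transposition of the great arteries (DTGA), atrial septal defect
#' (ASD), patent ductus arteriosus (PDA), pulmonary stenosis (PS), aortic
#' coarctation (COA), and pacemaker insertion (PACING).
#'
#' @return For `example_cardiac_histograms()`, a named list of named
#'   integer vectors (transfused-unit count -> patients). For
#'   `example_cardiac_cohort()`, a `transfusion_records` data frame.
#' @export
#' @examples
#' rec <- example_cardiac_cohort()
#' build_msbos_table(summarize_cohort(rec))
example_cardiac_histograms <- function() {
  list(
    VSD    = c(`3` = 1L, `2` = 43L, `1` = 12L, `0` = 8L),
    TOF    = c(`2` = 11L, `1` = 8L, `0` = 10L),
    DTGA   = c(`2` = 9L, `1` = 2L, `0` = 2L),
    ASD    = c(`2` = 10L, `1` = 5L),
    PDA    = c(`0` = 3L),
    PS     = c(`2` = 1L, `1` = 3L),
    COA    = c(`2` = 1L, `1` = 8L, `0` = 4L),
    PACING = c(`0` = 5L)
  )
}

#' @rdname example_cardiac_histograms
#' @export
example_cardiac_cohort <- function() {
  hists <- example_cardiac_histograms()
  parts <- lapply(names(hists), function(code)
    exact_cohort_from_histogram(hists[[code]], crossmatch_per_patient = 2,
                                procedure = code))
  out <- do.call(rbind, lapply(parts, as.data.frame))
  validate_records(out)
}
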