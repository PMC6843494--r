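#' Construct a peak table
#'
#' A peak table holds integrated chromatographic peak areas for a set of
#' samples (rows) and metabolites (columns), together with a missingness
#' mask. Areas are in arbitrary detector units and must be strictly
#' positive wherever they are observed; cells flagged missing carry `NA`
#' and are ignored by every downstream operation.
#'
#' @param areas Numeric matrix, samples in rows, metabolites in columns.
#'   Missing cells may be `NA`.
#' @param sample_ids Character vector of unique sample identifiers;
#'   defaults to `rownames(areas)`.
#' @param metabolite_ids Character vector of unique metabolite names;
#'   defaults to `colnames(areas)`.
#' @param missing Optional logical matrix of the same shape marking
#'   missing cells; defaults to `is.na(areas)`.
#' @return An object of class `peak_table`: a list with elements `areas`
#'   (numeric matrix with dimnames) and `missing` (logical matrix).
#' @export
peak_table <- function(areas, sample_ids = rownames(areas),
                       metabolite_ids = colnames(areas), missing = NULL) {
  areas <- as.matrix(areas)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(areas)))
  if (is.null(metabolite_ids)) metabolite_ids <- sprintf("M%03d", seq_len(ncol(areas)))
  sample_ids <- as.character(sample_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite identifiers: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  if (length(sample_ids) != nrow(areas) || length(metabolite_ids) != ncol(areas))
    stop("identifier lengths do not match matrix dimensions")
  if (is.null(missing)) missing <- is.na(areas)
  missing <- as.matrix(missing)
  storage.mode(missing) <- "logical"
  if (!identical(dim(missing), dim(areas)))
    stop("missing mask shape differs from areas")
  areas[missing] <- NA_real_
  bad <- which(!missing & (!is.finite(areas) | areas <= 0), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive or non-finite peak area at sample '%s', metabolite '%s'",
                 sample_ids[bad[1, 1]], metabolite_ids[bad[1, 2]]))
  dimnames(areas) <- dimnames(missing) <- list(sample_ids, metabolite_ids)
  structure(list(areas = areas, missing = missing), class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d samples x %d metabolites (%d missing cells)\n",
              nrow(x$areas), ncol(x$areas), sum(x$missing)))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$areas)

#' Sample metadata for a two-arm intervention cohort
#'
#' @param sample_id Character vector of sample identifiers.
#' @param group Group coding, 0 = placebo, 1 = active.
#' @param timepoint One of `"T0"`, `"T18"`, `"T48"` per sample.
#' @param batch_id Analytical batch label per sample.
#' @param covariates Optional data.frame of clinical covariates.
#' @return A data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, group, timepoint = "T18",
                        batch_id = "batch1", covariates = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in metadata")
  group <- as.integer(group)
  if (!all(group %in% c(0L, 1L))) stop("group must be coded 0 (placebo) / 1 (active)")
  timepoint <- as.character(timepoint)
  if (!all(timepoint %in% c("T0", "T18", "T48")))
    stop("timepoint must be one of T0, T18, T48")
  df <- data.frame(sample_id = sample_id, group = group,
                   timepoint = rep_len(timepoint, length(sample_id)),
                   batch_id = rep_len(as.character(batch_id), length(sample_id)),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Internal-standard peak areas
#'
#' Internal standards are compounds spiked at a fixed amount into every
#' sample; their signal tracks extraction and injection efficiency and
#' drives sample normalisation. The conventional panel size is 11
#' standards eluting across the chromatographic range.
#'
#' @param areas Numeric matrix, samples x standards, strictly positive.
#' @param sample_ids,standard_ids Identifiers; default to dimnames.
#' @return Object of class `is_table`.
#' @export
is_table <- function(areas, sample_ids = rownames(areas),
                     standard_ids = colnames(areas)) {
  areas <- as.matrix(areas)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(areas)))
  if (is.null(standard_ids)) standard_ids <- sprintf("IS%02d", seq_len(ncol(areas)))
  if (anyDuplicated(sample_ids) || anyDuplicated(standard_ids))
    stop("duplicate identifiers in internal-standard table")
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("internal-standard areas must all be positive and finite")
  dimnames(areas) <- list(as.character(sample_ids), as.character(standard_ids))
  structure(list(areas = areas), class = "is_table")
}

# symbols used on disk for direction calls
.dir_symbols <- c(UP = "+", DOWN = "-", NONE = "N", MISSING = ".")

#' Per-metabolite, per-study effect-direction table
#'
#' Each cell records whether a metabolite was higher (`UP`), lower
#' (`DOWN`) or unchanged (`NONE`) in the actively treated arm of one
#' study, or was not detected there (`MISSING`).
#'
#' @param calls Character matrix (metabolites x studies) of symbols in
#'   `UP`, `DOWN`, `NONE`, `MISSING`.
#' @param metabolite_ids,studies Identifiers; default to dimnames.
#' @return Object of class `direction_table`.
#' @export
direction_table <- function(calls, metabolite_ids = rownames(calls),
                            studies = colnames(calls)) {
  calls <- as.matrix(calls)
  if (!all(calls %in% names(.dir_symbols)))
    stop("direction calls must be UP, DOWN, NONE or MISSING")
  if (is.null(metabolite_ids) || is.null(studies))
    stop("metabolite and study identifiers are required")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite identifiers")
  if (anyDuplicated(studies)) stop("duplicate study labels")
  dimnames(calls) <- list(as.character(metabolite_ids), as.character(studies))
  structure(list(calls = calls), class = "direction_table")
}

#' @export
print.direction_table <- function(x, ...) {
  cat(sprintf("direction_table: %d metabolites x %d studies (%s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(colnames(x$calls), collapse = ", ")))
  invisible(x)
}

#' Read a peak table from a delimited file
#'
#' Expects a header row of metabolite names, one row per sample, and the
#' sample identifier in the first column. Empty cells mark missing
#' metabolites.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  areas <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                   dimnames = list(ids, colnames(m))))
  missing <- m == "" | is.na(m)
  areas[missing] <- NA_real_
  peak_table(areas, sample_ids = ids, metabolite_ids = colnames(m),
             missing = missing)
}

#' Write a peak table to a delimited file
#'
#' Missing cells are written as empty strings so that
#' [read_peak_table()] round-trips the missingness mask.
#'
#' @param x A [peak_table()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_peak_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  chr <- matrix(vapply(x$areas, function(a)
    if (is.na(a)) "" else format(a, digits = 17), character(1)),
    nrow = nrow(x$areas))
  out <- cbind(sample_id = rownames(x$areas), as.data.frame(chr))
  names(out)[-1] <- colnames(x$areas)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a direction table
#'
#' On disk a direction table is a TSV whose first column holds metabolite
#' names and whose remaining columns hold one study each, with cells in
#' `{+, -, N, .}` for up / down / no change / not detected.
#'
#' @param path File path.
#' @return [read_direction_table()] returns a [direction_table()].
#' @export
read_direction_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "\"")
  m <- as.matrix(df[, -1, drop = FALSE])
  sym2call <- stats::setNames(names(.dir_symbols), .dir_symbols)
  if (!all(m %in% names(sym2call)))
    stop("unknown direction symbol in ", path)
  calls <- matrix(sym2call[m], nrow = nrow(m),
                  dimnames = list(df[[1]], colnames(m)))
  direction_table(calls)
}

#' @rdname read_direction_table
#' @param x A [direction_table()].
#' @export
write_direction_table <- function(x, path) {
  sym <- matrix(.dir_symbols[x$calls], nrow = nrow(x$calls),
                dimnames = dimnames(x$calls))
  out <- cbind(metabolite = rownames(sym), as.data.frame(sym))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a packaged transcription of one of the study's printed tables
#'
#' The package ships verbatim transcriptions of the five printed summary
#' tables of the source study: baseline clinical characteristics
#' (`table1`), metabolites significantly decreased in the treated arm of
#' the main study with t-test p-values and VIP (`table2`), per-batch
#' significant compounds for the two validation studies (`table3`,
#' `table4`), and the three-study effect-direction matrix (`table5`).
#' Cells are stored exactly as printed ("NS", "n/a"); typed convenience
#' columns are added where a cell parses to a number.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table4"`,
#'   `"table5"`.
#' @return For `table5` a [direction_table()]; otherwise a data.frame.
#'   `table1` gains `p_numeric` (NA where blank or "n/a"); `table2`
#'   gains `p_numeric` (NA where "NS") and logical `significant`.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table4", "table5")) {
  name <- match.arg(name)
  file <- switch(name,
    table1 = "table1_baseline.tsv",
    table2 = "table2_metabolites.tsv",
    table3 = "table3_validation1.tsv",
    table4 = "table4_validation2.tsv",
    table5 = "table5_directions.tsv")
  path <- system.file("extdata", file, package = "oplsmet", mustWork = TRUE)
  if (name == "table5") return(read_direction_table(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "\"", fill = TRUE,
                          colClasses = "character")
  if (name == "table1") {
    for (col in c("active_count", "active_total", "placebo_count", "placebo_total"))
      df[[col]] <- as.integer(df[[col]])
    df$p_numeric <- suppressWarnings(as.numeric(df$p_printed))
  }
  if (name %in% c("table2", "table3", "table4")) {
    df$vip <- as.numeric(df$vip)
    df$p_numeric <- suppressWarnings(as.numeric(df$p_value))
    df$significant <- !is.na(df$p_numeric) & df$p_numeric < 0.05
  }
  df
}
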