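#' Welch two-sample t-test
#'
#' Two-sample, unequal-variance, two-tailed t-test with
#' Welch--Satterthwaite degrees of freedom.
#'
#' @param x1,x2 Numeric vectors, each of length at least 2.
#' @return List with `statistic` (t, positive when `mean(x1) > mean(x2)`),
#'   `df` and `p_value`.
#' @export
welch_t <- function(x1, x2) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(x1, x2, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Per-metabolite Welch t-tests between treatment groups
#'
#' Runs one Welch test per metabolite on the non-missing values at a
#' time point, active (group 1) versus placebo (group 0). P-values are
#' reported raw — the study convention — with an optional
#' Benjamini-Hochberg column. Metabolites with fewer than two observed
#' values in either group are flagged untestable and excluded from
#' testing (a message names them).
#'
#' @param table A [peak_table()].
#' @param meta A [sample_meta()] data.frame covering its samples.
#' @param timepoint Time point to analyse (default `"T18"`).
#' @param adjust Add a BH-adjusted `q` column (default `FALSE`).
#' @return Data.frame with `metabolite`, `direction` (sign of the
#'   active-minus-placebo mean difference: -1, 0 or 1), `mean_diff`,
#'   `p`, logical `tested`, and optionally `q`.
#' @export
metabolite_ttests <- function(table, meta, timepoint = "T18", adjust = FALSE) {
  ids <- rownames(table$areas)
  m <- meta[match(ids, meta$sample_id), ]
  if (anyNA(m$sample_id)) stop("metadata missing for some samples")
  sel <- m$timepoint == timepoint
  if (!any(sel)) stop("no samples at timepoint ", timepoint)
  grp <- m$group[sel]
  if (length(unique(grp)) < 2) stop("both groups required at ", timepoint)
  A <- table$areas[sel, , drop = FALSE]
  res <- lapply(colnames(A), function(met) {
    v <- A[, met]
    x1 <- v[grp == 1 & !is.na(v)]
    x0 <- v[grp == 0 & !is.na(v)]
    if (length(x1) < 2 || length(x0) < 2)
      return(data.frame(metabolite = met, direction = NA_integer_,
                        mean_diff = NA_real_, p = NA_real_, tested = FALSE))
    wt <- welch_t(x1, x0)
    d <- mean(x1) - mean(x0)
    data.frame(metabolite = met, direction = sign(d), mean_diff = d,
               p = wt$p_value, tested = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  skipped <- out$metabolite[!out$tested]
  if (length(skipped) > 0)
    message("untestable metabolites excluded: ", paste(skipped, collapse = ", "))
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' 2x2 contingency table
#'
#' @param a,b Yes/no counts in group 1.
#' @param c,d Yes/no counts in group 2.
#' @return Object of class `contingency_2x2` (a 2x2 integer matrix).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m <- matrix(as.integer(counts), 2, 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"), c("yes", "no")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square with 1 degree of freedom and no continuity
#' correction — the convention that reproduces the printed baseline
#' p-values of the study tables.
#'
#' @param tbl A [contingency_2x2()] or plain 2x2 matrix of counts.
#' @return List with `statistic` and `p_value`.
#' @export
chi2_2x2 <- function(tbl) {
  m <- unclass(as.matrix(tbl))
  if (!identical(dim(m), c(2L, 2L))) stop("tbl must be 2x2")
  if (sum(m) <= 0) stop("empty table")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("zero margin: chi-square test undefined")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Recompute baseline-table chi-square p-values from printed counts
#'
#' Convenience wrapper over [chi2_2x2()] for a baseline characteristics
#' table in the layout of the packaged `table1` fixture. Rows with a
#' zero margin or a zero observed cell (e.g. a medication absent in one
#' arm, where the chi-square approximation is meaningless at these group
#' sizes) are returned as `NA`, mirroring the "n/a" entries of the
#' printed table.
#'
#' @param baseline Data.frame with columns `variable`, `active_count`,
#'   `active_total`, `placebo_count`, `placebo_total`.
#' @return Data.frame with `variable` and recomputed `p`.
#' @export
baseline_chi2 <- function(baseline) {
  p <- vapply(seq_len(nrow(baseline)), function(i) {
    r <- baseline[i, ]
    tbl <- try(contingency_2x2(r$active_count, r$active_total - r$active_count,
                               r$placebo_count, r$placebo_total - r$placebo_count),
               silent = TRUE)
    if (inherits(tbl, "try-error")) return(NA_real_)
    if (any(tbl == 0)) return(NA_real_)
    out <- try(chi2_2x2(tbl), silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out$p_value
  }, numeric(1))
  data.frame(variable = baseline$variable, p = p, stringsAsFactors = FALSE)
}
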