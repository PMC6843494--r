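#' Unit-variance scaling
#'
#' Centres each column at its mean and divides by its population
#' (1/n) standard deviation, both computed over non-missing entries.
#' Missing entries are imputed as 0 after scaling, i.e. at the column
#' mean — neutral for PCA and PLS models fitted on the result.
#'
#' @param x Numeric matrix, samples in rows. `NA` marks missing.
#' @return A list with `scaled` (matrix, no `NA`), `mean` and `sd`
#'   (per-column vectors).
#' @export
uv_scale <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    sqrt(mean((v - mean(v))^2))
  })
  zero <- which(!is.finite(sdv) | sdv <= 0)
  if (length(zero) > 0) {
    nm <- colnames(x)[zero[1]]
    if (is.null(nm)) nm <- as.character(zero[1])
    stop("zero-variance variable cannot be unit-variance scaled: ", nm)
  }
  scaled <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  scaled[is.na(scaled)] <- 0
  list(scaled = scaled, mean = mu, sd = sdv)
}

#' Internal-standard normalisation by first-component score
#'
#' Fits a one-component principal component model to the internal
#' standards — each standard scaled to unit variance but not
#' mean-centred, so that the first score acts as a weighted mean
#' intensity factor — and divides every peak area in a sample by that
#' sample's score. The component sign is fixed so the mean score is
#' positive; because all standard areas are positive, scores of a
#' consistent standards panel are then positive too, and a non-positive
#' score aborts with an error (it signals standards that do not share a
#' common intensity factor).
#'
#' @param table A [peak_table()].
#' @param standards An [is_table()] whose samples match `table`.
#' @return A list of class `normalization_result` with `normalized`
#'   (peak_table), `t1_scores` (named per-sample factors) and
#'   `loadings` (per-standard weights of the component).
#' @export
is_normalize <- function(table, standards) {
  if (!inherits(table, "peak_table")) stop("table must be a peak_table")
  if (!inherits(standards, "is_table")) stop("standards must be an is_table")
  ids <- rownames(table$areas)
  if (!setequal(ids, rownames(standards$areas)))
    stop("internal-standard samples do not match the peak table")
  S <- standards$areas[ids, , drop = FALSE]
  # unit variance per standard, no centring: scores stay positive; a
  # perfectly stable (constant) standard is scaled by its mean instead,
  # so it contributes a constant column rather than dividing by zero
  sdv <- apply(S, 2, function(v) sqrt(mean((v - mean(v))^2)))
  flat <- sdv <= 0
  sdv[flat] <- colMeans(S)[flat]
  Ss <- sweep(S, 2, sdv, "/")
  pc <- nipals_pca(Ss, n_components = 1)
  t1 <- drop(pc$scores)
  if (mean(t1) < 0) {
    t1 <- -t1
    pc$loadings <- -pc$loadings
  }
  if (any(t1 <= 0))
    stop("non-positive normalisation score for sample ",
         ids[which(t1 <= 0)[1]],
         ": standards inconsistent with a common intensity factor")
  norm_areas <- sweep(table$areas, 1, t1, "/")
  res <- list(
    normalized = peak_table(norm_areas, sample_ids = ids,
                            metabolite_ids = colnames(table$areas),
                            missing = table$missing),
    t1_scores = stats::setNames(t1, ids),
    loadings = stats::setNames(drop(pc$loadings), colnames(S)))
  class(res) <- "normalization_result"
  res
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("internal-standard normalisation: %d samples, t1 range [%.3g, %.3g]\n",
              length(x$t1_scores), min(x$t1_scores), max(x$t1_scores)))
  invisible(x)
}
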