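# NIPALS core: X must be fully observed and already pre-processed.
# Deterministic start: the column with the largest remaining sum of
# squares. Convergence on the relative change of the score vector.
nipals_pca <- function(X, n_components, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  ss_total <- sum(X^2)
  n <- nrow(X); k <- ncol(X)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, k, n_components)
  r2 <- numeric(n_components)
  if (n_components == 0)
    return(list(scores = scores, loadings = loadings, r2x = r2))
  E <- X
  for (a in seq_len(n_components)) {
    css <- colSums(E^2)
    if (max(css) < .Machine$double.eps * max(ss_total, 1))
      stop("matrix rank exhausted before component ", a)
    t_vec <- E[, which.max(css)]
    for (it in seq_len(max_iter)) {
      p <- drop(crossprod(E, t_vec)) / sum(t_vec^2)
      p <- p / sqrt(sum(p^2))
      t_new <- drop(E %*% p)
      if (sqrt(sum((t_new - t_vec)^2)) <= tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
      if (it == max_iter)
        stop("NIPALS did not converge for component ", a)
    }
    # sign convention: largest-magnitude loading entry positive
    j <- which.max(abs(p))
    if (p[j] < 0) {
      p <- -p
      t_vec <- -t_vec
    }
    scores[, a] <- t_vec
    loadings[, a] <- p
    r2[a] <- sum(t_vec^2) / ss_total
    E <- E - tcrossprod(t_vec, p)
  }
  list(scores = scores, loadings = loadings, r2x = r2)
}

#' Principal component analysis by NIPALS
#'
#' Sequentially extracts components maximising explained variance, with
#' a deterministic start vector (the column of largest remaining sum of
#' squares), convergence tolerance `1e-10` and at most 500 iterations
#' per component. The sign of each loading vector is fixed so its
#' largest-magnitude entry is positive.
#'
#' @param X Numeric matrix, samples in rows. Must have no missing
#'   values (impute upstream, e.g. with [uv_scale()]).
#' @param n_components Number of components; may be 0 for an empty
#'   model that projects to no scores.
#' @param scaling `"uv"` for unit-variance scaling (with centring) or
#'   `"none"` for the raw matrix.
#' @param center Subtract column means before analysis. Defaults to
#'   `TRUE` under `"uv"` scaling and `FALSE` otherwise; the combined
#'   loading profile of the meta stage uses `scaling = "none"`,
#'   `center = FALSE`.
#' @return Object of class `pca_model`: scores, unit-norm loadings,
#'   `r2x_per_component`, and the per-variable `mean` and `sd` used so
#'   new samples can be projected.
#' @export
fit_pca <- function(X, n_components, scaling = c("uv", "none"),
                    center = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (is.null(center)) center <- scaling == "uv"
  if (n_components > min(dim(X)))
    stop("n_components exceeds matrix dimensions")
  if (scaling == "uv") {
    sc <- uv_scale(X)
    if (!center) {
      # unit variance without centring: rescale only
      sc$scaled <- sweep(X, 2, sc$sd, "/")
      sc$scaled[is.na(sc$scaled)] <- 0
      sc$mean <- rep(0, ncol(X))
    }
    Xs <- sc$scaled; mu <- sc$mean; sdv <- sc$sd
  } else {
    mu <- if (center) colMeans(X) else rep(0, ncol(X))
    sdv <- rep(1, ncol(X))
    Xs <- sweep(X, 2, mu, "-")
  }
  if (anyNA(Xs)) stop("X contains missing values; impute before fit_pca")
  fit <- nipals_pca(Xs, n_components)
  rownames(fit$scores) <- rownames(X)
  rownames(fit$loadings) <- colnames(X)
  structure(list(n_components = n_components,
                 scores = fit$scores, loadings = fit$loadings,
                 r2x_per_component = fit$r2x,
                 mean = stats::setNames(mu, colnames(X)),
                 sd = stats::setNames(sdv, colnames(X)),
                 scaling = scaling, center = center),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d components, R2X = %s (cum %.3f)\n",
              x$n_components,
              paste(sprintf("%.3f", x$r2x_per_component), collapse = " + "),
              sum(x$r2x_per_component)))
  invisible(x)
}

#' Project new samples into a fitted PCA model
#'
#' Applies the model's stored centring/scaling to `Xnew` and maps onto
#' the loading space. Projecting the training data reproduces the
#' training scores.
#'
#' @param model A `pca_model`.
#' @param Xnew Matrix with the model's variables (matched by name when
#'   both are named).
#' @return Score matrix for the new samples.
#' @export
project <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  vars <- names(model$mean)
  if (!is.null(colnames(Xnew)) && !is.null(vars)) {
    if (!setequal(colnames(Xnew), vars))
      stop("variables of Xnew do not match the model")
    Xnew <- Xnew[, vars, drop = FALSE]
  } else if (ncol(Xnew) != length(model$mean)) {
    stop("variable count mismatch with the model")
  }
  Xs <- sweep(sweep(Xnew, 2, model$mean, "-"), 2, model$sd, "/")
  Xs[is.na(Xs)] <- 0
  Xs %*% model$loadings
}

#' Hotelling T-squared statistics and control limit
#'
#' Computes the T-squared of each score row against the model's training
#' score variances and the F-distribution control limit
#' \eqn{A(n-1)/(n-A)\,F_{1-\alpha}(A, n-A)} with A components and n
#' training samples — the limit drawn as the ellipse on chemometrics
#' score plots and used to flag outlying samples.
#'
#' @param model A fitted `pca_model` with at least one component.
#' @param scores Score matrix (e.g. from [project()]); defaults to the
#'   training scores.
#' @param alpha Significance level of the limit.
#' @return List with per-sample `t2` and the scalar `limit`.
#' @export
hotelling_t2 <- function(model, scores = model$scores, alpha = 0.05) {
  A <- model$n_components
  if (A < 1) stop("model has no components")
  n <- nrow(model$scores)
  if (n <= A) stop("need more training samples than components")
  s2 <- apply(model$scores, 2, stats::var)
  t2 <- rowSums(sweep(as.matrix(scores)^2, 2, s2, "/"))
  limit <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
  list(t2 = t2, limit = limit)
}

#' Representative-sample selection by multivariate design
#'
#' Implements the selection used to pick study subjects spanning the
#' properties domain of a two-component PCA score plot: from each of the
#' four quadrants the most extreme sample (largest distance from the
#' origin) is taken first, then samples maximising the minimum distance
#' to those already picked in that quadrant; finally the samples closest
#' to the origin are added as centre picks. Boundary points (a score of
#' exactly 0) count to the positive side; all ties break by sample-id
#' order, making the selection deterministic.
#'
#' @param scores n x 2 score matrix with sample ids as rownames.
#' @param per_quadrant Samples to take from each quadrant (default 2).
#' @param center Samples to take from the centre (default 2).
#' @return Character vector of selected sample ids. If a quadrant holds
#'   fewer samples than requested a warning is issued and fewer ids are
#'   returned.
#' @export
select_representative <- function(scores, per_quadrant = 2, center = 2) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scores)))
  ord <- order(ids)
  scores <- scores[ord, , drop = FALSE]
  ids <- ids[ord]
  quadrant <- ifelse(scores[, 1] >= 0,
                     ifelse(scores[, 2] >= 0, 1L, 4L),
                     ifelse(scores[, 2] >= 0, 2L, 3L))
  dist0 <- sqrt(rowSums(scores^2))
  selected <- character(0)
  for (q in 1:4) {
    in_q <- which(quadrant == q)
    if (length(in_q) < per_quadrant)
      warning(sprintf("quadrant %d has only %d sample(s); requested %d",
                      q, length(in_q), per_quadrant))
    if (length(in_q) == 0) next
    picks <- in_q[which.max(dist0[in_q])]
    while (length(picks) < min(per_quadrant, length(in_q))) {
      rest <- setdiff(in_q, picks)
      mind <- vapply(rest, function(i) {
        min(sqrt(colSums((t(scores[picks, , drop = FALSE]) - scores[i, ])^2)))
      }, numeric(1))
      picks <- c(picks, rest[which.max(mind)])
    }
    selected <- c(selected, ids[picks])
  }
  remaining <- setdiff(seq_along(ids), match(selected, ids))
  n_center <- min(center, length(remaining))
  if (n_center < center)
    warning("fewer unselected samples than requested centre picks")
  centre_picks <- remaining[order(dist0[remaining])][seq_len(n_center)]
  c(selected, ids[centre_picks])
}
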