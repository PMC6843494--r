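#' Fit an OPLS / OPLS-DA model
#'
#' Orthogonal projections to latent structures with a binary response:
#' variation in X that is orthogonal to the class vector y is removed in
#' `n_orthogonal` sequential components, after which a single predictive
#' component is fitted to the filtered matrix. X is unit-variance scaled
#' internally ([uv_scale()]) and y is centred. With
#' `n_orthogonal = 0` the model coincides with one-component PLS1.
#'
#' Each orthogonal round computes the PLS weight `w` proportional to
#' `X'y`, the score `t = Xw` and loading `p = X't/(t't)`, then the
#' orthogonal weight `w_o` proportional to `p - (w'p)w`, the orthogonal
#' score `t_o = X w_o` and loading `p_o`, and deflates X by
#' `t_o p_o'`. Diagnostics follow chemometrics convention: R2X is the
#' fraction of scaled-X sum of squares captured by the predictive and
#' orthogonal components together, R2Y(cum) the fraction of y variance
#' explained, p(corr) the Pearson correlation of each scaled variable
#' with the predictive score, and VIP the variable importance in
#' projection over all components, normalised so the mean squared VIP
#' is 1.
#'
#' @param X Numeric matrix, samples x variables; `NA` allowed (treated
#'   as missing, imputed at the column mean after scaling).
#' @param y Binary class vector, 0 = placebo, 1 = active; both classes
#'   must be present.
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @return Object of class `opls_model`.
#' @export
fit_opls <- function(X, y, n_orthogonal = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length of y must match rows of X")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (n_orthogonal >= min(dim(X)))
    stop("n_orthogonal must be smaller than the rank of X")
  sc <- uv_scale(X)
  Xs <- sc$scaled
  y_mean <- mean(y)
  yc <- y - y_mean
  ss_x <- sum(Xs^2)
  ss_y <- sum(yc^2)

  E <- Xs
  w_o <- t_o <- p_o <- NULL
  r2x_orth <- numeric(0)
  for (a in seq_len(n_orthogonal)) {
    w <- drop(crossprod(E, yc))
    w <- w / sqrt(sum(w^2))
    t_vec <- drop(E %*% w)
    p <- drop(crossprod(E, t_vec)) / sum(t_vec^2)
    wo <- p - sum(w * p) * w
    wo_norm <- sqrt(sum(wo^2))
    if (wo_norm < 1e-12)
      stop("no orthogonal variation left at component ", a)
    wo <- wo / wo_norm
    to <- drop(E %*% wo)
    po <- drop(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    w_o <- cbind(w_o, wo)
    t_o <- cbind(t_o, to)
    p_o <- cbind(p_o, po)
    r2x_orth <- c(r2x_orth, sum(to^2) * sum(po^2) / ss_x)
  }
  w <- drop(crossprod(E, yc))
  w <- w / sqrt(sum(w^2))
  t_vec <- drop(E %*% w)
  p <- drop(crossprod(E, t_vec)) / sum(t_vec^2)
  b <- sum(t_vec * yc) / sum(t_vec^2)
  r2x_pred <- sum(t_vec^2) * sum(p^2) / ss_x
  r2y <- b^2 * sum(t_vec^2) / ss_y
  pcorr <- drop(stats::cor(Xs, t_vec))

  vars <- colnames(X)
  model <- structure(list(
    n_orthogonal = n_orthogonal,
    w = stats::setNames(w, vars), t = t_vec, p = stats::setNames(p, vars),
    w_o = w_o, t_o = t_o, p_o = p_o, b = b,
    x_mean = sc$mean, x_sd = sc$sd, y_mean = y_mean,
    r2x = r2x_pred + sum(r2x_orth), r2x_pred = r2x_pred,
    r2x_orth = r2x_orth,
    r2y_cum = r2y, q2_cum = NA_real_,
    pcorr = stats::setNames(pcorr, vars)),
    class = "opls_model")
  model$vip <- vip(model)
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model: 1 predictive + %d orthogonal component(s)\n  R2X = %.3f  R2Y(cum) = %.3f  Q2(cum) = %s\n",
    x$n_orthogonal, x$r2x, x$r2y_cum,
    if (is.na(x$q2_cum)) "not cross-validated" else sprintf("%.3f", x$q2_cum)))
  invisible(x)
}

#' Predict class values from an OPLS model
#'
#' Applies the stored scaling, strips the orthogonal variation with the
#' stored orthogonal weights/loadings, and predicts
#' `y-hat = b * t + mean(y)`.
#'
#' @param object An `opls_model`.
#' @param newdata Matrix with the training variables.
#' @param ... Unused.
#' @return Numeric vector of predicted y values.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  vars <- names(object$x_mean)
  if (!is.null(colnames(newdata)) && !is.null(vars)) {
    if (!setequal(colnames(newdata), vars))
      stop("variables of newdata do not match the model")
    newdata <- newdata[, vars, drop = FALSE]
  } else if (ncol(newdata) != length(object$x_mean)) {
    stop("variable count mismatch with the model")
  }
  Xs <- sweep(sweep(newdata, 2, object$x_mean, "-"), 2, object$x_sd, "/")
  Xs[is.na(Xs)] <- 0
  for (a in seq_len(object$n_orthogonal)) {
    to <- drop(Xs %*% object$w_o[, a])
    Xs <- Xs - tcrossprod(to, object$p_o[, a])
  }
  t_new <- drop(Xs %*% object$w)
  object$b * t_new + object$y_mean
}

#' Variable importance in projection over all model components
#'
#' The squared weight of each variable in every component is averaged
#' with component weights equal to the explained y-variance for the
#' predictive component and the explained X-variance for each orthogonal
#' component (the "total" VIP reported by standard chemometrics
#' software). The result is normalised so that the sum of squared VIP
#' equals the number of variables; the conventional selection threshold
#' is about 0.8.
#'
#' @param model A fitted `opls_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  K <- length(model$w)
  W <- cbind(model$w, model$w_o)
  q <- c(model$r2y_cum, model$r2x_orth)
  v <- sqrt(K * drop(W^2 %*% q) / sum(q))
  stats::setNames(v, names(model$w))
}

# deterministic folds: samples sorted by (class, sample id), dealt
# round-robin; returns integer fold per sample in original order
cv_folds <- function(y, sample_ids, n_folds) {
  ord <- order(y, sample_ids)
  folds <- integer(length(y))
  folds[ord] <- rep_len(seq_len(n_folds), length(y))
  folds
}

#' Seven-fold cross-validation of an OPLS model
#'
#' Samples are sorted by (class, sample id) and dealt round-robin into
#' folds, so the assignment is deterministic and both classes appear in
#' every fold. Each fold is predicted by a model refitted without it;
#' Q2 = 1 - PRESS / SS(y).
#'
#' @param X,y As in [fit_opls()]. Row names of `X` identify samples.
#' @param n_folds Number of cross-validation folds (default 7). If a
#'   class has fewer samples than folds the count is reduced with a
#'   warning; `n_folds` equal to the sample count gives leave-one-out.
#' @param n_orthogonal Orthogonal components per sub-model.
#' @return Object of class `opls_cv`: `n_folds`, per-sample `folds`,
#'   `cv_predicted_y`, `press`, `q2`.
#' @export
cross_validate <- function(X, y, n_folds = 7, n_orthogonal = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (n_folds < 2) stop("n_folds must be at least 2")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(X)))
  min_class <- min(table(y))
  if (n_folds > nrow(X)) {
    warning("n_folds reduced to the number of samples")
    n_folds <- nrow(X)
  } else if (min_class < n_folds && n_folds < nrow(X)) {
    # keep leave-one-out untouched; otherwise ensure folds span classes
    warning(sprintf("smallest class has %d samples; n_folds reduced", min_class))
    n_folds <- max(2L, min_class)
  }
  folds <- cv_folds(y, ids, n_folds)
  yhat <- numeric(length(y))
  for (g in seq_len(n_folds)) {
    hold <- folds == g
    fit <- fit_opls(X[!hold, , drop = FALSE], y[!hold], n_orthogonal)
    yhat[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  press <- sum((y - yhat)^2)
  ss <- sum((y - mean(y))^2)
  structure(list(n_folds = n_folds,
                 folds = stats::setNames(folds, ids),
                 cv_predicted_y = stats::setNames(yhat, ids),
                 press = press, q2 = 1 - press / ss),
            class = "opls_cv")
}

#' @export
print.opls_cv <- function(x, ...) {
  cat(sprintf("OPLS cross-validation: %d folds, Q2(cum) = %.3f\n",
              x$n_folds, x$q2))
  invisible(x)
}

#' Group test on cross-validated predicted class values
#'
#' Welch two-sample, two-tailed t-test comparing the out-of-fold
#' predicted y values between the two classes — the test used to state a
#' p-value for group separation on the cross-validated prediction plot.
#'
#' @param cv An `opls_cv` result.
#' @param y The class vector used to fit it.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
predicted_y_test <- function(cv, y) {
  y <- as.numeric(y)
  yhat <- cv$cv_predicted_y
  if (min(table(y)) < 2) stop("each class needs at least 2 samples")
  ht <- stats::t.test(yhat[y == 1], yhat[y == 0], var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Jack-knife confidence intervals for per-variable statistics
#'
#' Refits the model once per cross-validation fold (leaving that fold
#' out), records the per-variable statistic of each sub-model — p(corr)
#' by default, the effective regression coefficient as an option — and
#' forms jack-knife standard errors
#' \eqn{SE = \sqrt{\frac{G-1}{G}\sum_g (s_g - \bar s)^2}} over the G
#' sub-models. Confidence intervals are centred on the full-model
#' statistic with a t quantile on G-1 degrees of freedom; a variable is
#' flagged significant when its interval excludes 0. Before aggregation
#' each sub-model's statistic vector is sign-aligned to the full model's
#' predictive score direction, since the latent direction is only
#' defined up to sign.
#'
#' @param X,y,n_folds,n_orthogonal As in [cross_validate()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param statistic `"pcorr"` (default) or `"coefficient"`.
#' @return Data.frame of class `jackknife_result` with columns
#'   `metabolite`, `estimate`, `se`, `lower`, `upper`, `significant`.
#' @export
jackknife_ci <- function(X, y, n_folds = 7, n_orthogonal = 1,
                         alpha = 0.05, statistic = c("pcorr", "coefficient")) {
  statistic <- match.arg(statistic)
  X <- as.matrix(X)
  y <- as.numeric(y)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(X)))
  min_class <- min(table(y))
  if (n_folds > nrow(X)) n_folds <- nrow(X)
  if (min_class < n_folds && n_folds < nrow(X))
    n_folds <- max(2L, min_class)
  if (n_folds < 3) stop("jack-knife needs at least 3 cross-validation rounds")
  full <- fit_opls(X, y, n_orthogonal)
  stat_of <- function(m) if (statistic == "pcorr") m$pcorr else opls_coef(m)
  full_stat <- stat_of(full)
  folds <- cv_folds(y, ids, n_folds)
  G <- n_folds
  S <- matrix(0, G, ncol(X))
  for (g in seq_len(G)) {
    keep <- folds != g
    sub <- fit_opls(X[keep, , drop = FALSE], y[keep], n_orthogonal)
    s_g <- stat_of(sub)
    # sign-align the sub-model's latent direction with the full model's
    if (stats::cor(sub$t, full$t[keep]) < 0) s_g <- -s_g
    S[g, ] <- s_g
  }
  s_bar <- colMeans(S)
  se <- sqrt((G - 1) / G * colSums(sweep(S, 2, s_bar, "-")^2))
  tq <- stats::qt(1 - alpha / 2, G - 1)
  lower <- full_stat - tq * se
  upper <- full_stat + tq * se
  res <- data.frame(metabolite = names(full_stat), estimate = unname(full_stat),
                    se = se, lower = lower, upper = upper,
                    significant = lower > 0 | upper < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("jackknife_result", "data.frame")
  res
}

# effective regression coefficients of y on the scaled X, after the
# orthogonal filter: y-hat = b * (filtered Xs) w = Xs beta
opls_coef <- function(model) {
  K <- length(model$w)
  M <- diag(K)
  for (a in seq_len(model$n_orthogonal))
    M <- M %*% (diag(K) - tcrossprod(model$w_o[, a], model$p_o[, a]))
  stats::setNames(drop(M %*% model$w) * model$b, names(model$w))
}
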