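# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package's code paths.

# population-SD unit-variance scaling
uv_ref <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

# one-component PLS1 by the textbook NIPALS recursion
pls1_ref <- function(Xs, yc) {
  w <- drop(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xs %*% w)
  p <- drop(crossprod(Xs, t)) / sum(t^2)
  b <- sum(t * yc) / sum(t^2)
  list(w = w, t = t, p = p, b = b)
}

# A-component PLS1 with deflation of X and y; returns training fit
pls_multi_ref <- function(Xs, yc, A) {
  yhat <- rep(0, length(yc))
  for (a in seq_len(A)) {
    f <- pls1_ref(Xs, yc)
    yhat <- yhat + f$b * f$t
    Xs <- Xs - tcrossprod(f$t, f$p)
    yc <- yc - f$b * f$t
  }
  yhat
}

# Welch test from first principles
welch_ref <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- var(x1) / n1; v2 <- var(x2) / n2
  t <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# small deterministic cohort for structural tests
tiny_cohort <- function(seed = 1, n = 6, ...) {
  generate_cohort(sim_config(n_per_group = n, seed = seed, ...))
}

random_peak_table <- function(seed, n = 5, k = 8, missing_frac = 0) {
  set.seed(seed)
  areas <- matrix(exp(rnorm(n * k, 10, 1)), n, k,
                  dimnames = list(sprintf("S%02d", 1:n), sprintf("M%02d", 1:k)))
  if (missing_frac > 0) {
    miss <- matrix(runif(n * k) < missing_frac, n, k)
    areas[miss] <- NA
  }
  peak_table(areas)
}
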