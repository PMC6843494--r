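test_that("OPLS with no orthogonal component equals one-component PLS1", {
  set.seed(41)
  X <- matrix(rnorm(10 * 8), 10, 8)
  y <- rep(c(0, 1), each = 5)
  m <- fit_opls(X, y, n_orthogonal = 0)
  ref <- pls1_ref(uv_ref(X), y - mean(y))
  expect_equal(unname(m$w), ref$w, tolerance = 1e-8)
  expect_equal(m$t, ref$t, tolerance = 1e-8)
  expect_equal(unname(m$p), ref$p, tolerance = 1e-8)
  expect_equal(m$b, ref$b, tolerance = 1e-8)
})

test_that("OPLS with one orthogonal component matches two-component PLS predictions", {
  set.seed(42)
  X <- matrix(rnorm(12 * 10), 12, 10)
  y <- rep(c(0, 1), 6)
  m <- fit_opls(X, y, n_orthogonal = 1)
  yhat_opls <- predict(m, X) - mean(y)
  yhat_pls2 <- pls_multi_ref(uv_ref(X), y - mean(y), 2)
  expect_equal(yhat_opls, yhat_pls2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("model diagnostics satisfy their structural invariants", {
  set.seed(43)
  X <- matrix(rnorm(14 * 9), 14, 9, dimnames = list(NULL, paste0("m", 1:9)))
  y <- rep(c(0, 1), 7)
  m <- fit_opls(X, y, n_orthogonal = 2)
  # predictive score orthogonal to every orthogonal score
  expect_lt(max(abs(crossprod(m$t, m$t_o))), 1e-8)
  expect_true(m$r2y_cum >= 0 && m$r2y_cum <= 1)
  expect_true(all(abs(m$pcorr) <= 1 + 1e-12))
  expect_equal(sum(m$vip^2), ncol(X), tolerance = 1e-8)
  expect_true(m$r2x >= 0 && m$r2x <= 1 + 1e-8)
  # fitted R2Y equals squared correlation of training predictions with y
  expect_equal(cor(predict(m, X), y)^2, m$r2y_cum, tolerance = 1e-8)
  # predicting the training mean gives the mean class value
  expect_equal(unname(predict(m, t(colMeans(X)))), mean(y), tolerance = 1e-10)
})

test_that("a pure discriminator column has p(corr) of exactly 1", {
  y <- rep(c(0, 1), each = 4)
  # every column proportional to y: the predictive score is y itself
  X <- cbind(a = y * 2 + 1, b = y * -3 + 5, c = y * 0.5)
  m <- fit_opls(X, y, n_orthogonal = 0)
  expect_equal(unname(abs(m$pcorr)), rep(1, 3), tolerance = 1e-10)
  expect_equal(unname(m$pcorr["a"]), 1, tolerance = 1e-10)

  # with noise columns the discriminator still dominates
  set.seed(44)
  X2 <- cbind(y_copy = y, matrix(rnorm(8 * 6), 8, 6))
  m2 <- fit_opls(X2, y, n_orthogonal = 1)
  expect_equal(names(which.max(m2$pcorr)), "y_copy")
  expect_gt(m2$pcorr["y_copy"], 0.95)
})

test_that("class-swapped coding mirrors the predictions", {
  set.seed(45)
  X <- matrix(rnorm(60), 10, 6)
  y <- rep(c(0, 1), 5)
  m1 <- fit_opls(X, y, 1)
  m2 <- fit_opls(X, 1 - y, 1)
  expect_equal(predict(m2, X), 1 - predict(m1, X), tolerance = 1e-8)
})

test_that("negating a column flips its p(corr) and CI but not its VIP", {
  set.seed(46)
  X <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(paste0("s", 1:12), paste0("m", 1:6)))
  y <- rep(c(0, 1), 6)
  X2 <- X; X2[, 3] <- -X2[, 3]
  m1 <- fit_opls(X, y, 1); m2 <- fit_opls(X2, y, 1)
  expect_equal(m2$pcorr[3], -m1$pcorr[3], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(m2$vip, m1$vip, tolerance = 1e-8)
  jk1 <- jackknife_ci(X, y, 4, 1); jk2 <- jackknife_ci(X2, y, 4, 1)
  expect_equal(jk2$lower[3], -jk1$upper[3], tolerance = 1e-8)
  expect_equal(jk2$upper[3], -jk1$lower[3], tolerance = 1e-8)
})

test_that("VIP matches the hand-evaluated formula on a small model", {
  set.seed(47)
  X <- matrix(rnorm(10 * 3), 10, 3)
  y <- rep(c(0, 1), 5)
  m <- fit_opls(X, y, 1)
  W <- cbind(m$w, m$w_o)
  q <- c(m$r2y_cum, m$r2x_orth)
  by_hand <- sqrt(3 * (W[, 1]^2 * q[1] + W[, 2]^2 * q[2]) / (q[1] + q[2]))
  expect_equal(unname(m$vip), unname(by_hand), tolerance = 1e-10)

  # one-variable model: normalisation forces VIP = 1
  m1 <- fit_opls(cbind(v = rnorm(10) + y), y, 0)
  expect_equal(unname(m1$vip), 1, tolerance = 1e-10)

  # identical copies share VIP 1 by symmetry
  v <- rnorm(10) + 2 * y
  mc <- fit_opls(cbind(a = v, b = v, c = v), y, 0)
  expect_equal(unname(mc$vip), rep(1, 3), tolerance = 1e-10)
})

test_that("cross-validation folds partition samples and support leave-one-out", {
  set.seed(48)
  X <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(paste0("s", 1:10), NULL))
  y <- rep(c(0, 1), each = 5)
  cv <- suppressWarnings(cross_validate(X, y, n_folds = 4, n_orthogonal = 1))
  expect_setequal(names(cv$folds), paste0("s", 1:10))
  expect_true(all(table(cv$folds) >= 2))
  # deterministic assignment
  cv2 <- suppressWarnings(cross_validate(X, y, n_folds = 4, n_orthogonal = 1))
  expect_identical(cv$cv_predicted_y, cv2$cv_predicted_y)

  loo <- cross_validate(X, y, n_folds = 10, n_orthogonal = 1)
  expect_equal(loo$n_folds, 10)
  # each leave-one-out prediction excludes exactly its own sample:
  # removing any other sample's value must not change fold membership
  expect_identical(sort(unname(loo$folds)), 1:10)
  expect_error(cross_validate(X, y, n_folds = 1), "at least 2")
})

test_that("predicted-y group test behaves like a Welch t-test", {
  set.seed(49)
  co <- tiny_cohort(seed = 49, n = 9)
  cv <- cross_validate(co$peaks$areas, co$meta$group, 7, 1)
  y <- co$meta$group
  out <- predicted_y_test(cv, y)
  ref <- welch_ref(cv$cv_predicted_y[y == 1], cv$cv_predicted_y[y == 0])
  expect_equal(out$p_value, ref$p_value, tolerance = 1e-10)
  # invariant under affine transforms of the predictions
  cv_shift <- cv
  cv_shift$cv_predicted_y <- 3 * cv$cv_predicted_y - 7
  expect_equal(predicted_y_test(cv_shift, y)$p_value, out$p_value,
               tolerance = 1e-10)
  # identical distributions give p near 1
  cv_null <- cv
  cv_null$cv_predicted_y[y == 1] <- rep(c(0.4, 0.6), len = 9)
  cv_null$cv_predicted_y[y == 0] <- rep(c(0.4, 0.6), len = 9)
  expect_gt(predicted_y_test(cv_null, y)$p_value, 0.99)
})

test_that("jack-knife intervals are centred, ordered and symmetric for duplicates", {
  set.seed(50)
  X <- matrix(rnorm(14 * 6), 14, 6, dimnames = list(paste0("s", 1:14), paste0("m", 1:6)))
  y <- rep(c(0, 1), 7)
  jk <- jackknife_ci(X, y, n_folds = 7, n_orthogonal = 1)
  expect_true(all(jk$lower <= jk$estimate & jk$estimate <= jk$upper))
  expect_identical(jk$significant, jk$lower > 0 | jk$upper < 0)

  X2 <- cbind(X, m1_copy = X[, 1])
  jk2 <- jackknife_ci(X2, y, n_folds = 7, n_orthogonal = 1)
  expect_equal(jk2[jk2$metabolite == "m1_copy", -1],
               jk2[jk2$metabolite == "m1", -1],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(jackknife_ci(X, y, n_folds = 2), "at least 3")
})

test_that("planted block effects are recovered with the truth's signs", {
  hit <- numeric(30)
  for (s in 1:30) {
    co <- generate_cohort(sim_config(n_per_group = 9, seed = 700 + s))
    m <- fit_opls(co$peaks$areas, co$meta$group, 1)
    aff <- co$truth$direction != "NONE"
    want <- ifelse(co$truth$direction[aff] == "UP", 1, -1)
    hit[s] <- mean(sign(m$pcorr[aff]) == want)
  }
  expect_gte(mean(hit), 0.9)
})

test_that("strongly affected metabolites earn fully negative jack-knife intervals", {
  frac <- numeric(20)
  for (s in 1:20) {
    co <- generate_cohort(sim_config(n_per_group = 9, effect_down = 0.6,
                                     seed = 600 + s))
    jk <- jackknife_ci(co$peaks$areas, co$meta$group, 7, 1)
    down <- names(co$truth$direction)[co$truth$direction == "DOWN"]
    frac[s] <- mean(jk$upper[match(down, jk$metabolite)] < 0)
  }
  expect_gte(mean(frac), 0.8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_opls(X, rep(1, 5)), "both classes")
  expect_error(fit_opls(X, c(0, 1, 2, 0, 1)), "0/1")
  expect_error(fit_opls(X, rep(c(0, 1), len = 5), n_orthogonal = 4), "rank")
})
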