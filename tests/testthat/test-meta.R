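test_that("combining identical batch profiles returns that profile", {
  set.seed(61)
  prof <- rnorm(20)
  names(prof) <- sprintf("m%02d", 1:20)
  for (k in c(2, 3, 5)) {
    cp <- combine_pcorr(rep(list(prof), k))
    cosine <- sum(cp$p1 * prof) / sqrt(sum(cp$p1^2) * sum(prof^2))
    expect_gt(cosine, 0.9999)
  }
})

test_that("the combined profile is sign-anchored to the first batch", {
  set.seed(62)
  prof <- rnorm(15)
  names(prof) <- sprintf("m%02d", 1:15)
  cp <- combine_pcorr(list(prof, -prof))
  expect_gt(cor(cp$p1, prof), 0.9999)
  expect_equal(sum(cp$p1^2), 1, tolerance = 1e-10)
  # swapping batch order flips the anchor
  cp2 <- combine_pcorr(list(-prof, prof))
  expect_gt(cor(cp2$p1, -prof), 0.9999)
})

test_that("metabolites missing from a batch are mean-imputed, not dropped", {
  p1 <- c(a = 0.9, b = -0.8, c = 0.5)
  p2 <- c(a = 0.8, b = -0.9)          # c not detected in batch 2
  cp <- combine_pcorr(list(p1, p2))
  expect_setequal(cp$metabolite_ids, c("a", "b", "c"))
  expect_true(is.na(cp$pcorr_matrix[2, "c"]))
  expect_gt(cp$p1["c"], 0)
  expect_error(combine_pcorr(list(c(a = 1, b = 1))), "at least 2 batches")
  expect_error(combine_pcorr(list(c(a = 1, b = 1), c(c = 1, d = 1))),
               "fewer than 2 metabolites")
})

test_that("combined profiles recover the shared truth across batches", {
  hit <- numeric(20)
  for (s in 1:20) {
    profs <- lapply(1:3, function(b) {
      co <- generate_cohort(sim_config(n_per_group = 9, seed = 900 + s * 10 + b))
      fit_opls(co$peaks$areas, co$meta$group, 1)$pcorr
    })
    co <- generate_cohort(sim_config(n_per_group = 9, seed = 900 + s * 10 + 1))
    cp <- combine_pcorr(profs)
    aff <- co$truth$direction != "NONE"
    want <- ifelse(co$truth$direction[aff] == "UP", 1, -1)
    hit[s] <- mean(sign(cp$p1[aff]) == want)
  }
  expect_gte(mean(hit), 0.85)
})

test_that("direction calls combine the CI and VIP screens", {
  jk <- data.frame(metabolite = c("a", "b", "c", "d"),
                   estimate = c(-0.3, -0.3, 0.4, 0.1),
                   se = 0.1,
                   lower = c(-0.5, -0.5, 0.2, -0.2),
                   upper = c(-0.1, -0.1, 0.6, 0.3),
                   significant = c(TRUE, TRUE, TRUE, FALSE))
  v <- c(a = 1.2, b = 0.5, c = 1.0, d = 2.0)
  calls <- call_directions(jk, v)
  expect_identical(unname(calls), c("DOWN", "NONE", "UP", "NONE"))
  expect_error(call_directions(jk, v[1:3]), "different metabolites")
})

test_that("null cohorts are called NONE almost everywhere", {
  rate <- numeric(40)
  for (s in 1:40) {
    co <- generate_cohort(sim_config(n_per_group = 9, affected_down = 0,
                                     affected_up = 0, seed = 5000 + s))
    m <- fit_opls(co$peaks$areas, co$meta$group, 1)
    jk <- jackknife_ci(co$peaks$areas, co$meta$group, 7, 1)
    rate[s] <- mean(call_directions(jk, m$vip) == "NONE")
  }
  expect_gte(mean(rate), 0.9)
})

test_that("concordance counts matches against any comparison study", {
  calls <- matrix(c("UP",   "UP",   "DOWN",
                    "DOWN", "NONE", "DOWN",
                    "NONE", "UP",   "UP",
                    "MISSING", "UP", "UP"),
                  4, 3, byrow = TRUE,
                  dimnames = list(c("m1", "m2", "m3", "m4"),
                                  c("main", "v1", "v2")))
  dt <- direction_table(calls)
  cc <- concordance(dt, "main", c("v1", "v2"))
  expect_equal(cc$n_evaluated, 3)   # m4 MISSING in reference
  expect_equal(cc$n_congruent, 2)   # m1 (v1), m2 (v2); m3 matches nothing
  expect_equal(cc$fraction, 2 / 3)
  expect_error(concordance(dt, "nope"), "unknown reference")

  # all-identical studies are fully congruent
  same <- direction_table(matrix("UP", 3, 3,
                                 dimnames = list(paste0("m", 1:3),
                                                 c("main", "v1", "v2"))))
  expect_equal(concordance(same, "main")$fraction, 1)
})

test_that("concordance is invariant to metabolite order and UP/DOWN relabelling", {
  t5 <- load_fixture("table5")
  base <- concordance(t5, "main")
  shuffled <- direction_table(t5$calls[rev(rownames(t5$calls)), ])
  expect_equal(concordance(shuffled, "main")$n_congruent, base$n_congruent)
  flipped <- t5$calls
  flipped[t5$calls == "UP"] <- "DOWN"
  flipped[t5$calls == "DOWN"] <- "UP"
  expect_equal(concordance(direction_table(flipped), "main")$n_congruent,
               base$n_congruent)
})

test_that("pairwise agreement respects the changed-only filter", {
  calls <- matrix(c("UP",   "UP",
                    "DOWN", "UP",
                    "NONE", "NONE",
                    "DOWN", "DOWN",
                    "UP",   "MISSING",
                    "NONE", "UP"),
                  6, 2, byrow = TRUE,
                  dimnames = list(paste0("m", 1:6), c("A", "B")))
  dt <- direction_table(calls)
  # all non-missing: m1, m3, m4 agree among m1..m4, m6 -> 3/5
  expect_equal(as.numeric(pairwise_agreement(dt, "A", "B")), 3 / 5)
  # changed-only: eligible m1, m2, m4 -> 2/3
  expect_equal(as.numeric(pairwise_agreement(dt, "A", "B", changed_only = TRUE)),
               2 / 3)
  # identical studies agree fully; opposite studies never
  same <- direction_table(calls[, c(1, 1)] |>
                            `colnames<-`(c("A", "B")))
  expect_equal(as.numeric(pairwise_agreement(same, "A", "B")), 1)
  opp <- direction_table(matrix(c("UP", "DOWN", "DOWN", "UP"), 2, 2,
                                dimnames = list(c("m1", "m2"), c("A", "B"))))
  expect_equal(as.numeric(pairwise_agreement(opp, "A", "B")), 0)
  expect_error(pairwise_agreement(direction_table(
    matrix(c("MISSING", "UP"), 1, 2,
           dimnames = list("m1", c("A", "B")))), "A", "B"), "no eligible")
})
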