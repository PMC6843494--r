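#' Configuration for the synthetic cohort generator
#'
#' Defines a two-arm GC-MS-like plasma cohort on the log scale: a fixed
#' per-metabolite base abundance, a correlated block of metabolites
#' lowered by the intervention (amino-acid-like), a correlated block
#' raised by it (saturated-fatty-acid-like), per-sample multiplicative
#' dilution shared by metabolites and internal standards, per-batch
#' multiplicative offsets, and optional metabolites missing per batch.
#' Defaults emulate the shape of a main-study batch: 95 identified
#' metabolites, 11 internal standards, a fifth of the metabolites
#' lowered to 0.8-fold and 8% raised to 1.25-fold, residual biological
#' plus analytical log-SD of 0.18 (the level at which a 0.8-fold group
#' difference reaches two-sample t-test p of about 0.02 with nine
#' subjects per arm, the operating point such studies report for their
#' significant metabolites), dilution log-SD 0.3 and batch log-SD 0.1.
#'
#' @param n_per_group Subjects per arm (at least 2).
#' @param n_metabolites,n_standards Panel sizes (defaults 95, 11).
#' @param affected_down,affected_up Fractions of metabolites lowered /
#'   raised in the active arm (defaults 0.2, 0.08); counts are
#'   `floor(fraction * n_metabolites)`.
#' @param effect_down,effect_up Multiplicative group effects
#'   (defaults 0.8, 1.25).
#' @param block_correlation Within-block correlation of affected
#'   metabolites (default 0.5).
#' @param met_sd Residual log-SD of each metabolite (default 0.18).
#' @param is_sd Analytical log-SD of internal standards (default 0.05).
#' @param dilution_sd SD of the per-sample log dilution (default 0.3).
#' @param batch_shift_sd SD of the per-batch log offset (default 0.1).
#' @param n_batches Number of analytical batches (default 1).
#' @param missing_rate Probability that a metabolite is missing from a
#'   batch entirely (default 0).
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group, n_metabolites = 95, n_standards = 11,
                       affected_down = 0.2, affected_up = 0.08,
                       effect_down = 0.8, effect_up = 1.25,
                       block_correlation = 0.5, met_sd = 0.18, is_sd = 0.05,
                       dilution_sd = 0.3, batch_shift_sd = 0.1,
                       n_batches = 1, missing_rate = 0, seed = 1) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_metabolites = as.integer(n_metabolites),
              n_standards = as.integer(n_standards),
              affected_down = affected_down, affected_up = affected_up,
              effect_down = effect_down, effect_up = effect_up,
              block_correlation = block_correlation,
              met_sd = met_sd, is_sd = is_sd,
              dilution_sd = dilution_sd, batch_shift_sd = batch_shift_sd,
              n_batches = as.integer(n_batches),
              missing_rate = missing_rate, seed = as.integer(seed))
  if (cfg$n_per_group < 2) stop("n_per_group must be at least 2")
  fr <- c(cfg$affected_down, cfg$affected_up, cfg$missing_rate,
          cfg$block_correlation)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$affected_down + cfg$affected_up > 1)
    stop("affected fractions exceed 1 in total")
  if (cfg$effect_down <= 0 || cfg$effect_up <= 0) stop("effect sizes must be > 0")
  if (any(c(cfg$met_sd, cfg$is_sd, cfg$dilution_sd, cfg$batch_shift_sd) < 0))
    stop("standard deviations must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic two-arm cohort with known ground truth
#'
#' Draws peak areas as
#' `exp(base + block latent + group effect + batch offset + dilution + noise)`,
#' so all areas are strictly positive. The first
#' `floor(affected_down * K)` metabolites form a correlated
#' amino-acid-like block lowered in the active arm; the next
#' `floor(affected_up * K)` a saturated-fatty-acid-like block raised by
#' it. Internal standards carry the same dilution and batch terms but no
#' group effect. The same seed gives a bit-identical cohort.
#'
#' @param config A [sim_config()].
#' @return List with `peaks` ([peak_table()]), `meta` ([sample_meta()]),
#'   `standards` ([is_table()]) and `truth` (class `sim_truth`:
#'   per-metabolite `direction`, per-sample `dilution` factors,
#'   per-batch `batch_offset` factors, and the generating `config`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  K <- config$n_metabolites
  n <- 2L * config$n_per_group
  n_down <- floor(config$affected_down * K)
  n_up <- floor(config$affected_up * K)
  direction <- rep("NONE", K)
  direction[seq_len(n_down)] <- "DOWN"
  if (n_up > 0) direction[n_down + seq_len(n_up)] <- "UP"
  met_ids <- sprintf("%s_%03d",
                     c(rep("aa_like", n_down), rep("sfa_like", n_up),
                       rep("met", K - n_down - n_up)),
                     seq_len(K))
  sample_ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c(0L, 1L), each = config$n_per_group)
  # cyclic assignment keeps the arms balanced within each batch
  batch <- sprintf("batch%d", rep_len(seq_len(config$n_batches), n))

  base <- stats::rnorm(K, mean = log(1e5), sd = 1)
  dilution <- stats::rnorm(n, 0, config$dilution_sd)
  batch_offset <- stats::setNames(
    stats::rnorm(config$n_batches, 0, config$batch_shift_sd),
    sprintf("batch%d", seq_len(config$n_batches)))
  rho <- config$block_correlation
  z_down <- stats::rnorm(n)
  z_up <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * K), n, K)
  noise <- config$met_sd * eps
  if (n_down > 0)
    noise[, seq_len(n_down)] <-
      config$met_sd * (sqrt(rho) * z_down +
                       sqrt(1 - rho) * eps[, seq_len(n_down), drop = FALSE])
  if (n_up > 0)
    noise[, n_down + seq_len(n_up)] <-
      config$met_sd * (sqrt(rho) * z_up +
                       sqrt(1 - rho) * eps[, n_down + seq_len(n_up), drop = FALSE])
  effect <- rep(0, K)
  effect[direction == "DOWN"] <- log(config$effect_down)
  effect[direction == "UP"] <- log(config$effect_up)
  log_area <- matrix(base, n, K, byrow = TRUE) +
    outer(group, effect) +
    batch_offset[batch] + dilution + noise
  areas <- exp(log_area)
  dimnames(areas) <- list(sample_ids, met_ids)

  missing <- matrix(FALSE, n, K, dimnames = dimnames(areas))
  if (config$missing_rate > 0) {
    for (b in names(batch_offset)) {
      drop_met <- stats::runif(K) < config$missing_rate
      missing[batch == b, drop_met] <- TRUE
    }
  }

  base_is <- stats::rnorm(config$n_standards, mean = log(5e5), sd = 0.5)
  is_noise <- matrix(stats::rnorm(n * config$n_standards, 0, config$is_sd),
                     n, config$n_standards)
  is_areas <- exp(matrix(base_is, n, config$n_standards, byrow = TRUE) +
                    batch_offset[batch] + dilution + is_noise)
  dimnames(is_areas) <- list(sample_ids,
                             sprintf("IS%02d", seq_len(config$n_standards)))

  truth <- structure(list(
    direction = stats::setNames(direction, met_ids),
    dilution = stats::setNames(exp(dilution), sample_ids),
    batch_offset = exp(batch_offset),
    config = config), class = "sim_truth")

  list(peaks = peak_table(areas, missing = missing),
       meta = sample_meta(sample_ids, group, timepoint = "T18",
                          batch_id = batch),
       standards = is_table(is_areas),
       truth = truth)
}

#' Plant a non-compliant control sample
#'
#' Emulates a placebo participant who self-supplemented: the chosen
#' placebo sample's affected metabolites receive the active-arm
#' multiplicative effect (equivalent to re-drawing the sample under the
#' active-group model with the same noise realisation). The operation
#' is exactly invertible with [unplant_outlier()].
#'
#' @param table The cohort's [peak_table()].
#' @param meta Its [sample_meta()].
#' @param truth The `sim_truth` from [generate_cohort()].
#' @param sample_id Placebo sample to convert.
#' @param profile Outlier profile; only `"crossover"` is defined.
#' @return The modified [peak_table()].
#' @export
plant_outlier <- function(table, meta, truth, sample_id,
                          profile = c("crossover")) {
  profile <- match.arg(profile)
  if (!sample_id %in% rownames(table$areas))
    stop("unknown sample id: ", sample_id)
  g <- meta$group[match(sample_id, meta$sample_id)]
  if (is.na(g) || g != 0L) stop("sample ", sample_id, " is not in the placebo group")
  cfg <- truth$config
  f <- rep(1, length(truth$direction))
  f[truth$direction == "DOWN"] <- cfg$effect_down
  f[truth$direction == "UP"] <- cfg$effect_up
  areas <- table$areas
  areas[sample_id, ] <- areas[sample_id, ] * f
  peak_table(areas, missing = table$missing)
}

#' @rdname plant_outlier
#' @export
unplant_outlier <- function(table, truth, sample_id) {
  cfg <- truth$config
  f <- rep(1, length(truth$direction))
  f[truth$direction == "DOWN"] <- cfg$effect_down
  f[truth$direction == "UP"] <- cfg$effect_up
  areas <- table$areas
  areas[sample_id, ] <- areas[sample_id, ] / f
  peak_table(areas, missing = table$missing)
}
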