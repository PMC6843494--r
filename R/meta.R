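#' Combine per-batch p(corr) profiles into one loading profile
#'
#' Stacks the per-batch p(corr) vectors into a batches x metabolites
#' matrix and fits a one-component PCA with no scaling and no centring;
#' the first loading vector `p1` (unit norm) serves as the combined
#' metabolic profile of the batches. Metabolites missing from a batch
#' are mean-imputed across the remaining batches before the PCA. The
#' sign of `p1` is fixed so that its correlation with the first batch's
#' profile is positive.
#'
#' @param profiles A list of named numeric vectors (one per batch,
#'   names = metabolites) or a batches x metabolites matrix with `NA`
#'   for metabolites absent from a batch.
#' @return Object of class `combined_profile` with `metabolite_ids`,
#'   the assembled `pcorr_matrix`, and `p1`.
#' @export
combine_pcorr <- function(profiles) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    mets <- Reduce(union, lapply(profiles, names))
    if (is.null(mets)) stop("profiles must be named by metabolite")
    M <- t(vapply(profiles, function(p) {
      out <- stats::setNames(rep(NA_real_, length(mets)), mets)
      out[names(p)] <- p
      out
    }, numeric(length(mets))))
    if (is.null(rownames(M))) rownames(M) <- sprintf("batch%d", seq_len(nrow(M)))
  } else {
    M <- as.matrix(profiles)
    if (is.null(colnames(M))) stop("profile matrix needs metabolite column names")
  }
  if (nrow(M) < 2) stop("need at least 2 batches")
  shared <- colSums(!is.na(M)) == nrow(M)
  if (sum(shared) < 2) stop("batches share fewer than 2 metabolites")
  imputed <- apply(M, 2, function(col) {
    if (all(is.na(col))) stop("metabolite observed in no batch")
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  imputed <- matrix(imputed, nrow = nrow(M), dimnames = dimnames(M))
  pc <- nipals_pca(imputed, n_components = 1)
  p1 <- drop(pc$loadings)
  names(p1) <- colnames(M)
  first <- M[1, ]
  obs <- !is.na(first)
  if (sum(first[obs] * p1[obs]) < 0) p1 <- -p1
  structure(list(metabolite_ids = colnames(M), pcorr_matrix = M, p1 = p1),
            class = "combined_profile")
}

#' Call per-metabolite effect directions from model diagnostics
#'
#' A metabolite is called `UP` when its jack-knife confidence interval
#' lies entirely above 0 and its VIP reaches the threshold, `DOWN` when
#' the interval lies entirely below 0 with sufficient VIP, and `NONE`
#' otherwise — combining the two significance screens used for the
#' study's per-metabolite calls.
#'
#' @param jk A [jackknife_ci()] result.
#' @param vip Named per-metabolite VIP vector over the same metabolites.
#' @param vip_threshold VIP cutoff (default 0.8).
#' @return Named character vector of calls in `UP`/`DOWN`/`NONE`.
#' @export
call_directions <- function(jk, vip, vip_threshold = 0.8) {
  if (!setequal(jk$metabolite, names(vip)))
    stop("jack-knife result and VIP cover different metabolites")
  v <- vip[jk$metabolite]
  call <- ifelse(jk$lower > 0 & v >= vip_threshold, "UP",
          ifelse(jk$upper < 0 & v >= vip_threshold, "DOWN", "NONE"))
  stats::setNames(call, jk$metabolite)
}

#' Cross-study effect-direction concordance
#'
#' A metabolite is evaluated when it has a non-`MISSING` call in the
#' reference study, and counted congruent when its reference symbol
#' (`UP`, `DOWN` or `NONE` — "change, or no change") equals the symbol
#' in at least one comparison study; `MISSING` never matches.
#'
#' @param dirs A [direction_table()].
#' @param reference Study label used as reference.
#' @param comparisons Study labels compared against it; defaults to all
#'   other studies in the table.
#' @return List of class `concordance_summary`: `n_evaluated`,
#'   `n_congruent`, `fraction`, and `per_pair` congruence counts against
#'   each comparison study.
#' @export
concordance <- function(dirs, reference,
                        comparisons = setdiff(colnames(dirs$calls), reference)) {
  calls <- dirs$calls
  if (!reference %in% colnames(calls)) stop("unknown reference study: ", reference)
  if (!all(comparisons %in% colnames(calls)))
    stop("unknown comparison study label")
  ref <- calls[, reference]
  evaluated <- ref != "MISSING"
  match_any <- rep(FALSE, nrow(calls))
  per_pair <- stats::setNames(integer(length(comparisons)), comparisons)
  for (cs in comparisons) {
    hit <- evaluated & calls[, cs] != "MISSING" & calls[, cs] == ref
    per_pair[cs] <- sum(hit)
    match_any <- match_any | hit
  }
  structure(list(n_evaluated = sum(evaluated),
                 n_congruent = sum(match_any),
                 fraction = sum(match_any) / sum(evaluated),
                 per_pair = per_pair),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance: %d of %d evaluated metabolites congruent (%.1f%%)\n",
              x$n_congruent, x$n_evaluated, 100 * x$fraction))
  invisible(x)
}

#' Pairwise direction agreement between two studies
#'
#' Fraction of metabolites with equal direction symbols in the two
#' studies. `MISSING` calls are always excluded; with
#' `changed_only = TRUE` the comparison is restricted to metabolites
#' showing a change (non-`NONE`) in both studies.
#'
#' @param dirs A [direction_table()].
#' @param study_a,study_b Study labels.
#' @param changed_only Restrict to metabolites changed in both studies.
#' @return Fraction agreeing, with attributes `n_eligible`, `n_agree`.
#' @export
pairwise_agreement <- function(dirs, study_a, study_b, changed_only = FALSE) {
  calls <- dirs$calls
  if (!all(c(study_a, study_b) %in% colnames(calls)))
    stop("unknown study label")
  a <- calls[, study_a]
  b <- calls[, study_b]
  eligible <- a != "MISSING" & b != "MISSING"
  if (changed_only) eligible <- eligible & a != "NONE" & b != "NONE"
  if (!any(eligible)) stop("no eligible metabolites for the comparison")
  agree <- eligible & a == b
  structure(sum(agree) / sum(eligible),
            n_eligible = sum(eligible), n_agree = sum(agree))
}
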