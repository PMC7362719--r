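#' Split a case into contiguous equal time segments
#'
#' @param case a \linkS4class{PsgCase}.
#' @param n_segments number of segments (default 4: four 15-s segments
#'   of a 60-s case, the last ending at awakening).
#' @return list of \linkS4class{PsgCase}, ids suffixed `#seg<j>`.
#' @export
splitSegments <- function(case, n_segments = 4L) {
  n <- nrow(samples(case))
  if (n %% n_segments != 0L) {
    .fail("case %s: duration %.4g s not divisible into %d equal segments",
          caseId(case), duration(case), n_segments)
  }
  len <- n %/% n_segments
  lapply(seq_len(n_segments), function(j) {
    PsgCase(sprintf("%s#seg%d", caseId(case), j),
            samples(case)[((j - 1L) * len + 1L):(j * len), , drop = FALSE],
            samplingRate(case), channelInfo(case))
  })
}

.checkLabels <- function(labels_m, labels_n) {
  if (is.null(names(labels_m)) || is.null(names(labels_n)) ||
      !setequal(names(labels_m), names(labels_n))) {
    .fail("segment labelings must be named by the same case set")
  }
  labels_n[names(labels_m)]
}

#' Agreement fraction between two binary segment labelings
#'
#' `pi1` is the proportion of cases keeping their cluster co-membership
#' under the identity mapping of cluster names; `pi2 = 1 - pi1` is the
#' proportion under the swapped mapping.
#'
#' @param labels_m,labels_n named vectors of two-valued cluster labels
#'   over the same case set.
#' @return `pi1` in [0, 1].
#' @export
agreementFraction <- function(labels_m, labels_n) {
  labels_n <- .checkLabels(labels_m, labels_n)
  um <- sort(unique(as.character(labels_m)))
  un <- sort(unique(as.character(labels_n)))
  if (length(um) > 2L || length(un) > 2L) .fail("labelings must use at most 2 labels")
  mean((labels_m == um[1]) == (labels_n == un[1]))
}

#' Temporal consistency of clustering between two segments
#'
#' `C = 2 * |pi1 - 0.5|`, invariant to relabeling clusters in either
#' input: 0 for chance-level agreement, 1 for identical (or exactly
#' complementary) labelings.
#'
#' @inheritParams agreementFraction
#' @return consistency value in [0, 1].
#' @export
consistency <- function(labels_m, labels_n) {
  2 * abs(agreementFraction(labels_m, labels_n) - 0.5)
}

#' Monte-Carlo null bound for temporal consistency
#'
#' Upper `1 - alpha/n_comparisons` quantile of `C` under independent
#' uniformly random balanced labelings of both segments.
#'
#' @param n_cases number of cases.
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param alpha significance level in (0, 1).
#' @param n_comparisons Bonferroni divisor.
#' @param seed RNG seed.
#' @param size size of cluster 1 in the null labelings (default
#'   balanced, `floor(n_cases/2)`).
#' @return the null bound (scalar).
#' @export
consistencyNull <- function(n_cases, reps = 2000L, alpha = 0.05,
                            n_comparisons = 1L, seed = 1L,
                            size = n_cases %/% 2L) {
  if (reps < 1000L) .fail("reps must be >= 1000")
  if (alpha <= 0 || alpha >= 1) .fail("alpha must be in (0, 1)")
  withSeed(seed, {
    cvals <- vapply(seq_len(reps), function(r) {
      a <- seq_len(n_cases) %in% sample.int(n_cases, size)
      b <- seq_len(n_cases) %in% sample.int(n_cases, size)
      2 * abs(mean(a == b) - 0.5)
    }, 0)
    as.numeric(quantile(cvals, 1 - alpha / n_comparisons))
  })
}

#' Exact two-tailed binomial test on segment agreement
#'
#' Tests the count of co-membership agreements under the better of the
#' two label mappings against Binomial(N, 0.5).
#'
#' @inheritParams agreementFraction
#' @return two-tailed p-value.
#' @export
consistencyBinomial <- function(labels_m, labels_n) {
  p1 <- agreementFraction(labels_m, labels_n)
  n <- length(labels_m)
  k <- round(max(p1, 1 - p1) * n)
  binomialTwoTailed(n, k)
}

#' One-tailed permutation test for a rising consistency trend
#'
#' Tests whether the mean of the last half of time-ordered consistency
#' values exceeds the mean of the first half, by permuting the
#' assignment of values to time positions.
#'
#' @param C_values consistency values ordered by segment-pair time.
#' @param n_perm number of random permutations (ignored when
#'   `exhaustive`).
#' @param seed RNG seed.
#' @param exhaustive enumerate all permutations (requires short input).
#' @return one-tailed p: fraction of permutations with
#'   `mean(last) - mean(first) >= observed`.
#' @export
trendPermutationTest <- function(C_values, n_perm = 2000L, seed = 1L,
                                 exhaustive = FALSE) {
  n <- length(C_values)
  if (n < 2L) .fail("need at least 2 consistency values")
  h <- n %/% 2L
  stat <- function(v) mean(v[(n - h + 1L):n]) - mean(v[seq_len(h)])
  obs <- stat(C_values)
  if (exhaustive) {
    if (n > 8L) .fail("exhaustive enumeration limited to n <= 8")
    perms <- .allPerms(n)
    stats <- apply(perms, 1L, function(p) stat(C_values[p]))
    return(mean(stats >= obs - 1e-12))
  }
  if (n_perm < 1L) .fail("n_perm must be >= 1")
  withSeed(seed, {
    stats <- vapply(seq_len(n_perm), function(i) stat(sample(C_values)), 0)
    mean(stats >= obs - 1e-12)
  })
}

.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Screen candidate feature sets by temporal consistency
#'
#' For each feature set: every case is split into `n_segments` equal
#' segments, each segment's cohort is clustered independently with
#' [runCombinationClustering()], and the consistency of adjacent-segment
#' clusterings (1v2, 2v3, 3v4) is reported together with the
#' Monte-Carlo null bound and exact binomial flags.  The report ranks
#' sets by mean adjacent consistency; the choice among them is left to
#' the analyst.
#'
#' @param cases list of \linkS4class{PsgCase}.
#' @param set_names feature sets to screen (>= 2 unless you only want a
#'   one-row report).
#' @param config an [ensembleConfig()] for the per-segment clusterings.
#' @param n_segments segments per case (default 4).
#' @param null_reps,alpha null-model settings; the Bonferroni divisor is
#'   `length(set_names) * (n_segments - 1)`.
#' @param ... passed to [extractFeatures()].
#' @return data.frame: set, C per adjacent pair, mean C, null bound,
#'   significance flags; sorted by mean C (descending).
#' @export
screenFeatureSets <- function(cases, set_names, config = ensembleConfig(),
                              n_segments = 4L, null_reps = 2000L, alpha = 0.05,
                              ...) {
  segs <- lapply(cases, splitSegments, n_segments = n_segments)
  nAdj <- n_segments - 1L
  bound <- consistencyNull(length(cases), reps = null_reps, alpha = alpha,
                           n_comparisons = length(set_names) * nAdj,
                           seed = subSeed(config$seed, 77L))
  rows <- lapply(seq_along(set_names), function(si) {
    nm <- set_names[si]
    labs <- lapply(seq_len(n_segments), function(j) {
      fm <- extractFeatures(lapply(segs, `[[`, j), nm, ...)
      cfg <- config; cfg$seed <- subSeed(config$seed, si * 101L + j)
      res <- runCombinationClustering(fm, cfg)
      lab <- res$result$labels
      names(lab) <- sub("#seg\\d+$", "", names(lab))
      lab
    })
    cv <- vapply(seq_len(nAdj), function(j) consistency(labs[[j]], labs[[j + 1L]]), 0)
    pv <- vapply(seq_len(nAdj), function(j) consistencyBinomial(labs[[j]], labs[[j + 1L]]), 0)
    out <- data.frame(set = nm, stringsAsFactors = FALSE)
    for (j in seq_len(nAdj)) out[[sprintf("C%d%d", j, j + 1L)]] <- cv[j]
    out$mean_C <- mean(cv)
    out$null_bound <- bound
    out$above_null <- all(cv > bound)
    out$min_binom_p <- min(pv)
    out
  })
  rep <- do.call(rbind, rows)
  rep[order(-rep$mean_C), , drop = FALSE]
}
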