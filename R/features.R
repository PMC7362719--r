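#' @useDynLib dreamcatcher, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' FeatureMatrix construction and accessors
#'
#' `FeatureMatrix()` builds the cases-by-features container (stored
#' features-by-cases as a \linkS4class{SummarizedExperiment} assay);
#' `featureValues()` returns the cases-by-features matrix;
#' `transforms()` the provenance flags.
#'
#' @param values numeric cases-by-features matrix with rownames = case
#'   ids and colnames = namespaced feature names.
#' @param transforms character flags, e.g. `"log"`, `"studentized"`.
#' @return a \linkS4class{FeatureMatrix}.
#' @name FeatureMatrix
#' @aliases FeatureMatrix-class
#' @export
FeatureMatrix <- function(values, transforms = character()) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    .fail("values needs case ids as rownames and feature names as colnames")
  }
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(values = t(values)))
  new("FeatureMatrix", se, transforms = transforms)
}

#' @rdname FeatureMatrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "values"))
})

#' @rdname FeatureMatrix
#' @export
setMethod("transforms", "FeatureMatrix", function(x) x@transforms)

#' @rdname FeatureMatrix
#' @export
caseIds <- function(x) colnames(SummarizedExperiment::assay(x, "values"))

setMethod("show", "FeatureMatrix", function(object) {
  a <- SummarizedExperiment::assay(object, "values")
  cat(sprintf("FeatureMatrix: %d cases x %d features%s\n", ncol(a), nrow(a),
              if (length(object@transforms))
                paste0(" [", paste(object@transforms, collapse = ", "), "]") else ""))
})

#' The candidate feature-set names
#'
#' The eight Step-1 screening sets plus the composite Step-2 and Step-5
#' sets.
#' @return character vector of valid `name` arguments for
#'   [extractFeatureSet()].
#' @export
featureSetNames <- function() {
  c("powerband", "powerfine", "autocorr", "permen", "apen",
    "eogrms", "emgrms", "siclari", "step2_50", "step5")
}

#' Permutation entropy (ordinal-pattern Shannon entropy, nats)
#'
#' Bandt-Pompe permutation entropy: the Shannon entropy of the empirical
#' distribution of ordinal patterns of `order` consecutive (delayed)
#' samples.  Ties are broken by order of occurrence.  Ranges from 0
#' (monotone signal) to `log(factorial(order))`.
#'
#' @param x numeric vector, length >= `order * delay + 1`.
#' @param order pattern length (default 3).
#' @param delay sample delay between pattern elements (default 1).
#' @return entropy in nats.
#' @export
permutationEntropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x)
  if (n < order * delay + 1L) .fail("series too short for permutation entropy")
  nPat <- n - (order - 1L) * delay
  emb <- vapply(seq_len(order), function(j) x[(seq_len(nPat) - 1L) + (j - 1L) * delay + 1L],
                numeric(nPat))
  if (order == 1L) return(0)
  ranks <- matrix(1L, nPat, order)
  for (j in seq_len(order)) {
    for (k in seq_len(order)) {
      if (k == j) next
      less <- emb[, k] < emb[, j] | (emb[, k] == emb[, j] & k < j)
      ranks[, j] <- ranks[, j] + less
    }
  }
  code <- as.vector((ranks - 1L) %*% order^(seq_len(order) - 1L))
  p <- tabulate(code + 1L, nbins = order^order)
  p <- p[p > 0] / nPat
  -sum(p * log(p))
}

#' Approximate entropy (Pincus ApEn)
#'
#' `ApEn(m, r) = Phi_m - Phi_{m+1}` with Chebyshev distance, template
#' self-matches included.  A zero-variance input returns 0 by
#' convention.
#'
#' @param x numeric vector, length > m + 1.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return ApEn value (nats).
#' @export
approximateEntropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1L) .fail("series too short for ApEn")
  if (!is.finite(r) || r <= 0) {
    if (sd(x) == 0) return(0)
    .fail("r must be positive")
  }
  apEnCpp(as.numeric(x), as.integer(m), r)
}

# pooled RMS across a modality's channels over consecutive windows
.windowRms <- function(x, rate, win_s) {
  n <- nrow(x)
  nw <- floor(n / (win_s * rate))
  vapply(seq_len(nw), function(k) {
    idx <- ((k - 1) * win_s * rate + 1):(k * win_s * rate)
    sqrt(mean(x[idx, , drop = FALSE]^2))
  }, 0)
}

.featPowerFine <- function(case, window_s, overlap) {
  if (samplingRate(case) < 99) .fail("powerfine needs rate >= 99 Hz (bins to 49.5 Hz)")
  est <- welchLogPsd(case, window_s, overlap, fmax = 49.5)
  sel <- est$freq >= 0.5 - 1e-9
  m <- est$psd[sel, , drop = FALSE]
  fr <- est$freq[sel]
  v <- as.vector(m)
  names(v) <- as.vector(outer(fr, colnames(m),
                              function(f, ch) sprintf("powerfine/%s/%gHz", ch, f)))
  v
}

.featPowerBand <- function(case, window_s, overlap) {
  est <- welchPsd(modalitySamples(case, "EEG"), samplingRate(case), window_s, overlap)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                sigma = c(12, 15), beta = c(15, 30), gamma = c(30, 49.5))
  ch <- colnames(modalitySamples(case, "EEG"))
  out <- c()
  for (b in names(bands)) {
    bp <- log(pmax(.bandPower(est, bands[[b]][1], bands[[b]][2]), 1e-300))
    names(bp) <- sprintf("powerband/%s/%s", ch, b)
    out <- c(out, bp)
  }
  out
}

.featAutoCorr <- function(case) {
  x <- modalitySamples(case, "EEG")
  rate <- samplingRate(case)
  maxLag <- as.integer(2 * rate)
  out <- c()
  for (ch in colnames(x)) {
    a <- as.vector(acf(x[, ch], lag.max = maxLag, plot = FALSE)$acf)[-1]
    below <- which(a < exp(-1))
    zero <- which(a < 0)
    v <- c(decay = (if (length(below)) below[1] else maxLag) / rate,
           firstzero = (if (length(zero)) zero[1] else maxLag) / rate,
           lag1 = a[1])
    names(v) <- sprintf("autocorr/%s/%s", ch, c("decay", "firstzero", "lag1"))
    out <- c(out, v)
  }
  out
}

.featEntropy <- function(case, kind, entropy_decimate) {
  x <- modalitySamples(case, "EEG")
  dec <- max(1L, as.integer(entropy_decimate))
  x <- x[seq(1L, nrow(x), by = dec), , drop = FALSE]
  v <- vapply(colnames(x), function(ch) {
    if (kind == "permen") permutationEntropy(x[, ch]) else approximateEntropy(x[, ch])
  }, 0)
  names(v) <- sprintf("%s/%s", kind, colnames(x))
  v
}

.featRms <- function(case, modality) {
  x <- modalitySamples(case, modality)
  rate <- samplingRate(case)
  qlen <- nrow(x) %/% 4L
  out <- c()
  for (ch in colnames(x)) {
    v <- vapply(1:4, function(q) {
      sqrt(mean(x[((q - 1) * qlen + 1):(q * qlen), ch]^2))
    }, 0)
    names(v) <- sprintf("%srms/%s/q%d", tolower(modality), ch, 1:4)
    out <- c(out, v)
  }
  out
}

# The 11 hot-zone emulation features: regional band-averaged log power
# over trailing windows.  Bands follow the low 1-12 / high 18-50 Hz
# convention; the electrode groups and windows are documented defaults
# (configurable), since they emulate source-level regions on a scalp
# montage.
.featSiclari <- function(case, window_s, overlap) {
  rate <- samplingRate(case)
  n <- nrow(samples(case))
  fhi <- min(50, floor(rate / 2))
  tail_est <- function(sec) {
    idx <- (n - sec * rate + 1):n
    x <- modalitySamples(case, "EEG")[idx, , drop = FALSE]
    est <- welchPsd(x, rate, window_s, overlap)
    est$psd <- log(pmax(est$psd, 1e-300)); est$log <- TRUE
    colnames(est$psd) <- colnames(x)
    est
  }
  e20 <- tail_est(20); e40 <- tail_est(40); e60 <- tail_est(60)
  grp <- function(est, group, lo, hi) {
    mean(.bandLogPsd(est, lo, hi)[electrodeGroup(group, channelInfo(case))])
  }
  allCh <- function(est, lo, hi) mean(.bandLogPsd(est, lo, hi))
  v <- c(
    "siclari/whole/low/20s"  = allCh(e20, 1, 12),
    "siclari/whole/high/20s" = allCh(e20, 18, fhi),
    "siclari/po/low/20s" = grp(e20, "parieto-occipital", 1, 12),
    "siclari/po/low/40s" = grp(e40, "parieto-occipital", 1, 12),
    "siclari/po/low/60s" = grp(e60, "parieto-occipital", 1, 12),
    "siclari/frontal/high/20s" = grp(e20, "frontal", 18, fhi),
    "siclari/frontal/high/40s" = grp(e40, "frontal", 18, fhi),
    "siclari/frontal/high/60s" = grp(e60, "frontal", 18, fhi),
    "siclari/occipital/high/20s" = grp(e20, "occipital", 18, fhi),
    "siclari/temporal/high/20s" = grp(e20, "temporal", 18, fhi),
    "siclari/fusiform/high/20s" = grp(e20, "fusiform-proxy", 18, fhi)
  )
  v
}

#' Extract one named feature set from a case
#'
#' Implements the candidate feature families: `powerfine` (99 natural-log
#' PSD bins, 0.5--49.5 Hz in 0.5-Hz steps, per EEG channel: 2475 features
#' on the standard montage), `powerband` (log integrated power in the six
#' classical bands per channel), `autocorr` (1/e decay time, first zero
#' crossing, lag-1 value per channel), `permen` / `apen` (one entropy per
#' channel), `eogrms` / `emgrms` (RMS per 15-s quarter per channel),
#' `siclari` (11 hot-zone emulation features), `step2_50`
#' ([assembleStep2Features()]) and `step5` ([extractStep5Features()]).
#'
#' @param case a \linkS4class{PsgCase}.
#' @param name one of [featureSetNames()].
#' @param window_s,overlap Welch settings (2 s Hann, 80% overlap gives the
#'   0.5-Hz native resolution of `powerfine`).
#' @param entropy_decimate decimation factor applied before the entropy
#'   features (default 4, i.e. entropies are computed at rate/4).
#' @return named numeric feature vector.
#' @export
extractFeatureSet <- function(case, name, window_s = 2, overlap = 0.8,
                              entropy_decimate = 4L) {
  name <- match.arg(name, featureSetNames())
  switch(name,
    powerfine = .featPowerFine(case, window_s, overlap),
    powerband = .featPowerBand(case, window_s, overlap),
    autocorr  = .featAutoCorr(case),
    permen    = .featEntropy(case, "permen", entropy_decimate),
    apen      = .featEntropy(case, "apen", entropy_decimate),
    eogrms    = .featRms(case, "EOG"),
    emgrms    = .featRms(case, "EMG"),
    siclari   = .featSiclari(case, window_s, overlap),
    step2_50  = assembleStep2Features(case, window_s, overlap),
    step5     = extractStep5Features(case, window_s, overlap)
  )
}

#' Extract a feature set across a cohort
#'
#' @param cases list of \linkS4class{PsgCase}.
#' @param name feature set name.
#' @param ... passed to [extractFeatureSet()].
#' @return a \linkS4class{FeatureMatrix} (rows ordered as `cases`).
#' @export
extractFeatures <- function(cases, name, ...) {
  rows <- lapply(cases, extractFeatureSet, name = name, ...)
  nm <- names(rows[[1]])
  m <- do.call(rbind, lapply(rows, function(r) r[nm]))
  rownames(m) <- vapply(cases, caseId, "")
  colnames(m) <- nm
  logged <- name %in% c("powerfine", "powerband", "siclari", "step2_50", "step5")
  FeatureMatrix(m, transforms = if (logged) "log" else character())
}

#' Assemble the 50-feature Step-2 set
#'
#' 19 geometrically spaced scalp-average log-PSD bins spanning
#' 0.5--49.5 Hz (bin value = mean of the across-electrode-average
#' natural-log PSD within the bin, at 0.125-Hz native resolution),
#' the 11 hot-zone emulation features, and for each of EMG and EOG the
#' 0/25/50/75/100th percentiles of 1-s-window RMS within each of the two
#' 30-s halves (5 x 2 x 2 = 20).
#'
#' @param case a \linkS4class{PsgCase} (60 s).
#' @param window_s,overlap Welch settings for the hot-zone features.
#' @return named numeric vector of exactly 50 features.
#' @export
assembleStep2Features <- function(case, window_s = 2, overlap = 0.8) {
  rate <- samplingRate(case)
  est <- welchLogPsd(case, window_s = 8, overlap = overlap, fmax = 49.5)
  scalp <- rowMeans(est$psd)
  edges <- exp(seq(log(0.5), log(49.5), length.out = 20L))
  keep <- est$freq >= 0.5 - 1e-9
  fr <- est$freq[keep]; scalp <- scalp[keep]
  bin <- findInterval(fr, edges, rightmost.closed = TRUE)
  psd19 <- vapply(seq_len(19L), function(b) {
    if (!any(bin == b)) .fail("empty log-spaced PSD bin %d; increase resolution", b)
    mean(scalp[bin == b])
  }, 0)
  names(psd19) <- sprintf("scalppsd/bin%02d/%.2fHz", seq_len(19L),
                          sqrt(edges[-20] * edges[-1]))
  sic <- .featSiclari(case, window_s, overlap)
  halves <- list(seg1 = 1:(nrow(samples(case)) %/% 2L),
                 seg2 = (nrow(samples(case)) %/% 2L + 1L):nrow(samples(case)))
  pq <- c(0, 0.25, 0.5, 0.75, 1)
  modFeats <- function(modality) {
    x <- modalitySamples(case, modality)
    out <- c()
    for (h in names(halves)) {
      rms <- .windowRms(x[halves[[h]], , drop = FALSE], rate, 1)
      v <- quantile(rms, pq, names = FALSE)
      names(v) <- sprintf("%s/%s/p%d", tolower(modality), h, pq * 100)
      out <- c(out, v)
    }
    out
  }
  c(psd19, sic, modFeats("EMG"), modFeats("EOG"))
}

#' Extract the three Step-5 literature features
#'
#' Band-averaged natural-log PSD over electrode groups:
#' `SBP_low` = 1--4 Hz over parieto-occipital electrodes, `SBP_high` =
#' 20--50 Hz over parieto-occipital + lateral-frontal + temporal
#' electrodes, `Scarpelli` = 0.50--4.75 Hz over left fronto-temporal
#' electrodes.
#'
#' @param case a \linkS4class{PsgCase}.
#' @param window_s,overlap Welch settings.
#' @return named numeric vector `c(SBP_low, SBP_high, Scarpelli)`.
#' @export
extractStep5Features <- function(case, window_s = 2, overlap = 0.8) {
  rate <- samplingRate(case)
  est <- welchLogPsd(case, window_s, overlap)
  ch <- channelInfo(case)
  fhi <- min(50, floor(rate / 2))
  g <- function(groups, lo, hi) {
    chans <- unique(unlist(lapply(groups, electrodeGroup, channels = ch)))
    mean(.bandLogPsd(est, lo, hi)[chans])
  }
  c(SBP_low = g("parieto-occipital", 1, 4),
    SBP_high = g(c("parieto-occipital", "lateral-frontal", "temporal"), 20, fhi),
    Scarpelli = g("left-fronto-temporal", 0.50, 4.75))
}

#' Studentize a feature matrix
#'
#' Centers and scales every feature to mean 0 and sample SD 1 across
#' cases.  Zero-variance features become all-zeros with a warning.
#' Idempotent; records the `"studentized"` transform flag.
#'
#' @param fm a \linkS4class{FeatureMatrix} with >= 2 cases.
#' @return studentized \linkS4class{FeatureMatrix}.
#' @export
studentize <- function(fm) {
  v <- featureValues(fm)
  if (nrow(v) < 2L) .fail("studentization needs at least 2 cases")
  mu <- colMeans(v)
  sdv <- apply(v, 2L, sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s) set to all-zeros", sum(zero)))
    sdv[zero] <- 1
  }
  out <- sweep(sweep(v, 2L, mu), 2L, sdv, "/")
  out[, zero] <- 0
  FeatureMatrix(out, transforms = unique(c(transforms(fm), "studentized")))
}
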