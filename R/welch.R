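#' Welch power spectral density estimate
#'
#' Welch's averaged-periodogram PSD with Hann windows, mean-detrended
#' segments and one-sided density scaling: summing `psd * df` over bins
#' recovers the signal variance (Parseval consistency) up to windowing
#' edge effects.
#'
#' @param x numeric vector or samples-by-channels matrix (uV).
#' @param rate sampling rate (Hz).
#' @param window_s window length in seconds; `window_s * rate` must be an
#'   integer number of samples >= 2 and no longer than the record.
#' @param overlap fractional window overlap in (0, 1); default 0.8.
#' @param fmax optional upper frequency cut (Hz).
#' @return object of class `PsdEstimate`: list with `freq` (bin centers,
#'   Hz), `psd` (bins x channels, uV^2/Hz), `window_s`, `overlap`,
#'   `log` (FALSE).
#' @export
welchPsd <- function(x, rate, window_s = 2, overlap = 0.8, fmax = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  nper <- window_s * rate
  if (abs(nper - round(nper)) > 1e-9 || nper < 2) {
    .fail("window_s * rate must be an integer >= 2 samples")
  }
  nper <- as.integer(round(nper))
  if (nper > n) .fail("Welch window (%d samples) longer than record (%d)", nper, n)
  if (overlap <= 0 || overlap >= 1) .fail("overlap must be in (0, 1)")
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq.int(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq.int(0L, nper - 1L) / nper))
  U <- sum(w^2)
  idx <- outer(seq_len(nper) - 1L, starts, `+`)
  nb <- nper %/% 2L + 1L
  psd <- matrix(0, nb, ncol(x))
  for (j in seq_len(ncol(x))) {
    seg <- matrix(x[idx, j], nper, length(starts))
    seg <- sweep(seg, 2L, colMeans(seg))
    P <- Mod(stats::mvfft(seg * w))^2
    p <- rowMeans(P[seq_len(nb), , drop = FALSE]) / (rate * U)
    p[-1L] <- p[-1L] * 2
    if (nper %% 2L == 0L) p[nb] <- p[nb] / 2
    psd[, j] <- p
  }
  freq <- (seq_len(nb) - 1L) * rate / nper
  if (!is.null(fmax)) {
    keep <- freq <= fmax + 1e-9
    freq <- freq[keep]; psd <- psd[keep, , drop = FALSE]
  }
  structure(list(freq = freq, psd = psd, window_s = window_s,
                 overlap = overlap, log = FALSE),
            class = "PsdEstimate")
}

#' Natural-log Welch PSD of a case's channels
#'
#' @param case a \linkS4class{PsgCase}.
#' @param window_s,overlap,fmax as in [welchPsd()].
#' @param modality restrict to one modality (default EEG).
#' @return `PsdEstimate` with `psd` on the natural-log scale
#'   (`log = TRUE`); a floor of 1e-300 guards all-zero channels.
#' @export
welchLogPsd <- function(case, window_s = 2, overlap = 0.8, fmax = NULL,
                        modality = "EEG") {
  x <- modalitySamples(case, modality)
  est <- welchPsd(x, samplingRate(case), window_s, overlap, fmax)
  est$psd <- log(pmax(est$psd, 1e-300))
  est$log <- TRUE
  colnames(est$psd) <- colnames(x)
  est
}

# mean natural-log PSD over bins with centers in [lo, hi], per channel
.bandLogPsd <- function(est, lo, hi) {
  stopifnot(isTRUE(est$log))
  sel <- est$freq >= lo - 1e-9 & est$freq <= hi + 1e-9
  if (!any(sel)) .fail("no PSD bins inside band [%g, %g] Hz", lo, hi)
  colMeans(est$psd[sel, , drop = FALSE])
}

# natural log of integrated band power (sum psd * df) per channel
.bandPower <- function(est, lo, hi) {
  stopifnot(!isTRUE(est$log))
  sel <- est$freq >= lo - 1e-9 & est$freq <= hi + 1e-9
  if (!any(sel)) .fail("no PSD bins inside band [%g, %g] Hz", lo, hi)
  df <- est$freq[2] - est$freq[1]
  colSums(est$psd[sel, , drop = FALSE]) * df
}
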