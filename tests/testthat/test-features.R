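test_that("Welch PSD matches analytic oracles", {
  fs <- 100
  tt <- seq_len(60 * fs) / fs
  est <- welchPsd(sin(2 * pi * 10 * tt), fs)
  df <- est$freq[2] - est$freq[1]
  # unit-amplitude sine: total power 1/2, concentrated at 10 Hz
  expect_lt(abs(sum(est$psd) * df - 0.5) / 0.5, 0.05)
  expect_equal(est$freq[which.max(est$psd)], 10)
  # all-zero channel
  expect_true(all(welchPsd(numeric(600), fs)$psd == 0))
  # white noise: flat at sigma^2 / (fs/2), Monte Carlo
  sims <- withr::with_seed(1, vapply(1:30, function(i) {
    e <- welchPsd(rnorm(60 * fs, sd = 2), fs)
    mean(e$psd)
  }, 0))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - 4 / (fs / 2)), 3 * se)
  # Parseval consistency on a stationary mixed signal
  x <- withr::with_seed(2, rnorm(60 * fs)) + 3 * sin(2 * pi * 4 * tt)
  x <- x - mean(x)
  e <- welchPsd(x, fs)
  expect_lt(abs(sum(e$psd) * df - var(x)) / var(x), 0.10)
  expect_error(welchPsd(rnorm(100), fs, window_s = 2), "longer than record")
})

test_that("the fine-power set has 2475 features consistent with welchLogPsd", {
  cs <- quickCase()
  v <- extractFeatureSet(cs, "powerfine")
  expect_length(v, 2475L)
  est <- welchLogPsd(cs, 2, 0.8, fmax = 49.5)
  expect_equal(unname(v["powerfine/Cz/12.5Hz"]),
               unname(est$psd[est$freq == 12.5, "Cz"]))
  expect_equal(unname(v["powerfine/O1/0.5Hz"]),
               unname(est$psd[est$freq == 0.5, "O1"]))
  # deterministic
  expect_identical(v, extractFeatureSet(cs, "powerfine"))
})

test_that("permutation entropy matches hand enumeration and its bounds", {
  expect_equal(permutationEntropy(1:100), 0)
  # six ordinal pairs: 4 up, 2 down
  expect_equal(permutationEntropy(c(4, 7, 9, 10, 6, 11, 3), order = 2),
               -(4 / 6 * log(4 / 6) + 2 / 6 * log(2 / 6)), tolerance = 1e-12)
  x <- withr::with_seed(3, runif(20000))
  expect_lt(abs(permutationEntropy(x, 3) - log(6)) / log(6), 0.02)
  expect_equal(permutationEntropy(x, 2), permutationEntropy(-x, 2))
  expect_equal(permutationEntropy(rep(1, 50)), 0)  # ties: single pattern
  expect_error(permutationEntropy(1:3, order = 4), "too short")
})

test_that("approximate entropy follows the Pincus convention", {
  expect_equal(approximateEntropy(rep(2, 60)), 0)
  # a perfect period-2 signal is maximally regular up to O(1/N) edge terms
  alt <- rep(c(1, -1), 40)
  expect_lt(abs(approximateEntropy(alt, m = 2, r = 0.1)), 1e-3)
  # independent R oracle: brute-force template counting on a short series
  apenOracle <- function(x, m, r) {
    phi <- function(mm) {
      N <- length(x) - mm + 1
      tpl <- sapply(seq_len(N), function(i) x[i:(i + mm - 1)])
      cnt <- vapply(seq_len(N), function(i) {
        sum(vapply(seq_len(N), function(j) {
          max(abs(tpl[, i] - tpl[, j])) <= r
        }, TRUE))
      }, 0L)
      mean(log(cnt / N))
    }
    phi(m) - phi(m + 1)
  }
  x <- withr::with_seed(4, rnorm(80))
  expect_equal(approximateEntropy(x, 2, 0.2 * sd(x)),
               apenOracle(x, 2, 0.2 * sd(x)), tolerance = 1e-12)
  # irregularity ordering: noise above a sine of equal variance
  n <- withr::with_seed(5, rnorm(600))
  s <- sin(2 * pi * 5 * seq_len(600) / 100) * sd(n) / sqrt(0.5)
  expect_gt(approximateEntropy(n, 2, 0.2 * sd(n)),
            approximateEntropy(s, 2, 0.2 * sd(s)))
})

test_that("the Step-2 set has exactly 50 features with the expected structure", {
  cs <- quickCase()
  v <- assembleStep2Features(cs)
  expect_length(v, 50L)
  expect_length(grep("^scalppsd/", names(v)), 19L)
  expect_length(grep("^siclari/", names(v)), 11L)
  expect_length(grep("^emg/", names(v)), 10L)
  expect_length(grep("^eog/", names(v)), 10L)
  # constant EMG channels: every percentile equals |a|
  x <- samples(cs)
  x[, channelInfo(cs)$modality == "EMG"] <- -3
  v2 <- assembleStep2Features(PsgCase("ID01", x, samplingRate(cs), channelInfo(cs)))
  expect_true(all(abs(v2[grep("^emg/", names(v2))] - 3) < 1e-12))
  # doubling all EEG amplitudes raises every scalp-average log bin by 2 ln 2
  x3 <- samples(cs)
  eeg <- channelInfo(cs)$modality == "EEG"
  x3[, eeg] <- 2 * x3[, eeg]
  v3 <- assembleStep2Features(PsgCase("ID01", x3, samplingRate(cs), channelInfo(cs)))
  expect_equal(unname(v3[1:19] - v[1:19]), rep(2 * log(2), 19), tolerance = 1e-9)
})

test_that("Step-5 features respect band and region separation", {
  cs <- quickCase()
  v0 <- extractStep5Features(cs)
  expect_named(v0, c("SBP_low", "SBP_high", "Scarpelli"))
  # adding a 2-Hz tone to parieto-occipital channels raises SBP_low only
  x <- samples(cs)
  po <- channelInfo(cs)$name %in% electrodeGroup("parieto-occipital")
  tone <- 30 * sin(2 * pi * 2 * seq_len(nrow(x)) / samplingRate(cs))
  x[, po] <- x[, po] + tone
  v1 <- extractStep5Features(PsgCase("ID01", x, samplingRate(cs), channelInfo(cs)))
  expect_gt(v1["SBP_low"], v0["SBP_low"])
  expect_equal(v1["SBP_high"], v0["SBP_high"], tolerance = 1e-9)
  # left-right mirroring changes Scarpelli but not the symmetric features
  ch <- channelInfo(cs)
  mirror <- ch$name
  swap <- function(a, b) { mirror[match(c(a, b), ch$name)] <<- c(b, a) }
  for (pr in list(c("Fp1", "Fp2"), c("F7", "F8"), c("F3", "F4"), c("FT7", "FT8"),
                  c("FC3", "FC4"), c("T7", "T8"), c("C3", "C4"), c("P7", "P8"),
                  c("P3", "P4"), c("O1", "O2"))) swap(pr[1], pr[2])
  xm <- samples(cs)[, match(mirror, ch$name)]
  colnames(xm) <- ch$name
  vm <- extractStep5Features(PsgCase("ID01", xm, samplingRate(cs), ch))
  expect_equal(vm["SBP_low"], v0["SBP_low"], tolerance = 1e-9)
  expect_equal(vm["SBP_high"], v0["SBP_high"], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(vm["Scarpelli"], v0["Scarpelli"], tolerance = 1e-6)))
})

test_that("studentization normalizes, is idempotent and flags zero variance", {
  m <- withr::with_seed(6, matrix(rnorm(40), 10,
                                  dimnames = list(sprintf("ID%02d", 1:10),
                                                  paste0("f", 1:4))))
  fm <- FeatureMatrix(m)
  st <- studentize(fm)
  v <- featureValues(st)
  expect_true(all(abs(colMeans(v)) < 1e-10))
  expect_equal(unname(apply(v, 2, sd)), rep(1, 4))
  expect_equal(featureValues(studentize(st)), v, tolerance = 1e-12)
  expect_true("studentized" %in% transforms(st))
  m[, 2] <- 7
  expect_warning(z <- studentize(FeatureMatrix(m)), "zero-variance")
  expect_true(all(featureValues(z)[, 2] == 0))
})

test_that("per-channel RMS and autocorrelation summaries are well-formed", {
  cs <- quickCase()
  expect_length(extractFeatureSet(cs, "eogrms"), 8L)
  expect_length(extractFeatureSet(cs, "emgrms"), 8L)
  ac <- extractFeatureSet(cs, "autocorr")
  expect_length(ac, 75L)
  expect_true(all(ac[grep("/decay$", names(ac))] > 0))
})
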