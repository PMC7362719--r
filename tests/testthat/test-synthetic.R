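test_that("a default cohort has 54 cases of 29 channels, deterministically", {
  coh <- strongCohort()
  expect_length(coh$cases, 54L)
  expect_true(all(vapply(coh$cases, function(cs) nrow(channelInfo(cs)), 0L) == 29L))
  expect_true(all(vapply(coh$cases, duration, 0) == 60))
  expect_identical(vapply(coh$cases, caseId, ""), sort(coh$key@key$case_id))
  # bit-identical regeneration under the same config
  cfg <- cohortConfig(seed = 101L, rate = 100L, participant_effect_sd = 0,
                      spectral_exponent_sd = 0, condition_delta_ratio = 4,
                      condition_high_ratio = 2)
  again <- synthCohort(cfg)
  expect_identical(samples(again$cases[[10]]), samples(coh$cases[[10]]))
  # different seed permutes the truth table
  other <- synthCohort(cohortConfig(seed = 11L, rate = 100L))
  expect_false(identical(other$truth$case_id, coh$truth$case_id))
})

test_that("unit condition ratios make the two conditions identically generated", {
  cfg <- cohortConfig(rate = 100L, condition_delta_ratio = 1,
                      condition_high_ratio = 1)
  st <- participantState(cfg, 1L)
  a <- synthCase(cfg, st, "dreamful", seed = 5L)
  b <- synthCase(cfg, st, "dreamless", seed = 5L)
  expect_identical(samples(a), samples(b))
})

test_that("condition names never appear inside analysis-visible objects", {
  coh <- strongCohort()
  for (cs in coh$cases[c(1, 30)]) {
    expect_false(any(grepl("dreamful|dreamless", unlist(channelInfo(cs)))))
    expect_false(grepl("dreamful|dreamless", caseId(cs)))
  }
  expect_false(any(grepl("dreamful|dreamless", unlist(coh$key@key))))
})

test_that("the injected delta-band factor is recovered as log 4 by Welch power", {
  # paired Monte Carlo: same background, only the condition filter differs
  cfg <- cohortConfig(rate = 100L, participant_effect_sd = 0,
                      spectral_exponent_sd = 0, condition_delta_ratio = 4,
                      condition_high_ratio = 1, noise_sd = 0)
  st <- participantState(cfg, 1L)
  po <- electrodeGroup("parieto-occipital")
  diffs <- vapply(1:60, function(i) {
    dl <- synthCase(cfg, st, "dreamless", seed = 3000L + i)
    df <- synthCase(cfg, st, "dreamful", seed = 3000L + i)
    f <- function(cs) {
      est <- welchPsd(modalitySamples(cs, "EEG")[, po], 100, 2, 0.8)
      # interior of the injected 0.5-4 Hz band: bins within half a
      # window-mainlobe (0.5 Hz) of the filter edges mix filtered and
      # unfiltered power by spectral leakage, diluting the factor
      sel <- est$freq >= 1.25 & est$freq <= 3.25
      log(mean(colSums(est$psd[sel, ]) * 0.5))
    }
    f(dl) - f(df)
  }, 0)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - log(4)), 3 * se + 0.02)
})

test_that("no systematic condition factor leaks outside the injected bands", {
  cfg <- cohortConfig(rate = 100L, participant_effect_sd = 0,
                      spectral_exponent_sd = 0, condition_delta_ratio = 4,
                      condition_high_ratio = 2, noise_sd = 0)
  st <- participantState(cfg, 1L)
  diffs <- vapply(1:40, function(i) {
    dl <- synthCase(cfg, st, "dreamless", seed = 5000L + i)
    df <- synthCase(cfg, st, "dreamful", seed = 5000L + i)
    f <- function(cs) {
      est <- welchPsd(modalitySamples(cs, "EEG"), 100, 2, 0.8)
      log(mean(colSums(est$psd[est$freq >= 6 & est$freq <= 16, ]) * 0.5))
    }
    f(dl) - f(df)
  }, 0)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 0.02)
})

test_that("the background follows the configured power law", {
  cfg <- cohortConfig(rate = 100L, participant_effect_sd = 0,
                      spectral_exponent_sd = 0, spectral_exponent_mean = 1.5,
                      delta_burst_rate = 0, spindle_density = 0, noise_sd = 0,
                      condition_delta_ratio = 1, condition_high_ratio = 1)
  st <- participantState(cfg, 1L)
  cs <- synthCase(cfg, st, "dreamless", seed = 9L)
  est <- welchPsd(modalitySamples(cs, "EEG"), 100, 4, 0.8)
  sel <- est$freq >= 2 & est$freq <= 30
  slope <- stats::coef(stats::lm(log(rowMeans(est$psd[sel, ])) ~ log(est$freq[sel])))[2]
  expect_lt(abs(slope + 1.5), 0.2)
})

test_that("participant random effects dominate the between/within decomposition", {
  coh <- participantCohort()
  lp <- vapply(coh$cases, function(cs) {
    est <- welchPsd(modalitySamples(cs, "EEG"), samplingRate(cs), 2, 0.8)
    log(mean(colSums(est$psd) * (est$freq[2] - est$freq[1])))
  }, 0)
  pp <- coh$truth$participant[match(vapply(coh$cases, caseId, ""), coh$truth$case_id)]
  fit <- stats::aov(lp ~ factor(pp))
  ms <- summary(fit)[[1]]$`Mean Sq`
  expect_gt(ms[1], ms[2])  # between-participant variance exceeds within
})
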