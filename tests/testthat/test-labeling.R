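test_that("Cohen's d reproduces the study's summary-statistic values", {
  # sleep-duration contrasts reported for the cohort design
  expect_equal(round(cohensDSummary(685, 166, 570, 240)$d, 2), 0.56)
  expect_equal(round(cohensDSummary(8026, 5369, 7264, 3994)$d, 2), 0.16)
  x <- withr::with_seed(60, rnorm(20)); y <- withr::with_seed(61, rnorm(25, 1))
  expect_equal(cohensD(x, y)$d, -cohensD(y, x)$d)
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_error(cohensD(rep(1, 4), rep(1, 4)), "pooled SD")
  # raw equal-n input agrees with the summary convention
  expect_equal(cohensD(x, y[1:20])$d,
               cohensDSummary(mean(x), sd(x), mean(y[1:20]), sd(y[1:20]))$d)
})

.psdFeatureMatrix <- function(dLow, dHigh, seed = 62L, n = 20L) {
  ids <- sprintf("ID%02d", seq_len(n))
  freqs <- seq(0.5, 49.5, by = 0.5)
  v <- withr::with_seed(seed, matrix(rnorm(n * length(freqs)), n,
                                     dimnames = list(ids, sprintf("powerfine/Cz/%gHz", freqs))))
  half <- seq_len(n / 2)
  v[half, freqs >= 1 & freqs <= 12] <- v[half, freqs >= 1 & freqs <= 12] + dLow
  v[half, freqs >= 18 & freqs <= 50] <- v[half, freqs >= 18 & freqs <= 50] + dHigh
  labels <- setNames(rep(c(1L, 2L), each = n / 2), ids)
  list(fm = FeatureMatrix(v, "log"), labels = labels)
}

test_that("the spectral rule labels higher-low/lower-high as dreamless", {
  z <- .psdFeatureMatrix(dLow = 2, dHigh = -2)
  call <- labelBySpectrum(z$labels, z$fm)
  expect_equal(unname(call$mapping["1"]), "dreamless")
  expect_false(call$conflict)
  z2 <- .psdFeatureMatrix(dLow = -2, dHigh = 2)
  expect_equal(unname(labelBySpectrum(z2$labels, z2$fm)$mapping["1"]), "dreamful")
  # identical spectra: no separable contrast
  ids <- sprintf("ID%02d", 1:4)
  same <- matrix(rep(c(1, 2), each = 4), 4,
                 dimnames = list(ids, c("powerfine/Cz/2Hz", "powerfine/Cz/20Hz")))
  expect_error(labelBySpectrum(setNames(c(1L, 1L, 2L, 2L), ids),
                               FeatureMatrix(same, "log")), "no separable")
  # conflicting bands: the larger |d| band decides and the conflict is logged
  z3 <- .psdFeatureMatrix(dLow = 0.3, dHigh = 3)  # both higher in cluster 1
  call3 <- labelBySpectrum(z3$labels, z3$fm)
  expect_true(call3$conflict)
  expect_equal(unname(call3$mapping["1"]), "dreamful")  # high band wins
})

test_that("Step-4 labeling uses the frontal high-frequency contrast", {
  ids <- sprintf("ID%02d", 1:10)
  labels <- setNames(rep(c(1L, 2L), each = 5), ids)
  v <- withr::with_seed(63, matrix(rnorm(30, sd = 0.01), 10,
                                   dimnames = list(ids, c("siclari/frontal/high/20s",
                                                          "siclari/frontal/high/40s",
                                                          "siclari/frontal/high/60s"))))
  v[1:5, ] <- v[1:5, ] - 2   # cluster 1 has suppressed frontal high power
  call <- labelStep4(labels, FeatureMatrix(v, "log"))
  expect_equal(unname(call$mapping["1"]), "dreamless")
  expect_error(labelStep4(labels,
                          FeatureMatrix(matrix(1, 10, 1,
                                               dimnames = list(ids, "siclari/frontal/high/20s")),
                                        "log")),
               "zero|contrast")
  # agreement between rules yields the spectral call
  z <- .psdFeatureMatrix(dLow = 2, dHigh = -2)
  vv <- cbind(featureValues(z$fm),
              "siclari/frontal/high/20s" = rowMeans(featureValues(z$fm)[, 36:40]))
  call2 <- labelStep4(z$labels, FeatureMatrix(vv, "log"))
  expect_equal(unname(call2$mapping["1"]), "dreamless")
})

test_that("Step-5 voting labels groups and honors per-participant centering", {
  ids <- sprintf("ID%02d", 1:54)
  participants <- setNames(rep(sprintf("S%d", 1:9), each = 6), ids)
  groupA <- ids[seq(1, 54, 2)]; groupB <- ids[seq(2, 54, 2)]
  v <- withr::with_seed(64, matrix(rnorm(54 * 3, sd = 0.05), 54,
                                   dimnames = list(ids, c("SBP_low", "SBP_high",
                                                          "Scarpelli"))))
  # group A: delta suppressed, gamma elevated -> dreamful
  v[groupA, "SBP_low"] <- v[groupA, "SBP_low"] - 1
  v[groupA, "SBP_high"] <- v[groupA, "SBP_high"] + 1
  v[groupA, "Scarpelli"] <- v[groupA, "Scarpelli"] - 1
  call <- labelStep5(FeatureMatrix(v, "log"), groupA, groupB, participants)
  expect_equal(unname(call$mapping["A"]), "dreamful")
  # adding a constant to one participant's cases changes nothing
  v2 <- v
  v2[names(participants)[participants == "S2"], ] <-
    v2[names(participants)[participants == "S2"], ] + 100
  call2 <- labelStep5(FeatureMatrix(v2, "log"), groupA, groupB, participants)
  expect_identical(call2$mapping, call$mapping)
  expect_equal(call2$contrasts, call$contrasts, tolerance = 1e-9)
  # identical groups: tie error
  v3 <- v; v3[groupB, ] <- v3[groupA, ]
  expect_error(labelStep5(FeatureMatrix(v3, "log"), groupA, groupB, participants),
               "tie")
})
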