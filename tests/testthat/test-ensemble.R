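test_that("combination sampling enumerates the configured ensemble exactly", {
  cfg <- ensembleConfig(sizes = 2L, combinations = 3L, seed = 9L)
  subs <- sampleCombinations(5L, cfg)
  expect_length(subs, 5L + 3L)
  expect_true(all(lengths(subs[1:5]) == 1L))
  expect_identical(subs, sampleCombinations(5L, cfg))
  cfg23 <- ensembleConfig(sizes = 2:3, combinations = 10L, singletons = TRUE)
  expect_length(sampleCombinations(5L, cfg23), 5L + 20L)
  expect_error(sampleCombinations(1L, cfg), "below the largest")
  expect_error(ensembleConfig(sizes = 2:10), "<= 9")
})

test_that("sub-clustering separates blobs and degrades gracefully", {
  x <- matrix(c(rnorm(10, 0, 0.05), rnorm(10, 5, 0.05)), ncol = 1,
              dimnames = list(sprintf("ID%02d", 1:20), NULL))
  s <- subcluster(x, seed = 3L)
  expect_equal(length(unique(s$labels[1:10])), 1L)
  expect_equal(length(unique(s$labels[11:20])), 1L)
  expect_gt(s$weight, 0.9)
  # scaling a single feature by a positive constant changes nothing
  s2 <- subcluster(x * 100, seed = 3L)
  expect_true(all(s$labels == s2$labels) || all(s$labels == 3L - s2$labels))
  # identical points: one cluster, zero weight
  s3 <- subcluster(matrix(1, 5, 2, dimnames = list(letters[1:5], NULL)))
  expect_equal(s3$weight, 0)
  expect_equal(length(unique(s3$labels)), 1L)
})

test_that("co-association accumulation tallies weighted co-membership", {
  ids <- letters[1:4]
  s1 <- list(labels = setNames(c(1L, 1L, 2L, 2L), ids), weight = 1)
  m1 <- coAssocValues(accumulate(list(s1)))
  expect_true(all(m1[1:2, 1:2] == 1) && all(m1[3:4, 3:4] == 1))
  expect_true(all(m1[1:2, 3:4] == 0))
  # duplicated evidence normalizes away
  expect_equal(coAssocValues(accumulate(list(s1, c(s1[1], weight = 5)))), m1)
  # two orthogonal splits with equal weights: off-diagonals 0 or 0.5
  s2 <- list(labels = setNames(c(1L, 2L, 1L, 2L), ids), weight = 1)
  m <- coAssocValues(accumulate(list(s1, s2)))
  expect_true(all(m[upper.tri(m)] %in% c(0, 0.5)))
  expect_error(accumulate(list(list(labels = s1$labels, weight = 0))), "zero")
})

test_that("co-association invariants hold on ensemble output", {
  v <- withr::with_seed(11, matrix(rnorm(54 * 6), 54,
                                   dimnames = list(sprintf("ID%02d", 1:54),
                                                   paste0("f", 1:6))))
  fm <- FeatureMatrix(v)
  cc <- runCombinationClustering(fm, ensembleConfig(sizes = 2:3, combinations = 10L,
                                                    seed = 2L))
  expect_equal(cc$n_subclusterings, 6L + 20L)
  m <- coAssocValues(cc$coassoc)
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(diag(m) == 1))
  expect_true(validObject(cc$coassoc))
})

test_that("two-cluster extraction picks the cut nearest to half the cases", {
  ids <- sprintf("ID%02d", 1:54)
  block <- function(sizes) {
    m <- matrix(0.05, 54, 54, dimnames = list(ids, ids))
    at <- cumsum(c(0, sizes))
    for (b in seq_along(sizes)) {
      idx <- (at[b] + 1):at[b + 1]
      m[idx, idx] <- 0.95
    }
    diag(m) <- 1
    new("CoAssocMatrix", values = m)
  }
  sizesOf <- function(r) sort(as.integer(table(r$labels)))
  r <- extractTwoClusters(block(c(27, 27)))
  expect_equal(sizesOf(r), c(27L, 27L))
  expect_equal(length(unique(r$labels[1:27])), 1L)
  r2 <- extractTwoClusters(block(c(28, 26)))
  expect_equal(sizesOf(r2), c(26L, 28L))
  # three blocks 20/20/14: nearest-to-half block vs the rest
  r3 <- extractTwoClusters(block(c(20, 20, 14)))
  expect_equal(sizesOf(r3), c(20L, 34L))
  uniform <- new("CoAssocMatrix",
                 values = {
                   m <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
                   diag(m) <- 1; m
                 })
  expect_error(extractTwoClusters(uniform), "not separable")
})

test_that("a singleton-only ensemble on one clean feature equals direct 2-means", {
  x <- withr::with_seed(12, c(rnorm(27, 0, 0.1), rnorm(27, 3, 0.1)))
  ids <- sprintf("ID%02d", 1:54)
  fm <- FeatureMatrix(matrix(x, 54, 1, dimnames = list(ids, "f")))
  cc <- runCombinationClustering(fm, ensembleConfig(sizes = integer(0),
                                                    combinations = 1L,
                                                    singletons = TRUE, seed = 5L))
  km <- withr::with_seed(5, kmeans(x, 2, nstart = 10))
  agree <- mean((cc$result$labels == 1L) == (km$cluster == km$cluster[1]))
  expect_true(agree %in% c(0, 1))
})

test_that("case order permutes labels equivariantly", {
  v <- withr::with_seed(13, matrix(rnorm(20 * 4), 20,
                                   dimnames = list(sprintf("ID%02d", 1:20),
                                                   paste0("f", 1:4))))
  v[1:10, 1] <- v[1:10, 1] + 6
  cfg <- ensembleConfig(sizes = 2L, combinations = 5L, seed = 7L)
  r1 <- runCombinationClustering(FeatureMatrix(v), cfg)$result$labels
  perm <- withr::with_seed(14, sample(20))
  r2 <- runCombinationClustering(FeatureMatrix(v[perm, ]), cfg)$result$labels
  r2 <- r2[names(r1)]
  expect_true(all(r1 == r2) || all(r1 == 3L - r2))
})
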