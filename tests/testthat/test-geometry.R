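.unitRows <- function(n, d, seed) {
  U <- withr::with_seed(seed, matrix(rnorm(n * d), n))
  U / sqrt(rowSums(U^2))
}

.pairedMatrix <- function(n_pairs, d, seed) {
  ids <- sprintf("ID%02d", seq_len(2 * n_pairs))
  v <- withr::with_seed(seed, matrix(rnorm(2 * n_pairs * d), 2 * n_pairs,
                                     dimnames = list(ids, paste0("f", 1:d))))
  pairs <- setNames(rep(sprintf("P%02d", seq_len(n_pairs)), each = 2), ids)
  list(fm = FeatureMatrix(v), pairs = pairs)
}

test_that("pair differences are canonical unit vectors, order-invariant", {
  pm <- .pairedMatrix(27, 50, seed = 20)
  dvs <- pairDifferences(pm$fm, pm$pairs)
  expect_equal(dim(dvs$vectors), c(27L, 50L))
  expect_equal(unname(sqrt(rowSums(dvs$vectors^2))), rep(1, 27))
  # polarity canonical: first non-zero coordinate positive
  expect_true(all(apply(dvs$vectors, 1, function(r) r[which(r != 0)[1]] > 0)))
  # flipping member order changes nothing (members are sorted internally)
  swapped <- setNames(pm$pairs, names(pm$pairs))
  dvs2 <- pairDifferences(pm$fm, swapped[rev(seq_along(swapped))])
  expect_equal(dvs2$vectors[rownames(dvs$vectors), ], dvs$vectors)
  # identical members: excluded with warning
  v <- featureValues(pm$fm)
  v["ID02", ] <- v["ID01", ]
  expect_warning(d3 <- pairDifferences(FeatureMatrix(v), pm$pairs), "identical")
  expect_equal(nrow(d3$vectors), 26L)
})

test_that("mean orientation matches the exhaustive oracle to 1e-9", {
  # degenerate cases first
  u <- c(0.6, 0.8)
  same <- rbind(u, u, -u)
  mo <- meanOrientation(same)
  expect_equal(mo$goodness, 1, tolerance = 1e-12)
  expect_equal(abs(sum(mo$v * u)), 1, tolerance = 1e-12)
  expect_equal(meanOrientation(matrix(c(1, -1, 1), 3, 1))$goodness, 1)
  # random sets across sizes and dimensions vs sign enumeration
  cases <- expand.grid(n = c(3L, 7L, 11L, 15L), d = c(2L, 5L, 9L))
  for (i in seq_len(nrow(cases))) {
    U <- .unitRows(cases$n[i], cases$d[i], seed = 100 + i)
    a <- meanOrientation(U, seed = 1L)
    b <- meanOrientationExact(U)
    expect_lt(abs(a$goodness - b$goodness), 1e-9)
    expect_equal(abs(sum(a$v * b$v)), 1, tolerance = 1e-6)
  }
})

test_that("hyperplane sub-clustering never co-associates pair members", {
  for (s in 1:10) {
    pm <- .pairedMatrix(9, 6, seed = 200 + s)
    dvs <- pairDifferences(studentize(pm$fm), pm$pairs)
    orient <- meanOrientation(dvs, seed = s)
    sc <- hyperplaneSubcluster(dvs, orient)
    for (i in seq_len(nrow(dvs$members))) {
      expect_false(sc$labels[dvs$members$case_a[i]] ==
                     sc$labels[dvs$members$case_b[i]])
    }
  }
})

test_that("hyperplane sides match hand geometry in two dimensions", {
  # two pairs in 2-D: difference directions (1,0) and (0,1);
  # against v = (1,1)/sqrt(2) both projections are positive
  ids <- c("a1", "a2", "b1", "b2")
  v <- matrix(c(1, 0, 0, 0,
                0, 0, 1, 0), 4, 2,
              dimnames = list(ids, c("x", "y")))
  pairs <- setNames(c("P1", "P1", "P2", "P2"), ids)
  dvs <- pairDifferences(FeatureMatrix(v), pairs)
  sc <- hyperplaneSubcluster(dvs, c(1, 1) / sqrt(2))
  expect_equal(unname(sc$labels[c("a1", "b1")]), c(1L, 1L))
  expect_equal(unname(sc$labels[c("a2", "b2")]), c(2L, 2L))
  # all difference vectors parallel to v reproduce a consistent split
  pm <- .pairedMatrix(5, 3, seed = 33)
  vals <- featureValues(pm$fm)
  base <- c(1, 0, 0)
  for (p in unique(pm$pairs)) {
    ids2 <- names(pm$pairs)[pm$pairs == p]
    vals[ids2[1], ] <- rnorm(1) + base
    vals[ids2[2], ] <- vals[ids2[1], ] - 2 * base
  }
  dvs2 <- pairDifferences(FeatureMatrix(vals), pm$pairs)
  sc2 <- hyperplaneSubcluster(dvs2, meanOrientation(dvs2))
  firsts <- sc2$labels[dvs2$members$case_a]
  expect_equal(length(unique(firsts)), 1L)
})

test_that("Monte-Carlo goodness normalization has the right limits", {
  expect_equal(expectedRandomGoodness(10L, 1L), 1)
  expect_equal(expectedRandomGoodness(1L, 50L), 1)
  g <- expectedRandomGoodness(27L, 50L, reps = 1000L, seed = 3L)
  expect_gt(g, 1 / sqrt(50))
  expect_lt(g, 1)
  expect_identical(g, expectedRandomGoodness(27L, 50L, reps = 1000L, seed = 3L))
  expect_equal(mcNormalizeGoodness(0.3, 10L, 1L), 0.3)  # dim 1: raw
})

test_that("condition-group differences behave like group-level pairs", {
  ids <- sprintf("ID%02d", 1:54)
  v <- withr::with_seed(40, matrix(rnorm(54 * 50), 54,
                                   dimnames = list(ids, paste0("f", 1:50))))
  participants <- setNames(rep(sprintf("S%d", 1:9), each = 6), ids)
  groups <- setNames(rep(sprintf("G%02d", 1:18), each = 3), ids)
  dvs <- step4ConditionDifferences(FeatureMatrix(v), groups, participants)
  expect_equal(dim(dvs$vectors), c(9L, 50L))
  expect_equal(unname(sqrt(rowSums(dvs$vectors^2))), rep(1, 9))
  # swapping a participant's two groups leaves the canonical vector alone
  g2 <- groups
  s1 <- names(participants)[participants == "S1"]
  g2[s1] <- setNames(rep(rev(unique(groups[s1])), each = 3), s1)
  dvs2 <- step4ConditionDifferences(FeatureMatrix(v), g2, participants)
  expect_equal(dvs2$vectors, dvs$vectors)
  # zero group difference excluded with a warning
  v2 <- v
  gA <- names(groups)[groups == "G01"]; gB <- names(groups)[groups == "G02"]
  v2[gB, ] <- v2[gA, ]
  expect_warning(d3 <- step4ConditionDifferences(FeatureMatrix(v2), groups,
                                                 participants), "identical")
  expect_equal(nrow(d3$vectors), 8L)
})

test_that("the four-way similarity satisfies the co-association contract", {
  ids <- sprintf("ID%02d", 1:18)
  v <- withr::with_seed(41, matrix(rnorm(18 * 8), 18,
                                   dimnames = list(ids, paste0("f", 1:8))))
  v[seq(1, 18, 2), 1] <- v[seq(1, 18, 2), 1] + 5   # aligned pair structure
  participants <- setNames(rep(sprintf("S%d", 1:3), each = 6), ids)
  pairs <- setNames(rep(sprintf("P%02d", 1:9), each = 2), ids)
  co <- step3Similarity(studentize(FeatureMatrix(v)), pairs, participants,
                        ensembleConfig(sizes = 2:3, combinations = 8L,
                                       singletons = FALSE, seed = 6L))
  m <- coAssocValues(co)
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1) && all(diag(m) == 1))
  expect_true(validObject(co))
  # the aligned structure dominates: first members co-associate
  firsts <- ids[seq(1, 18, 2)]; seconds <- ids[seq(2, 18, 2)]
  expect_gt(mean(m[firsts, firsts][upper.tri(m[firsts, firsts])]),
            mean(m[firsts, seconds][upper.tri(m[firsts, seconds])]))
})
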