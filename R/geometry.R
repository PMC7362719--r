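# Pair-difference geometry: the paired design turns each
# dreamful/dreamless pair into a sign-ambiguous direction in feature
# space; sub-clustering happens by splitting cases with a hyperplane
# normal to the mean orientation of those directions.

.canonicalize <- function(v) {
  nz <- which(abs(v) > 0)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  v
}

#' Pair difference vectors from a Studentized feature matrix
#'
#' Per pair: subtract the two members' feature vectors, canonicalize the
#' arbitrary polarity (first non-zero coordinate >= 0) and normalize to
#' unit length.  Zero difference vectors are excluded with a warning.
#'
#' @param fm a Studentized \linkS4class{FeatureMatrix}.
#' @param pairs named character vector: pair label per case id; every
#'   pair must have exactly 2 cases.
#' @return list of class `DifferenceVectorSet`: `vectors`
#'   (pairs-by-features unit matrix), `members` (data.frame pair /
#'   case_a / case_b in case-id order), `polarity`.
#' @export
pairDifferences <- function(fm, pairs) {
  v <- featureValues(fm)
  if (!all(names(pairs) %in% rownames(v))) .fail("pairs name cases absent from the matrix")
  split_ids <- split(names(pairs), pairs)
  bad <- names(split_ids)[lengths(split_ids) != 2L]
  if (length(bad)) .fail("pairs must have exactly 2 cases: %s", paste(bad, collapse = ", "))
  vecs <- list(); members <- list()
  for (p in names(split_ids)) {
    ids <- sort(split_ids[[p]])
    d <- v[ids[1], ] - v[ids[2], ]
    if (all(d == 0)) {
      warning(sprintf("pair %s has identical members; excluded", p))
      next
    }
    dc <- .canonicalize(d)
    # sign relating the canonical vector back to (case_a - case_b):
    # needed to place the actual members on their geometric sides
    flip <- if (identical(dc, d)) 1L else -1L
    vecs[[p]] <- dc / sqrt(sum(dc^2))
    members[[p]] <- data.frame(pair = p, case_a = ids[1], case_b = ids[2],
                               sign = flip, stringsAsFactors = FALSE)
  }
  if (!length(vecs)) .fail("no non-degenerate pairs")
  structure(list(vectors = do.call(rbind, vecs),
                 members = do.call(rbind, members),
                 polarity = "first-nonzero-positive"),
            class = "DifferenceVectorSet")
}

#' Mean orientation of sign-ambiguous unit vectors
#'
#' Finds the unit vector maximizing the mean absolute cosine similarity
#' to the inputs, by alternating sign-assignment / averaging ascent
#' started from the leading eigenvector of the outer-product sum plus
#' seeded random restarts.  The objective is non-convex; restarts guard
#' against local optima (see [meanOrientationExact()] for the exhaustive
#' reference for small sets).
#'
#' @param vectors a `DifferenceVectorSet` or a rows-as-unit-vectors
#'   matrix.
#' @param restarts additional random initializations (default 10).
#' @param seed RNG seed for the restarts.
#' @param maxit ascent iteration cap per start.
#' @return list of class `OrientationVector`: `v` (unit vector),
#'   `goodness` (mean |cos|), `normalized` (NA until
#'   [mcNormalizeGoodness()]).
#' @export
meanOrientation <- function(vectors, restarts = 10L, seed = 1L, maxit = 200L) {
  U <- if (inherits(vectors, "DifferenceVectorSet")) vectors$vectors else vectors
  if (is.null(dim(U))) U <- matrix(U, nrow = 1L)
  n <- nrow(U); d <- ncol(U)
  if (n < 1L) .fail("need at least one vector")
  snorm <- function(s) sqrt(sum(colSums(U * s)^2))
  # 1-opt / 2-opt local search over sign flips; escapes the shallow
  # fixed points of the bare alternating scheme at negligible cost for
  # small sets
  polish <- function(s) {
    repeat {
      improved <- FALSE
      g0 <- snorm(s)
      for (i in seq_len(n)) {
        s2 <- s; s2[i] <- -s2[i]
        g2 <- snorm(s2)
        if (g2 > g0 + 1e-13) { s <- s2; g0 <- g2; improved <- TRUE }
      }
      if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        s2 <- s; s2[c(i, j)] <- -s2[c(i, j)]
        g2 <- snorm(s2)
        if (g2 > g0 + 1e-13) { s <- s2; g0 <- g2; improved <- TRUE }
      }
      if (!improved) return(s)
    }
  }
  doPolish <- n <= 20L
  ascend <- function(v0) {
    v <- v0 / sqrt(sum(v0^2))
    g <- mean(abs(U %*% v))
    for (it in seq_len(maxit)) {
      s <- as.vector(sign(U %*% v)); s[s == 0] <- 1
      if (doPolish) s <- polish(s)
      w <- colSums(U * s)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      v2 <- w / nw
      g2 <- mean(abs(U %*% v2))
      if (g2 <= g + 1e-14) { v <- v2; break }
      v <- v2; g <- g2
    }
    list(v = v, g = mean(abs(U %*% v)))
  }
  inits <- list(eigen(crossprod(U), symmetric = TRUE)$vectors[, 1])
  if (restarts > 0L) {
    inits <- c(inits, withSeed(seed, lapply(seq_len(restarts), function(i) rnorm(d))))
  }
  best <- NULL
  for (v0 in inits) {
    r <- ascend(v0)
    if (is.null(best) || r$g > best$g) best <- r
  }
  structure(list(v = .canonicalize(best$v), goodness = best$g, normalized = NA_real_),
            class = "OrientationVector")
}

#' Exhaustive mean-orientation reference (small sets)
#'
#' Enumerates all sign patterns (up to global flip) and returns the
#' exact maximizer of the mean absolute cosine similarity.  Limited to
#' 15 vectors.
#'
#' @inheritParams meanOrientation
#' @return as [meanOrientation()].
#' @export
meanOrientationExact <- function(vectors) {
  U <- if (inherits(vectors, "DifferenceVectorSet")) vectors$vectors else vectors
  if (is.null(dim(U))) U <- matrix(U, nrow = 1L)
  n <- nrow(U)
  if (n > 15L) .fail("exhaustive enumeration limited to 15 vectors")
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n - 1L)))
  S <- cbind(1, S)
  G <- S %*% U
  norms <- sqrt(rowSums(G^2))
  i <- which.max(norms)
  v <- G[i, ] / norms[i]
  structure(list(v = .canonicalize(v), goodness = norms[i] / n,
                 normalized = NA_real_),
            class = "OrientationVector")
}

#' Hyperplane sub-clustering of paired cases
#'
#' Splits cases by the side of the hyperplane through the origin normal
#' to the orientation vector: each pair's members sit at +/- half its
#' difference vector around the pair midpoint, so members always land on
#' opposite sides and never co-associate.  An exact tie sends the first
#' member to the positive side.
#'
#' @param dvs a `DifferenceVectorSet`.
#' @param orientation an `OrientationVector` (or unit vector).
#' @return [subcluster()]-style list: `labels` (1 = positive side, 2 =
#'   negative) over all paired cases, `weight` (caller-set, default
#'   `NA`).
#' @export
hyperplaneSubcluster <- function(dvs, orientation) {
  v <- if (inherits(orientation, "OrientationVector")) orientation$v else orientation
  sgn <- if (!is.null(dvs$members$sign)) dvs$members$sign else rep(1L, nrow(dvs$members))
  # undo the polarity canonicalization so the projection is that of the
  # actual (case_a - case_b) difference
  proj <- as.vector(dvs$vectors %*% v) * sgn
  labels <- integer(0)
  for (i in seq_len(nrow(dvs$members))) {
    sideA <- if (proj[i] > 0) 1L else if (proj[i] < 0) 2L else 1L
    labels[dvs$members$case_a[i]] <- sideA
    labels[dvs$members$case_b[i]] <- 3L - sideA
  }
  list(labels = labels, weight = NA_real_)
}

# memo cache for Monte-Carlo expected goodness of random orientations
.mcGoodnessCache <- new.env(parent = emptyenv())

#' Expected mean-orientation goodness of random directions
#'
#' Monte-Carlo mean of the [meanOrientation()] goodness over draws of
#' `n_vectors` uniformly random directions in `dim` dimensions; used to
#' normalize goodness values across sub-clustering dimensionalities.
#' Results are memoized per (n, dim, reps, seed).
#'
#' @param n_vectors,dim matched to the sub-clustering being normalized.
#' @param reps Monte-Carlo draws (>= 1000).
#' @param seed RNG seed.
#' @return expected goodness in (0, 1].
#' @export
expectedRandomGoodness <- function(n_vectors, dim, reps = 1000L, seed = 1L) {
  if (dim < 1L || n_vectors < 1L) .fail("invalid dimensions")
  if (dim == 1L || n_vectors == 1L) return(1)
  if (reps < 1000L) .fail("reps must be >= 1000")
  key <- sprintf("n%d_d%d_r%d_s%d", n_vectors, dim, reps, seed)
  if (!is.null(.mcGoodnessCache[[key]])) return(.mcGoodnessCache[[key]])
  val <- withSeed(seed, {
    mean(vapply(seq_len(reps), function(r) {
      U <- matrix(rnorm(n_vectors * dim), n_vectors)
      U <- U / sqrt(rowSums(U^2))
      meanOrientation(U, restarts = 2L, seed = r)$goodness
    }, 0))
  })
  .mcGoodnessCache[[key]] <- val
  val
}

#' Normalize a goodness value against the random-orientation baseline
#'
#' @param goodness raw mean absolute cosine similarity.
#' @param n_vectors,dim,reps,seed as [expectedRandomGoodness()].
#' @return normalized goodness (> 0; 1 = chance level).
#' @export
mcNormalizeGoodness <- function(goodness, n_vectors, dim, reps = 1000L, seed = 1L) {
  goodness / expectedRandomGoodness(n_vectors, dim, reps, seed)
}

# pairwise hyperplane ensemble over random feature subsets:
# one sub-clustering per subset, weighted by MC-normalized goodness
.pairwiseEnsemble <- function(fm, pairs, config, mc_reps = 1000L,
                              per_participant = NULL) {
  v <- featureValues(fm)
  subsets <- sampleCombinations(ncol(v), config)
  subs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub_fm <- FeatureMatrix(v[, subsets[[i]], drop = FALSE], transforms(fm))
    dvs <- suppressWarnings(pairDifferences(sub_fm, pairs))
    k <- length(subsets[[i]])
    if (is.null(per_participant)) {
      orient <- meanOrientation(dvs, seed = subSeed(config$seed, i))
      sc <- hyperplaneSubcluster(dvs, orient)
      sc$weight <- mcNormalizeGoodness(orient$goodness, nrow(dvs$vectors), k,
                                       reps = mc_reps, seed = subSeed(config$seed, 31L))
    } else {
      # per-participant orientations; weight = mean normalized goodness
      labels <- integer(0); gs <- numeric(0)
      for (pp in unique(per_participant)) {
        pr <- names(per_participant)[per_participant == pp]
        keep <- dvs$members$pair %in% pr
        sub_dvs <- list(vectors = dvs$vectors[keep, , drop = FALSE],
                        members = dvs$members[keep, , drop = FALSE])
        class(sub_dvs) <- "DifferenceVectorSet"
        orient <- meanOrientation(sub_dvs, seed = subSeed(config$seed, i))
        part <- hyperplaneSubcluster(sub_dvs, orient)
        labels <- c(labels, part$labels)
        gs <- c(gs, mcNormalizeGoodness(orient$goodness, nrow(sub_dvs$vectors), k,
                                        reps = mc_reps, seed = subSeed(config$seed, 37L)))
      }
      sc <- list(labels = labels, weight = mean(gs))
    }
    subs[[i]] <- sc
  }
  subs
}

#' Step-2 pairwise combination clustering
#'
#' The full Step-2 procedure on a Studentized feature matrix: random
#' feature subsets, pair difference vectors in each subspace, mean
#' orientation, hyperplane sub-clustering weighted by Monte-Carlo
#' normalized goodness, co-association accumulation and two-cluster
#' extraction (average linkage by default).
#'
#' @param fm Studentized \linkS4class{FeatureMatrix}.
#' @param pairs named character vector, pair label per case id.
#' @param config an [ensembleConfig()].
#' @param mc_reps Monte-Carlo draws for goodness normalization.
#' @return as [runCombinationClustering()].
#' @export
runPairwiseClustering <- function(fm, pairs, config = ensembleConfig(),
                                  mc_reps = 1000L) {
  subs <- .pairwiseEnsemble(fm, pairs, config, mc_reps)
  co <- accumulate(subs, case_ids = rownames(featureValues(fm)))
  list(result = extractTwoClusters(co, config$linkage), coassoc = co,
       n_subclusterings = length(subs))
}

#' Step-3 four-way similarity
#'
#' Average of four co-association matrices: (a) pairwise hyperplane
#' splits against the global mean orientation; (b) pairwise splits
#' against each participant's own mean orientation; (c) 2-means
#' sub-clustering over all cases; (d) 2-means sub-clustering within each
#' participant's cases, tallied globally.  Each component is normalized
#' to [0, 1] by its own accumulated weights, so the two weight families
#' (normalized goodness, silhouette) need no cross-calibration.
#'
#' @param fm Studentized \linkS4class{FeatureMatrix}.
#' @param pairs named character vector, pair label per case id.
#' @param participants named character vector, participant per case id.
#' @param config an [ensembleConfig()].
#' @param mc_reps Monte-Carlo draws for goodness normalization.
#' @return a \linkS4class{CoAssocMatrix}.
#' @export
step3Similarity <- function(fm, pairs, participants, config = ensembleConfig(),
                            mc_reps = 1000L) {
  v <- featureValues(fm)
  ids <- rownames(v)
  pairPart <- vapply(split(participants[names(pairs)], pairs), function(x) x[1], "")
  A <- accumulate(.pairwiseEnsemble(fm, pairs, config, mc_reps), ids)
  B <- accumulate(.pairwiseEnsemble(fm, pairs, config, mc_reps,
                                    per_participant = pairPart), ids)
  subsets <- sampleCombinations(ncol(v), config)
  subsC <- lapply(seq_along(subsets), function(i) {
    subcluster(v[, subsets[[i]], drop = FALSE], config$restarts,
               seed = subSeed(config$seed, 7000L + i))
  })
  Cm <- accumulate(subsC, ids)
  subsD <- list()
  for (pp in unique(participants)) {
    own <- names(participants)[participants == pp]
    for (i in seq_along(subsets)) {
      subsD[[length(subsD) + 1L]] <-
        subcluster(v[own, subsets[[i]], drop = FALSE], config$restarts,
                   seed = subSeed(config$seed, 8000L + i))
    }
  }
  Dm <- accumulate(subsD, ids)
  avg <- (coAssocValues(A) + coAssocValues(B) + coAssocValues(Cm) + coAssocValues(Dm)) / 4
  diag(avg) <- 1
  new("CoAssocMatrix", values = avg)
}

#' Step-4 condition-group difference vectors
#'
#' One unit vector per participant: the difference between the mean
#' feature vectors of the participant's two (unlabeled) condition
#' groups, canonicalized and normalized.  The result behaves exactly
#' like a pair difference set in which each "member" is a whole
#' 3-case group, so hyperplane sub-clustering assigns a participant's
#' two groups to opposite clusters.
#'
#' @param fm Studentized \linkS4class{FeatureMatrix}.
#' @param groups named character vector: participant-condition group
#'   label per case id (two groups of 3 per participant).
#' @param participants named character vector, participant per case id.
#' @return a `DifferenceVectorSet` whose `members` columns `case_a` /
#'   `case_b` hold the two group labels; `group_cases` maps group label
#'   to case ids.
#' @export
step4ConditionDifferences <- function(fm, groups, participants) {
  v <- featureValues(fm)
  byPart <- split(names(participants), participants)
  vecs <- list(); members <- list(); groupCases <- list()
  for (pp in names(byPart)) {
    g <- unique(groups[byPart[[pp]]])
    if (length(g) != 2L) .fail("participant %s must have exactly 2 condition groups", pp)
    g <- sort(g)
    casesA <- names(groups)[groups == g[1]]
    casesB <- names(groups)[groups == g[2]]
    if (length(casesA) != 3L || length(casesB) != 3L) {
      .fail("condition groups of participant %s must have 3 cases each", pp)
    }
    d <- colMeans(v[casesA, , drop = FALSE]) - colMeans(v[casesB, , drop = FALSE])
    if (all(d == 0)) {
      warning(sprintf("participant %s has identical condition-group means; excluded", pp))
      next
    }
    dc <- .canonicalize(d)
    flip <- if (identical(dc, d)) 1L else -1L
    vecs[[pp]] <- dc / sqrt(sum(dc^2))
    members[[pp]] <- data.frame(pair = pp, case_a = g[1], case_b = g[2],
                                sign = flip, stringsAsFactors = FALSE)
    groupCases[[g[1]]] <- casesA; groupCases[[g[2]]] <- casesB
  }
  if (!length(vecs)) .fail("no non-degenerate participants")
  structure(list(vectors = do.call(rbind, vecs), members = do.call(rbind, members),
                 polarity = "first-nonzero-positive", group_cases = groupCases),
            class = "DifferenceVectorSet")
}

#' Step-4 group-level pairwise clustering
#'
#' Hyperplane ensemble over random feature subsets applied to the
#' participant condition-group difference vectors; group side labels are
#' expanded to their member cases before accumulation.
#'
#' @inheritParams step4ConditionDifferences
#' @param config an [ensembleConfig()].
#' @param mc_reps Monte-Carlo draws for goodness normalization.
#' @return as [runCombinationClustering()].
#' @export
runStep4Clustering <- function(fm, groups, participants,
                               config = ensembleConfig(linkage = "ward"),
                               mc_reps = 1000L) {
  v <- featureValues(fm)
  subsets <- sampleCombinations(ncol(v), config)
  subs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub_fm <- FeatureMatrix(v[, subsets[[i]], drop = FALSE], transforms(fm))
    dvs <- suppressWarnings(step4ConditionDifferences(sub_fm, groups, participants))
    orient <- meanOrientation(dvs, seed = subSeed(config$seed, i))
    sc <- hyperplaneSubcluster(dvs, orient)
    caseLabels <- integer(0)
    for (g in names(sc$labels)) {
      caseLabels[dvs$group_cases[[g]]] <- sc$labels[[g]]
    }
    subs[[i]] <- list(labels = caseLabels,
                      weight = mcNormalizeGoodness(orient$goodness, nrow(dvs$vectors),
                                                   length(subsets[[i]]),
                                                   reps = mc_reps,
                                                   seed = subSeed(config$seed, 41L)))
  }
  co <- accumulate(subs, case_ids = rownames(v))
  list(result = extractTwoClusters(co, config$linkage), coassoc = co,
       n_subclusterings = length(subs))
}
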