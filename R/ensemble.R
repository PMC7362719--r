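#' Configuration of the combination-clustering ensemble
#'
#' Sub-clusterings are run on random feature combinations of each size
#' in `sizes` (plus, optionally, every single feature on its own), each
#' a best-of-`restarts` 2-means, weighted by its mean silhouette.
#' The Step-1 configuration (`sizes = 2:9`, `combinations = 10000`,
#' singletons on) enumerates `n_features + 8 * 10000` sub-clusterings
#' (82 475 for the 2475-feature fine-power set).
#'
#' @param sizes feature-subset sizes (max 9: the ensemble never considers
#'   more than nine features at a time).
#' @param combinations random combinations per size (default 10000).
#' @param singletons include one sub-clustering per single feature.
#' @param restarts k-means restarts per sub-clustering.
#' @param linkage hierarchical linkage for cluster extraction
#'   (`"average"` for Steps 1--2, `"ward"` for Steps 3--4).
#' @param seed master seed; every sub-clustering derives its own stream.
#' @return list of class `EnsembleConfig`.
#' @export
ensembleConfig <- function(sizes = 2:9, combinations = 10000L,
                           singletons = TRUE, restarts = 10L,
                           linkage = c("average", "ward"), seed = 1L) {
  linkage <- match.arg(linkage)
  if (length(sizes) && max(sizes) > 9L) .fail("feature-subset sizes are limited to <= 9")
  if (combinations < 1L) .fail("combinations must be >= 1")
  structure(list(sizes = as.integer(sizes), combinations = as.integer(combinations),
                 singletons = singletons, restarts = as.integer(restarts),
                 linkage = linkage, seed = as.integer(seed)),
            class = "EnsembleConfig")
}

#' Enumerate the ensemble's feature subsets
#'
#' Singleton subsets for every feature (when enabled) plus
#' `combinations` uniformly random subsets per size; deterministic under
#' the config seed.
#'
#' @param n_features number of available features (>= max subset size).
#' @param config an [ensembleConfig()].
#' @return list of integer index vectors.
#' @export
sampleCombinations <- function(n_features, config = ensembleConfig()) {
  if (length(config$sizes) && n_features < max(config$sizes)) {
    .fail("n_features (%d) below the largest subset size (%d)",
          n_features, max(config$sizes))
  }
  out <- if (config$singletons) as.list(seq_len(n_features)) else list()
  withSeed(config$seed, {
    for (k in config$sizes) {
      out <- c(out, lapply(seq_len(config$combinations),
                           function(i) sort(sample.int(n_features, k))))
    }
  })
  out
}

#' One 2-means sub-clustering with silhouette weight
#'
#' Best-of-`restarts` 2-means in the given feature subspace; the weight
#' is the mean silhouette (Euclidean), clipped at zero.  Degenerate
#' inputs (all points identical) yield a single-cluster labeling with
#' weight 0.
#'
#' @param x cases-by-dims numeric matrix (rownames = case ids).
#' @param restarts number of random k-means initializations.
#' @param seed RNG seed for the restarts.
#' @return list with `labels` (named 1/2 vector), `weight` and `subset`
#'   (filled by callers).
#' @export
subcluster <- function(x, restarts = 10L, seed = 1L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(names(x), NULL))
  n <- nrow(x)
  if (n < 2L) .fail("sub-clustering needs at least 2 cases")
  if (nrow(unique(x)) < 2L) {
    return(list(labels = setNames(rep(1L, n), rownames(x)), weight = 0))
  }
  km <- withSeed(seed, kmeans(x, centers = 2L, nstart = restarts))
  lab <- km$cluster
  w <- 0
  if (length(unique(lab)) == 2L) {
    sil <- cluster::silhouette(lab, dist(x))
    w <- max(0, mean(sil[, "sil_width"]))
  }
  list(labels = setNames(as.integer(lab), rownames(x)), weight = w)
}

#' Accumulate sub-clusterings into a co-association matrix
#'
#' Entry (i, j) is the weight-normalized frequency with which i and j
#' were placed in the same cluster, over the sub-clusterings covering
#' both; the diagonal is 1.  Sub-clusterings may cover only a subset of
#' cases (their labels simply name fewer cases).
#'
#' @param subclusterings list of [subcluster()] results.
#' @param case_ids full case id set (default: union of labeled cases).
#' @return a \linkS4class{CoAssocMatrix}.
#' @export
accumulate <- function(subclusterings, case_ids = NULL) {
  if (!length(subclusterings)) .fail("no sub-clusterings to accumulate")
  if (is.null(case_ids)) {
    case_ids <- unique(unlist(lapply(subclusterings, function(s) names(s$labels))))
  }
  n <- length(case_ids)
  num <- matrix(0, n, n, dimnames = list(case_ids, case_ids))
  den <- matrix(0, n, n, dimnames = list(case_ids, case_ids))
  for (s in subclusterings) {
    if (s$weight <= 0) next
    idx <- match(names(s$labels), case_ids)
    co <- outer(s$labels, s$labels, `==`) * 1
    num[idx, idx] <- num[idx, idx] + s$weight * co
    den[idx, idx] <- den[idx, idx] + s$weight
  }
  if (all(den == 0)) .fail("total sub-clustering weight is zero")
  v <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
  diag(v) <- 1
  new("CoAssocMatrix", values = v)
}

#' @rdname CoAssocMatrix-class
#' @export
setMethod("coAssocValues", "CoAssocMatrix", function(x) x@values)

setMethod("show", "CoAssocMatrix", function(object) {
  cat(sprintf("CoAssocMatrix: %d cases, mean off-diagonal %.3f\n",
              nrow(object@values),
              mean(object@values[upper.tri(object@values)])))
})

#' Extract two near-equal clusters from a co-association matrix
#'
#' Hierarchical clustering on `1 - coassoc`; over all dendrogram cuts,
#' the cut whose best single cluster is closest in size to half the
#' cases wins (ties go to the highest threshold, i.e. fewest clusters);
#' that cluster becomes class 1 and every other case class 2.
#'
#' @param coassoc a \linkS4class{CoAssocMatrix}.
#' @param linkage `"average"` or `"ward"` (Ward.D2 on the
#'   dissimilarity).
#' @return list with `labels` (named 1/2 vector), `linkage`,
#'   `cut_threshold`, `pre_merge_sizes`.
#' @export
extractTwoClusters <- function(coassoc, linkage = c("average", "ward")) {
  linkage <- match.arg(linkage)
  v <- coAssocValues(coassoc)
  n <- nrow(v)
  off <- v[upper.tri(v)]
  if (max(off) - min(off) < 1e-12) {
    .fail("co-association matrix is uniform: cases are not separable")
  }
  hc <- hclust(stats::as.dist(1 - v),
               method = if (linkage == "ward") "ward.D2" else "average")
  # candidate cuts are the realizable thresholds only: a k-cluster cut
  # exists iff the k-th and (k-1)-th largest merge heights differ, so
  # runs of tied merges (e.g. chains inside a uniform block) are never
  # split apart
  hsort <- sort(hc$height)
  best <- NULL
  for (k in 2:n) {
    if (k < n && hsort[n - k] >= hsort[n - k + 1L] - 1e-12) next
    ct <- cutree(hc, k)
    sizes <- table(ct)
    dev <- min(abs(sizes - n / 2))
    # scanned from the highest threshold down: ties keep the first hit
    if (is.null(best) || dev < best$dev) {
      pick <- names(sizes)[which.min(abs(sizes - n / 2))]
      best <- list(dev = dev, k = k, ct = ct, pick = pick,
                   sizes = as.integer(sizes))
    }
    if (best$dev == 0) break
  }
  labels <- setNames(ifelse(best$ct == as.integer(best$pick), 1L, 2L), rownames(v))
  list(labels = labels, linkage = linkage,
       cut_threshold = if (best$k <= n - 1L) hsort[n - best$k + 1L] else 0,
       pre_merge_sizes = best$sizes)
}

#' Run combination clustering end to end
#'
#' Feature-combination sampling, silhouette-weighted 2-means
#' sub-clustering, co-association accumulation and two-cluster
#' extraction; fully deterministic under the config seed.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param config an [ensembleConfig()].
#' @return list with `result` ([extractTwoClusters()] output), `coassoc`
#'   and `n_subclusterings`.
#' @export
runCombinationClustering <- function(fm, config = ensembleConfig()) {
  v <- featureValues(fm)
  subsets <- sampleCombinations(ncol(v), config)
  subs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subcluster(v[, subsets[[i]], drop = FALSE], restarts = config$restarts,
                    seed = subSeed(config$seed, i))
    s$subset <- subsets[[i]]
    subs[[i]] <- s
  }
  co <- accumulate(subs, case_ids = rownames(v))
  list(result = extractTwoClusters(co, config$linkage), coassoc = co,
       n_subclusterings = length(subsets))
}
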