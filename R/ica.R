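# Per-participant ICA cleanup: unmix the participant's concatenated
# EEG+EOG record, score components for condition relevance via the
# paired design, drop the irrelevant ones and recompose.  EMG channels
# are never touched.

#' Fit an ICA decomposition on one participant's cases
#'
#' Symmetric fixed-point ICA (tanh contrast) after whitening, fit on the
#' EEG+EOG channels of the participant's concatenated cases.
#' Deterministic under `seed`.  With full component retention the
#' decomposition reconstructs the input to numerical precision; rank
#' deficiency reduces the component count with a warning.
#'
#' @param cases the participant's cases (a list of
#'   \linkS4class{PsgCase} with a common channel set; 6 in the standard
#'   design).
#' @param n_components number of components (default: all EEG+EOG
#'   channels, which preserves the reconstruction identity).
#' @param seed RNG seed for the unmixing initialization.
#' @param maxit,tol fixed-point iteration controls.  Near-Gaussian
#'   sources make the contrast surface flat, so the iteration is capped
#'   rather than required to converge; the result stays deterministic.
#' @param max_rows row subsample cap for the fixed-point updates (the
#'   final activations and the reconstruction always use all samples).
#' @return list of class `IcaModel`: `mixing` (components x channels),
#'   `activations` (per case, samples x components), `channel_means`,
#'   `cases` (ids), `channels` (names used), `keep_all_error`.
#' @export
fitParticipantIca <- function(cases, n_components = NULL, seed = 1L,
                              maxit = 100L, tol = 1e-7, max_rows = 8000L) {
  if (length(cases) < 2L) .fail("participant ICA needs >= 2 cases")
  ch0 <- channelInfo(cases[[1]])
  use <- ch0$modality %in% c("EEG", "EOG")
  chNames <- ch0$name[use]
  X <- do.call(rbind, lapply(cases, function(cs) {
    ch <- channelInfo(cs)
    if (!identical(ch$name, ch0$name)) .fail("cases must share a channel set")
    samples(cs)[, use, drop = FALSE]
  }))
  p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  cv <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  nc <- if (is.null(n_components)) p else min(n_components, p)
  if (sum(pos) < nc) {
    warning(sprintf("rank-deficient data: %d components instead of %d", sum(pos), nc))
    nc <- sum(pos)
  }
  K <- eg$vectors[, seq_len(nc), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(nc)]), nc)
  Z <- Xc %*% K
  Zit <- if (nrow(Z) > max_rows) {
    Z[unique(round(seq(1L, nrow(Z), length.out = max_rows))), , drop = FALSE]
  } else Z
  W <- withSeed(seed, matrix(rnorm(nc * nc), nc))
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(maxit)) {
    U <- Zit %*% W
    gU <- tanh(U)
    W1 <- crossprod(Zit, gU) / nrow(Zit) -
      sweep(W, 2L, colMeans(1 - gU^2), `*`)
    W1 <- orth(W1)
    delta <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  M <- K %*% W                      # channels -> sources: S = Xc M
  A <- if (nc == p) solve(M) else {
    solve(crossprod(M)) %*% t(M)    # least-squares recomposition
  }
  S <- Xc %*% M
  lens <- vapply(cases, function(cs) nrow(samples(cs)), 0L)
  stops <- cumsum(lens)
  starts <- c(1L, head(stops, -1L) + 1L)
  acts <- lapply(seq_along(cases), function(i) S[starts[i]:stops[i], , drop = FALSE])
  names(acts) <- vapply(cases, caseId, "")
  structure(list(mixing = A, unmixing = M, activations = acts,
                 channel_means = mu, channels = chNames,
                 cases = vapply(cases, caseId, ""), n_components = nc),
            class = "IcaModel")
}

#' Score ICA components for condition relevance
#'
#' Per component, the log power (log variance of the activation) is
#' computed per case; the paired contrast is the within-pair difference
#' under the polarity that maximizes its absolute mean (equivalently the
#' mean absolute difference, since pair member order is blinded), scaled
#' by its standard error.  For the Step-4 variant (`groups`), the
#' contrast is the absolute difference of the participant's two
#' condition-group means.  Higher = more condition-relevant; a component
#' identical across cases scores 0.  Sign flips of components do not
#' change the score.
#'
#' @param model an `IcaModel`.
#' @param pairs named character vector: pair label per case id (at least
#'   the model's cases).
#' @param groups optional named character vector of condition-group
#'   labels; when given, the group-mean contrast replaces the pair
#'   contrast.
#' @return numeric score per component.
#' @export
scoreConditionRelevance <- function(model, pairs = NULL, groups = NULL) {
  lp <- vapply(model$activations, function(a) log(pmax(apply(a, 2L, var), 1e-300)),
               numeric(model$n_components))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1L, dimnames = list(NULL, model$cases))
  score1 <- function(vals) {
    if (!is.null(groups)) {
      g <- split(vals, groups[names(vals)])
      if (length(g) != 2L) .fail("need exactly 2 condition groups")
      return(abs(mean(g[[1]]) - mean(g[[2]])))
    }
    d <- vapply(split(vals, pairs[names(vals)]), function(x) abs(diff(x)), 0)
    if (all(d == 0)) return(0)
    se <- sd(d) / sqrt(length(d))
    if (se == 0) return(mean(d) / .Machine$double.eps^0.5)
    mean(d) / se
  }
  if (is.null(pairs) && is.null(groups)) .fail("pair or group labels required")
  vapply(seq_len(model$n_components), function(cc) {
    vals <- setNames(lp[cc, ], model$cases)
    if (max(vals) - min(vals) < 1e-12) 0 else score1(vals)
  }, 0)
}

#' Recompose cases from retained components
#'
#' Rebuilds each case's EEG+EOG channels from the retained components
#' only; EMG channels pass through bit-for-bit.  Keeping every component
#' reproduces the original signals to numerical precision.
#'
#' @param model an `IcaModel`.
#' @param cases the original cases the model was fit on.
#' @param keep integer or logical index of components to retain (>= 1).
#' @return list of cleaned \linkS4class{PsgCase}.
#' @export
removeAndRecompose <- function(model, cases, keep) {
  keep <- which(seq_len(model$n_components) %in%
                  (if (is.logical(keep)) which(keep) else keep))
  if (!length(keep)) .fail("component retention must keep at least one component")
  lapply(cases, function(cs) {
    a <- model$activations[[caseId(cs)]]
    if (is.null(a)) .fail("case %s was not part of the ICA fit", caseId(cs))
    rec <- a[, keep, drop = FALSE] %*% model$mixing[keep, , drop = FALSE]
    rec <- sweep(rec, 2L, model$channel_means, `+`)
    x <- samples(cs)
    x[, match(model$channels, channelInfo(cs)$name)] <- rec
    PsgCase(caseId(cs), x, samplingRate(cs), channelInfo(cs))
  })
}

#' Per-participant ICA cleanup of a cohort
#'
#' Fits one ICA per participant, scores components for condition
#' relevance (pairs for Step 3, condition groups for Step 4) and
#' retains the top `keep_fraction` by score.  No transform crosses
#' participants.
#'
#' @param cases full cohort (list of \linkS4class{PsgCase}).
#' @param participants named character vector, participant per case id.
#' @param pairs named pair labels (Step-3 scoring), or `NULL`.
#' @param groups named condition-group labels (Step-4 scoring), or
#'   `NULL`.
#' @param keep_fraction fraction of components retained (default 0.5; a
#'   documented substitute for an unpublished selection rule).
#' @param seed master seed.
#' @return list of cleaned cases in the input order.
#' @export
icaCleanCohort <- function(cases, participants, pairs = NULL, groups = NULL,
                           keep_fraction = 0.5, seed = 1L) {
  ids <- vapply(cases, caseId, "")
  out <- vector("list", length(cases))
  names(out) <- ids
  for (pp in unique(participants)) {
    own <- names(participants)[participants == pp]
    sel <- which(ids %in% own)
    model <- fitParticipantIca(cases[sel], seed = subSeed(seed, match(pp, unique(participants))))
    sc <- scoreConditionRelevance(model, pairs = pairs, groups = groups)
    nKeep <- max(1L, ceiling(keep_fraction * length(sc)))
    keep <- order(sc, decreasing = TRUE)[seq_len(nKeep)]
    out[ids[sel]] <- removeAndRecompose(model, cases[sel], keep)
  }
  out[ids]
}
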