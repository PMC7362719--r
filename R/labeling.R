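# Rule-based labeling of unlabeled clusters for dreamfulness, following
# the literature-derived expectations: dreamless sleep shows higher
# low-frequency and lower high-frequency EEG power.

#' Cohen's d effect size
#'
#' For raw samples, the pooled SD is the standard
#' `sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`; for summary inputs
#' (means and SDs) the equal-n convention `sqrt((s1^2 + s2^2)/2)` is
#' used.
#'
#' @param x1,x2 numeric vectors of raw values.
#' @return list of class `EffectSize`: `d`, `mu1`, `mu2`, `pooled_sd`.
#' @export
cohensD <- function(x1, x2) {
  if (!length(x1) || !length(x2)) .fail("both groups must be non-empty")
  n1 <- length(x1); n2 <- length(x2)
  s <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  if (!is.finite(s) || s == 0) .fail("pooled SD is zero")
  structure(list(d = (mean(x1) - mean(x2)) / s, mu1 = mean(x1), mu2 = mean(x2),
                 pooled_sd = s), class = "EffectSize")
}

#' @rdname cohensD
#' @param m1,s1,m2,s2 group means and SDs (summary form, equal n).
#' @export
cohensDSummary <- function(m1, s1, m2, s2) {
  s <- sqrt((s1^2 + s2^2) / 2)
  if (!is.finite(s) || s == 0) .fail("pooled SD is zero")
  structure(list(d = (m1 - m2) / s, mu1 = m1, mu2 = m2, pooled_sd = s),
            class = "EffectSize")
}

.conditionCall <- function(mapping, rule, contrasts, conflict = FALSE) {
  if (!setequal(mapping, c("dreamful", "dreamless"))) {
    .fail("cluster mapping must be a bijection onto dreamful/dreamless")
  }
  structure(list(mapping = mapping, rule = rule, contrasts = contrasts,
                 conflict = conflict), class = "ConditionCall")
}

#' @export
print.ConditionCall <- function(x, ...) {
  cat(sprintf("ConditionCall [%s]%s: %s\n", x$rule,
              if (isTRUE(x$conflict)) " (band conflict logged)" else "",
              paste(sprintf("cluster %s -> %s", names(x$mapping), x$mapping),
                    collapse = ", ")))
  invisible(x)
}

# per-feature Cohen's d (cluster 1 minus cluster 2) over a feature matrix
.clusterD <- function(labels, values) {
  g1 <- values[names(labels)[labels == 1L], , drop = FALSE]
  g2 <- values[names(labels)[labels == 2L], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  s <- sqrt(((n1 - 1) * apply(g1, 2, var) + (n2 - 1) * apply(g2, 2, var)) /
              (n1 + n2 - 2))
  d <- (colMeans(g1) - colMeans(g2)) / s
  d[!is.finite(d)] <- 0
  d
}

# parse the frequency (Hz) out of namespaced log-PSD feature names
.featureFreq <- function(nm) {
  hz <- regmatches(nm, regexpr("[0-9.]+(?=Hz)", nm, perl = TRUE))
  out <- rep(NA_real_, length(nm))
  out[grepl("Hz", nm)] <- as.numeric(hz)
  out
}

#' Label two clusters for dreamfulness by their spectra
#'
#' Computes the per-frequency-bin Cohen's d (log scale, cluster 1 minus
#' cluster 2) and summarizes it over the low (1--12 Hz) and high
#' (18--50 Hz) bands.  The cluster with higher low-band and lower
#' high-band power is called dreamless.  If the two band summaries
#' disagree with that pattern, the band with the larger |mean d|
#' decides and the conflict is recorded on the call.
#'
#' @param labels named 1/2 cluster labels per case id.
#' @param fm a \linkS4class{FeatureMatrix} of natural-log PSD features
#'   whose names carry `<freq>Hz` (e.g. the fine-power or scalp-average
#'   sets).
#' @return a `ConditionCall`.
#' @export
labelBySpectrum <- function(labels, fm) {
  v <- featureValues(fm)
  fr <- .featureFreq(colnames(v))
  if (all(is.na(fr))) .fail("no frequency-resolved features present")
  d <- .clusterD(labels, v)
  dLow <- mean(d[!is.na(fr) & fr >= 1 & fr <= 12])
  dHigh <- mean(d[!is.na(fr) & fr >= 18 & fr <= 50])
  if (is.na(dLow) || is.na(dHigh)) .fail("low or high band missing from features")
  if (dLow == 0 && dHigh == 0) .fail("no separable contrast between clusters")
  contrasts <- c(low_band_d = dLow, high_band_d = dHigh)
  if (dLow > 0 && dHigh < 0) {
    m <- c("1" = "dreamless", "2" = "dreamful")
  } else if (dLow < 0 && dHigh > 0) {
    m <- c("1" = "dreamful", "2" = "dreamless")
  } else {
    # bands conflict: the stronger band decides
    if (abs(dHigh) >= abs(dLow)) {
      m <- if (dHigh > 0) c("1" = "dreamful", "2" = "dreamless")
           else c("1" = "dreamless", "2" = "dreamful")
    } else {
      m <- if (dLow > 0) c("1" = "dreamless", "2" = "dreamful")
           else c("1" = "dreamful", "2" = "dreamless")
    }
    return(.conditionCall(m, "spectral-conflict", contrasts, conflict = TRUE))
  }
  .conditionCall(m, "spectral", contrasts)
}

#' Step-4 labeling: spectral rule with frontal high-frequency tiebreak
#'
#' Applies the spectral rule to the frequency-resolved Step-2 features;
#' the hot-zone frontal high-frequency contrast (lower power indicating
#' absent dream experience) breaks conflicts and is recorded alongside.
#'
#' @param labels named 1/2 cluster labels per case id.
#' @param fm the Step-2 \linkS4class{FeatureMatrix} (must contain the
#'   `siclari/frontal/high/...` features).
#' @return a `ConditionCall`.
#' @export
labelStep4 <- function(labels, fm) {
  v <- featureValues(fm)
  fh <- grep("^siclari/frontal/high", colnames(v), value = TRUE)
  if (!length(fh)) .fail("frontal high-frequency features missing")
  dFh <- mean(.clusterD(labels, v[, fh, drop = FALSE]))
  spectral <- tryCatch(labelBySpectrum(labels, fm), error = function(e) NULL)
  if (is.null(spectral)) {
    if (dFh == 0) .fail("all contrasts are zero")
    m <- if (dFh < 0) c("1" = "dreamless", "2" = "dreamful")
         else c("1" = "dreamful", "2" = "dreamless")
    return(.conditionCall(m, "frontal-high", c(frontal_high_d = dFh)))
  }
  if (isTRUE(spectral$conflict) && dFh != 0) {
    m <- if (dFh < 0) c("1" = "dreamless", "2" = "dreamful")
         else c("1" = "dreamful", "2" = "dreamless")
    return(.conditionCall(m, "frontal-high-tiebreak",
                          c(spectral$contrasts, frontal_high_d = dFh),
                          conflict = TRUE))
  }
  .conditionCall(spectral$mapping, paste0(spectral$rule, "+frontal-high-checked"),
                 c(spectral$contrasts, frontal_high_d = dFh),
                 conflict = spectral$conflict)
}

#' Step-5 labeling of the two condition groups
#'
#' After subtracting each participant's mean from every feature, the
#' group means of `SBP_low`, `SBP_high` and `Scarpelli` are compared;
#' the group with lower SBP_low, higher SBP_high and lower Scarpelli
#' collects votes for dreamful, and the majority wins.  A tied (or
#' fully zero) vote is an error.
#'
#' @param fm \linkS4class{FeatureMatrix} of Step-5 features over all 54
#'   cases.
#' @param groupA,groupB case ids of the two condition groups (27 each).
#' @param participants named character vector, participant per case id.
#' @return a `ConditionCall` with mapping names `"A"` and `"B"`.
#' @export
labelStep5 <- function(fm, groupA, groupB, participants) {
  v <- featureValues(fm)
  need <- c("SBP_low", "SBP_high", "Scarpelli")
  if (!all(need %in% colnames(v))) .fail("Step-5 features missing")
  for (pp in unique(participants)) {
    own <- names(participants)[participants == pp]
    v[own, ] <- sweep(v[own, , drop = FALSE], 2L, colMeans(v[own, , drop = FALSE]))
  }
  dm <- colMeans(v[groupA, need, drop = FALSE]) - colMeans(v[groupB, need, drop = FALSE])
  # vote for "A is dreamful": lower SBP_low, higher SBP_high, lower Scarpelli
  votes <- c(SBP_low = -sign(dm["SBP_low"]), SBP_high = sign(dm["SBP_high"]),
             Scarpelli = -sign(dm["Scarpelli"]))
  tally <- sum(votes)
  if (tally == 0) .fail("tie vote: features give no majority for either group")
  m <- if (tally > 0) c(A = "dreamful", B = "dreamless")
       else c(A = "dreamless", B = "dreamful")
  .conditionCall(m, "step5-majority", c(dm, votes = unname(tally)))
}
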