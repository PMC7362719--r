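#' Exact two-tailed binomial test
#'
#' Point-probability method: the p-value sums the probabilities of all
#' outcomes no more likely than the observed count.  For `p0 = 0.5`
#' this equals the doubled tail capped at 1.
#'
#' @param n number of decisions.
#' @param k number correct (0..n).
#' @param p0 null success probability (default 0.5).
#' @return two-tailed p-value.
#' @export
binomialTwoTailed <- function(n, k, p0 = 0.5) {
  if (k < 0 || k > n) .fail("k must be in 0..n")
  dd <- dbinom(0:n, n, p0)
  min(1, sum(dd[dd <= dbinom(k, n, p0) * (1 + 1e-12)]))
}

#' Monte-Carlo power of the paired t-test
#'
#' Fraction of replicates in which a one-sample t-test on `n_pairs`
#' Gaussian paired differences with mean `effect_d` and unit SD rejects
#' at `alpha` (one- or two-tailed).  Deterministic under `seed`.
#'
#' @param n_pairs number of paired differences per replicate.
#' @param effect_d standardized effect size of the differences.
#' @param alpha significance level.
#' @param tails 1 (directional) or 2.
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed RNG seed.
#' @return estimated power in [0, 1].
#' @export
mcPower <- function(n_pairs, effect_d, alpha = 0.05, tails = 1L,
                    reps = 10000L, seed = 1L) {
  if (reps < 1000L) .fail("reps must be >= 1000")
  if (alpha <= 0 || alpha >= 1) .fail("alpha must be in (0, 1)")
  if (!tails %in% c(1L, 2L)) .fail("tails must be 1 or 2")
  withSeed(seed, {
    x <- matrix(rnorm(n_pairs * reps, mean = effect_d, sd = 1), n_pairs, reps)
    m <- colMeans(x)
    s <- sqrt((colSums(x^2) - n_pairs * m^2) / (n_pairs - 1))
    tstat <- sqrt(n_pairs) * m / s
    df <- n_pairs - 1
    if (tails == 1L) mean(tstat > qt(1 - alpha, df))
    else mean(abs(tstat) > qt(1 - alpha / 2, df))
  })
}

#' @rdname truthTable
#' @export
setMethod("truthTable", "DataTeamOracle", function(x) {
  .fail("blinded: the truth table is guarded; only scoreStep() may consult it")
})

#' Construct the scoring oracle
#'
#' @param truth data.frame with columns `case_id`, `participant`,
#'   `session`, `condition` (names).
#' @param key a \linkS4class{BlindKey}.
#' @return a \linkS4class{DataTeamOracle}.
#' @export
DataTeamOracle <- function(truth, key) {
  new("DataTeamOracle", truth = truth[, c("case_id", "participant", "session",
                                          "condition")], key = key)
}

#' @describeIn reveal the oracle delegates to its key.
#' @export
setMethod("reveal", "DataTeamOracle", function(key, step) reveal(key@key, step))

setMethod("show", "DataTeamOracle", function(object) {
  cat(sprintf("DataTeamOracle: %d cases (truth guarded)\n", nrow(object@truth)))
})

#' @rdname scoreStep
#' @export
setMethod("scoreStep", "DataTeamOracle", function(oracle, predictions, step) {
  step <- as.integer(step)
  if (!step %in% 1:5) .fail("step must be 1..5")
  truth <- setNames(oracle@truth$condition, oracle@truth$case_id)
  key <- oracle@key@key
  if (!setequal(names(predictions), names(truth))) {
    .fail("predictions must cover exactly the cohort's case ids")
  }
  ok <- predictions[names(truth)] == truth
  if (step == 1L) {
    decisions <- length(truth); correct <- sum(ok)
  } else if (step %in% c(2L, 3L)) {
    pr <- setNames(key$pair, key$case_id)
    byPair <- split(names(truth), pr[names(truth)])
    correct <- sum(vapply(byPair, function(ids) all(ok[ids]), TRUE))
    decisions <- length(byPair)
  } else if (step == 4L) {
    pp <- setNames(key$participant, key$case_id)
    byPart <- split(names(truth), pp[names(truth)])
    correct <- sum(vapply(byPart, function(ids) all(ok[ids]), TRUE))
    decisions <- length(byPart)
  } else {
    decisions <- 1L; correct <- as.integer(all(ok))
  }
  info <- c("Case", "Pair", "Subject", "Subject-condition", "Condition")[step]
  data.frame(step = step, information_revealed = info, decisions = decisions,
             correct = correct, accuracy = 100 * correct / decisions,
             p_value = binomialTwoTailed(decisions, correct),
             stringsAsFactors = FALSE)
})

#' Assemble the five-step performance table
#'
#' @param step_results list (or rbind-able set) of [scoreStep()] rows.
#' @return data.frame with columns Step, Information revealed, Number of
#'   decisions, Number correct, Accuracy (%) (recomputed) and p; empty
#'   input gives an empty table.
#' @export
table2Report <- function(step_results) {
  if (!length(step_results)) {
    return(data.frame(Step = integer(), `Information revealed` = character(),
                      `Number of decisions` = integer(),
                      `Number correct` = integer(), `Accuracy (%)` = numeric(),
                      p = numeric(), check.names = FALSE))
  }
  df <- do.call(rbind, step_results)
  data.frame(Step = df$step, `Information revealed` = df$information_revealed,
             `Number of decisions` = df$decisions, `Number correct` = df$correct,
             `Accuracy (%)` = round(100 * df$correct / df$decisions),
             p = df$p_value, check.names = FALSE)
}
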