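#' Configuration of the synthetic polysomnogram cohort
#'
#' Parameters of the generative model behind [synthCohort()]: a 1/f-like
#' EEG background with participant-specific amplitude and spectral
#' exponent, delta-band oscillatory bursts, 12--15 Hz spindles, additive
#' sensor noise, slow EOG events and high-frequency EMG tonus, plus a
#' condition (dreamful vs dreamless) effect expressed purely as
#' multiplicative band-power factors with regional weights.
#'
#' `condition_delta_ratio` is the dreamless/dreamful power ratio in the
#' 0.5--4 Hz band; `condition_high_ratio` the dreamful/dreamless ratio
#' in 18--50 Hz; both must be >= 1 (1 = no effect).  Regional weights
#' multiply the log of these ratios per electrode position tag.
#'
#' @param seed master seed of the cohort.
#' @param rate sampling rate in Hz (integer).
#' @param n_participants,sessions_per_condition design size (9 x 3 x 2).
#' @param participant_effect_sd between-participant SD of overall
#'   log power (natural-log scale).
#' @param spectral_exponent_mean,spectral_exponent_sd background 1/f^a
#'   exponent distribution across participants.
#' @param condition_delta_ratio,condition_high_ratio condition band-power
#'   factors (>= 1).
#' @param regional_weighting list with named numeric vectors `low` and
#'   `high`, one weight per position tag.
#' @param delta_burst_rate,delta_burst_amp slow-wave burst events per
#'   minute and their amplitude (uV).
#' @param spindle_density,spindle_amp 12--15 Hz spindles per minute and
#'   their amplitude (uV).
#' @param eog_event_rate slow eye-movement events per minute.
#' @param emg_tonus_level EMG RMS amplitude (uV).
#' @param noise_sd additive white sensor noise SD (uV).
#' @param base_rms baseline EEG RMS scale (uV).
#' @param eog_coupled,emg_coupled optionally couple EOG/EMG activity to
#'   the condition (off by default: condition-independent).
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(seed = 1L, rate = 256L,
                         n_participants = 9L, sessions_per_condition = 3L,
                         participant_effect_sd = 0.4,
                         spectral_exponent_mean = 1.5, spectral_exponent_sd = 0.2,
                         condition_delta_ratio = 2.2, condition_high_ratio = 1.8,
                         regional_weighting = list(
                           low = c("parieto-occipital" = 1, frontal = 0.25,
                                   central = 0.25, temporal = 0.25),
                           high = c(frontal = 1, temporal = 0.5,
                                    central = 0.25, "parieto-occipital" = 0.25)),
                         delta_burst_rate = 30, delta_burst_amp = 40,
                         spindle_density = 5, spindle_amp = 15,
                         eog_event_rate = 4, emg_tonus_level = 5,
                         noise_sd = 2, base_rms = 25,
                         eog_coupled = FALSE, emg_coupled = FALSE) {
  cfg <- as.list(environment())
  if (cfg$condition_delta_ratio < 1 || cfg$condition_high_ratio < 1) {
    .fail("condition ratios must be >= 1")
  }
  sds <- c(cfg$participant_effect_sd, cfg$spectral_exponent_sd, cfg$noise_sd)
  if (any(sds < 0)) .fail("all SDs must be >= 0")
  if (cfg$rate != round(cfg$rate) || cfg$rate < 64) .fail("rate must be an integer >= 64 Hz")
  if (!all(c("low", "high") %in% names(cfg$regional_weighting))) {
    .fail("regional_weighting needs 'low' and 'high' components")
  }
  class(cfg) <- "CohortConfig"
  cfg
}

#' Draw one participant's random-effect state
#'
#' @param config a `CohortConfig`.
#' @param participant participant index (1-based).
#' @param seed seed; defaults to a stream derived from `config$seed`.
#' @return list with `amp` (multiplicative power offset, mean-one
#'   log-normal) and `exponent` (background spectral exponent).
#' @export
participantState <- function(config, participant, seed = subSeed(config$seed, participant)) {
  withSeed(seed, {
    list(
      participant = participant,
      amp = exp(rnorm(1L, 0, config$participant_effect_sd)),
      exponent = rnorm(1L, config$spectral_exponent_mean, config$spectral_exponent_sd)
    )
  })
}

# one-sided band gain profile over the full-length FFT frequency axis
.conditionGain <- function(freqAbs, condition, config, position) {
  g <- rep(1, length(freqAbs))
  if (condition == "dreamful") {
    wl <- config$regional_weighting$low[[position]]
    wh <- config$regional_weighting$high[[position]]
    low <- freqAbs >= 0.5 & freqAbs <= 4
    high <- freqAbs >= 18 & freqAbs <= 50
    g[low] <- (1 / config$condition_delta_ratio)^(wl / 2)
    g[high] <- config$condition_high_ratio^(wh / 2)
  }
  g
}

# colored background of unit expected variance via spectral shaping
.coloredNoise <- function(n, rate, exponent) {
  f <- c(0, seq_len(n - 1)) * rate / n
  fAbs <- pmin(f, rate - f)
  h <- pmax(fAbs, 0.5)^(-exponent / 2)
  h[1] <- 0  # no DC
  h <- h / sqrt(mean(h^2))
  w <- fft(stats::rnorm(n))
  Re(fft(w * h, inverse = TRUE)) / n
}

.burstTrain <- function(n, rate, perMin, fRange, durRange, amp) {
  x <- numeric(n)
  k <- stats::rpois(1L, perMin * n / rate / 60)
  if (k == 0L) return(x)
  for (i in seq_len(k)) {
    dur <- stats::runif(1L, durRange[1], durRange[2])
    len <- max(8L, round(dur * rate))
    start <- sample.int(max(1L, n - len), 1L)
    tt <- seq_len(len) / rate
    env <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))
    f0 <- stats::runif(1L, fRange[1], fRange[2])
    x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] +
      amp * env * sin(2 * pi * f0 * tt + stats::runif(1L, 0, 2 * pi))
  }
  x
}

#' Synthesize one polysomnogram case
#'
#' EEG channels are 1/f^a background plus delta bursts and sleep
#' spindles; the condition effect is applied as a spectral band filter
#' (so in-band Welch power scales by exactly the configured factor,
#' before sensor noise); EOG carries slow conjugate eye-movement events
#' plus frontal-EEG crosstalk; EMG is high-pass-shaped noise.
#'
#' @param config a `CohortConfig`.
#' @param state a [participantState()] list.
#' @param condition `"dreamful"` or `"dreamless"`.
#' @param session session index (1..3), recorded in the case id only.
#' @param seed integer seed; fixed seed reproduces the case bit-for-bit.
#' @param caseId label for the resulting case.
#' @return a \linkS4class{PsgCase} of exactly 60 s.
#' @export
synthCase <- function(config, state, condition = c("dreamless", "dreamful"),
                      session = 1L, seed = 1L, caseId = "ID00") {
  condition <- match.arg(condition)
  rate <- config$rate
  n <- as.integer(rate * 60)
  mont <- standardMontage()
  withSeed(seed, {
    out <- matrix(0, n, nrow(mont))
    f <- c(0, seq_len(n - 1)) * rate / n
    fAbs <- pmin(f, rate - f)
    eegIdx <- which(mont$modality == "EEG")
    for (j in eegIdx) {
      bg <- .coloredNoise(n, rate, state$exponent) *
        sqrt(state$amp) * config$base_rms
      x <- bg +
        .burstTrain(n, rate, config$delta_burst_rate, c(0.75, 3.5), c(0.8, 2.5),
                    config$delta_burst_amp * sqrt(state$amp)) +
        .burstTrain(n, rate, config$spindle_density, c(12, 15), c(0.5, 1.5),
                    config$spindle_amp * sqrt(state$amp))
      gain <- .conditionGain(fAbs, condition, config, mont$position[j])
      if (any(gain != 1)) x <- Re(fft(fft(x) * gain, inverse = TRUE)) / n
      out[, j] <- x + stats::rnorm(n, 0, config$noise_sd)
    }
    # EOG: conjugate slow events + crosstalk from frontal EEG
    eogRate <- config$eog_event_rate *
      (if (config$eog_coupled && condition == "dreamful") 1.5 else 1)
    slow <- .burstTrain(n, rate, eogRate, c(0.15, 0.5), c(1.5, 4), 80)
    frontal <- rowMeans(out[, eegIdx[mont$position[eegIdx] == "frontal"], drop = FALSE])
    eogIdx <- which(mont$modality == "EOG")
    out[, eogIdx[1]] <- slow + 0.1 * frontal + stats::rnorm(n, 0, 3)
    out[, eogIdx[2]] <- -slow + 0.1 * frontal + stats::rnorm(n, 0, 3)
    # EMG: high-pass shaped noise
    emgAmp <- config$emg_tonus_level *
      (if (config$emg_coupled && condition == "dreamful") 1.5 else 1)
    hp <- fAbs / (fAbs + 20)
    for (j in which(mont$modality == "EMG")) {
      w <- fft(stats::rnorm(n))
      e <- Re(fft(w * hp, inverse = TRUE)) / n
      out[, j] <- emgAmp * e / sqrt(mean(hp^2)) + stats::rnorm(n, 0, 0.5)
    }
    PsgCase(caseId, out, rate, mont)
  })
}

#' Generate a full blinded 54-case synthetic cohort
#'
#' Produces the study-design cohort (9 participants x 3 sessions x 2
#' conditions), blinds it with [applyBlinding()] and returns the cases
#' under their blinded ids, sorted by case id.  The truth table is
#' returned separately and must never be passed to analysis stages;
#' condition names are not stored anywhere in the cases.
#'
#' @param config a `CohortConfig`.
#' @return list with `cases` (list of \linkS4class{PsgCase}), `key`
#'   (\linkS4class{BlindKey}) and `truth` (data.frame with recording,
#'   case_id, participant, session, condition and the injected
#'   participant effect parameters).
#' @export
synthCohort <- function(config = cohortConfig()) {
  nP <- config$n_participants
  nS <- config$sessions_per_condition
  if (nP != 9L || nS != 3L) .fail("the blinded protocol requires 9 participants x 3 sessions")
  conds <- c("dreamful", "dreamless")
  rows <- expand.grid(condition = conds, session = seq_len(nS),
                      participant = seq_len(nP), stringsAsFactors = FALSE)
  rows <- rows[order(rows$participant, rows$session, rows$condition), ]
  truth <- data.frame(
    recording = sprintf("R%02d", seq_len(nrow(rows))),
    participant = rows$participant, session = rows$session,
    condition = rows$condition, stringsAsFactors = FALSE
  )
  states <- lapply(seq_len(nP), function(p) participantState(config, p))
  truth$amp <- vapply(truth$participant, function(p) states[[p]]$amp, 0)
  truth$exponent <- vapply(truth$participant, function(p) states[[p]]$exponent, 0)
  key <- applyBlinding(truth, seed = subSeed(config$seed, 999L))
  truth$case_id <- key@key$case_id[match(truth$recording, key@recording)]
  cases <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cases[[i]] <- synthCase(config, states[[truth$participant[i]]],
                            condition = truth$condition[i],
                            session = truth$session[i],
                            seed = subSeed(config$seed, 1000L + i),
                            caseId = truth$case_id[i])
  }
  ord <- order(vapply(cases, caseId, ""))
  list(cases = cases[ord], key = key, truth = truth)
}
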