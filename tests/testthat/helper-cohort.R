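# Shared synthetic cohorts, built once per test run and cached.
# Test cohorts use 100 Hz (the lowest rate supporting the 49.5-Hz
# fine-power grid) to keep the suite fast; the generator's default for
# real use is 256 Hz.

.cohortCache <- new.env(parent = emptyenv())

.cachedCohort <- function(name, config) {
  if (is.null(.cohortCache[[name]])) .cohortCache[[name]] <- synthCohort(config)
  .cohortCache[[name]]
}

# strong condition effect, participant random effects off
strongCohort <- function() {
  .cachedCohort("strong", cohortConfig(
    seed = 101L, rate = 100L, participant_effect_sd = 0,
    spectral_exponent_sd = 0, condition_delta_ratio = 4,
    condition_high_ratio = 2))
}

# strong participant random effects, no condition effect
participantCohort <- function() {
  .cachedCohort("participant", cohortConfig(
    seed = 102L, rate = 100L, participant_effect_sd = 1,
    spectral_exponent_sd = 0.3, condition_delta_ratio = 1,
    condition_high_ratio = 1))
}

# no condition effect, no participant effects (pure noise cohort)
nullCohort <- function() {
  .cachedCohort("null", cohortConfig(
    seed = 103L, rate = 100L, participant_effect_sd = 0,
    spectral_exponent_sd = 0, condition_delta_ratio = 1,
    condition_high_ratio = 1))
}

# one quick standard case for feature tests
quickCase <- function(seed = 7L, rate = 100L, condition = "dreamless", ...) {
  cfg <- cohortConfig(seed = seed, rate = rate, ...)
  synthCase(cfg, participantState(cfg, 1L), condition = condition,
            session = 1L, seed = seed, caseId = "ID01")
}

# a small ensemble configuration for tests
tinyEnsemble <- function(seed = 1L, linkage = "average") {
  ensembleConfig(sizes = 2:9, combinations = 40L, singletons = TRUE,
                 restarts = 5L, linkage = linkage, seed = seed)
}

# truth lookup helper
truthConditions <- function(coh) {
  setNames(coh$truth$condition, coh$truth$case_id)
}
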