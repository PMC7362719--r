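#' Configuration of a five-step blinded run
#'
#' @param seed master seed for every stochastic stage.
#' @param step1_set feature set clustered at Step 1 (default the
#'   fine-resolution power set, with the spectral labeling rule applied
#'   to it).
#' @param ensemble an [ensembleConfig()] for the case-level ensembles
#'   (Steps 1 and 3c/3d).
#' @param paired_ensemble an [ensembleConfig()] for the pairwise
#'   hyperplane ensembles (Steps 2--4); singleton runs are pointless in
#'   1-D orientation space and default off.
#' @param mc_reps Monte-Carlo draws for goodness normalization.
#' @param ica_keep fraction of ICA components retained at Steps 3--4.
#' @param screen run the Step-1 temporal-consistency screen and record
#'   its report (the clustered set remains `step1_set`).
#' @param screen_sets candidate sets for the screen.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, step1_set = "powerfine",
                      ensemble = ensembleConfig(seed = seed),
                      paired_ensemble = ensembleConfig(singletons = FALSE,
                                                       seed = seed),
                      mc_reps = 1000L, ica_keep = 0.5,
                      screen = FALSE,
                      screen_sets = c("powerband", "powerfine", "eogrms", "emgrms")) {
  structure(list(seed = seed, step1_set = step1_set, ensemble = ensemble,
                 paired_ensemble = paired_ensemble, mc_reps = mc_reps,
                 ica_keep = ica_keep, screen = screen, screen_sets = screen_sets),
            class = "RunConfig")
}

.asNamed <- function(rv, col) setNames(rv[[col]], rv$case_id)

.predictFromClusters <- function(labels, mapping) {
  setNames(unname(mapping[as.character(labels)]), names(labels))
}

#' Run one step of the blinded classification
#'
#' Each step sees only [reveal()]`(oracle, step)` plus the cases
#' themselves; the truth never enters (and [truthTable()] on the oracle
#' is an error by construction).
#'
#' Step 1: combination clustering of the chosen feature set, spectral
#' labeling.  Step 2: Step-2 feature assembly, Studentization, pairwise
#' hyperplane ensemble (average linkage), spectral labeling.  Step 3:
#' per-participant ICA cleanup, the four-way similarity, Ward
#' extraction, spectral labeling.  Step 4: adjusted ICA cleanup,
#' condition-group difference vectors, hyperplane ensemble, spectral +
#' frontal-high labeling.  Step 5: the three literature features,
#' per-participant centering, majority vote.
#'
#' @param step integer 1--5.
#' @param cases blinded cohort (list of \linkS4class{PsgCase}).
#' @param oracle a \linkS4class{DataTeamOracle} (used only via
#'   [reveal()]).
#' @param config a [runConfig()].
#' @return list with `predictions` (named condition per case id),
#'   `call` (the `ConditionCall`), `artifacts` (step-specific objects).
#' @export
runStep <- function(step, cases, oracle, config = runConfig()) {
  step <- as.integer(step)
  rv <- reveal(oracle, step)
  ids <- vapply(cases, caseId, "")
  if (!setequal(ids, rv$case_id)) .fail("cases and blinding key disagree")
  artifacts <- list()
  if (step == 1L) {
    if (isTRUE(config$screen)) {
      artifacts$screen <- screenFeatureSets(cases, config$screen_sets,
                                            config = config$ensemble)
    }
    fm <- extractFeatures(cases, config$step1_set)
    cc <- runCombinationClustering(fm, config$ensemble)
    labFm <- if (any(grepl("Hz", colnames(featureValues(fm))))) fm
             else extractFeatures(cases, "powerfine")
    call <- labelBySpectrum(cc$result$labels, labFm)
    preds <- .predictFromClusters(cc$result$labels, call$mapping)
    artifacts$clustering <- cc
  } else if (step == 2L) {
    pairs <- .asNamed(rv, "pair")
    fm <- extractFeatures(cases, "step2_50")
    st <- studentize(fm)
    cfg <- config$paired_ensemble; cfg$linkage <- "average"
    cc <- runPairwiseClustering(st, pairs, cfg, mc_reps = config$mc_reps)
    call <- labelBySpectrum(cc$result$labels, fm)
    preds <- .predictFromClusters(cc$result$labels, call$mapping)
    artifacts$clustering <- cc
  } else if (step == 3L) {
    pairs <- .asNamed(rv, "pair"); parts <- .asNamed(rv, "participant")
    cleaned <- icaCleanCohort(cases, parts, pairs = pairs,
                              keep_fraction = config$ica_keep,
                              seed = subSeed(config$seed, 3L))
    fm <- extractFeatures(cleaned, "step2_50")
    st <- studentize(fm)
    cfg <- config$paired_ensemble; cfg$seed <- subSeed(config$seed, 33L)
    co <- step3Similarity(st, pairs, parts, cfg, mc_reps = config$mc_reps)
    res <- extractTwoClusters(co, "ward")
    call <- labelBySpectrum(res$labels, fm)
    preds <- .predictFromClusters(res$labels, call$mapping)
    artifacts$clustering <- list(result = res, coassoc = co)
  } else if (step == 4L) {
    parts <- .asNamed(rv, "participant"); groups <- .asNamed(rv, "participant_condition")
    cleaned <- icaCleanCohort(cases, parts, groups = groups,
                              keep_fraction = config$ica_keep,
                              seed = subSeed(config$seed, 4L))
    fm <- extractFeatures(cleaned, "step2_50")
    st <- studentize(fm)
    cfg <- config$paired_ensemble; cfg$seed <- subSeed(config$seed, 44L)
    cfg$linkage <- "ward"
    cc <- runStep4Clustering(st, groups, parts, cfg, mc_reps = config$mc_reps)
    call <- labelStep4(cc$result$labels, fm)
    preds <- .predictFromClusters(cc$result$labels, call$mapping)
    artifacts$clustering <- cc
  } else if (step == 5L) {
    conds <- .asNamed(rv, "condition"); parts <- .asNamed(rv, "participant")
    fm <- extractFeatures(cases, "step5")
    cl <- sort(unique(conds))
    groupA <- names(conds)[conds == cl[1]]
    groupB <- names(conds)[conds == cl[2]]
    call <- labelStep5(fm, groupA, groupB, parts)
    preds <- setNames(ifelse(conds == cl[1], call$mapping[["A"]],
                             call$mapping[["B"]]), names(conds))
    artifacts$features <- fm
  } else .fail("step must be 1..5")
  list(predictions = preds[sort(names(preds))], call = call, artifacts = artifacts)
}

#' Run the full five-step blinded experiment
#'
#' Runs the requested steps in order, submits each step's predictions
#' to the oracle for scoring (the only feedback the analysis side ever
#' receives, mirroring the protocol), and assembles the summary
#' performance table.
#'
#' @param cases blinded cohort.
#' @param oracle a \linkS4class{DataTeamOracle}.
#' @param config a [runConfig()].
#' @param steps which steps to run (default all five).
#' @return list with `table` (five-row performance report), `results`
#'   (per-step [scoreStep()] rows) and `steps` (per-step [runStep()]
#'   outputs).
#' @export
runExperiment <- function(cases, oracle, config = runConfig(), steps = 1:5) {
  outs <- list(); results <- list()
  for (s in steps) {
    outs[[as.character(s)]] <- runStep(s, cases, oracle, config)
    results[[as.character(s)]] <- scoreStep(oracle, outs[[as.character(s)]]$predictions, s)
  }
  list(table = table2Report(results), results = results, steps = outs)
}
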