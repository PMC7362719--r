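#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom stats fft var sd quantile dbinom qt median acf dist hclust
#'   cutree kmeans rnorm runif cov t.test complete.cases setNames
#' @importFrom utils read.csv write.csv head combn
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PsgCase: one multichannel polysomnogram segment
#'
#' A single (typically 60-s, typically blinded) polysomnogram case:
#' a samples-by-channels matrix in microvolts together with channel
#' metadata and the sampling rate.
#'
#' @slot caseId character scalar, e.g. `"ID07"`.
#' @slot channels data.frame with columns `name`, `modality`
#'   (EEG/EOG/EMG) and `position` (nominal scalp region for EEG channels,
#'   `NA` otherwise).
#' @slot samples numeric matrix, one column per channel, microvolts.
#' @slot rate sampling rate in Hz.
#'
#' @examples
#' cs <- synthCase(cohortConfig(rate = 128), participantState(cohortConfig(), 1),
#'                 condition = "dreamless", session = 1, seed = 1)
#' duration(cs)
#' @export
setClass("PsgCase", representation(
  caseId   = "character",
  channels = "data.frame",
  samples  = "matrix",
  rate     = "numeric"
))

setValidity("PsgCase", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(object@caseId) != 1L) msg <- c(msg, "caseId must be a single string")
  need <- c("name", "modality", "position")
  if (!all(need %in% names(ch))) {
    msg <- c(msg, "channels needs columns name, modality, position")
  } else {
    if (ncol(object@samples) != nrow(ch)) {
      msg <- c(msg, sprintf("case %s: %d channel rows but %d sample columns",
                            object@caseId, nrow(ch), ncol(object@samples)))
    }
    bad <- setdiff(unique(ch$modality), c("EEG", "EOG", "EMG"))
    if (length(bad)) msg <- c(msg, paste("unknown modality:", paste(bad, collapse = ", ")))
    if (any(ch$modality == "EEG" & (is.na(ch$position) | ch$position == ""))) {
      msg <- c(msg, sprintf("case %s: every EEG channel needs a position tag", object@caseId))
    }
  }
  if (length(object@rate) != 1L || object@rate <= 0) msg <- c(msg, "rate must be a positive scalar")
  if (anyNA(object@samples)) msg <- c(msg, sprintf("case %s has missing samples", object@caseId))
  if (length(msg)) msg else TRUE
})

#' BlindKey: blinded case labels
#'
#' The Data Team's randomized label assignment for a 54-case cohort:
#' per case a recording label (ID01--ID54), pair label (P01--P27),
#' participant label (S1--S9), participant-condition group label
#' (G01--G18) and condition label (C1--C2).  The true condition name
#' map (C1/C2 to dreamful/dreamless) and the original recording
#' identities are held in separate slots that [reveal()] never exposes.
#'
#' @slot key data.frame with columns `case_id`, `pair`, `participant`,
#'   `participant_condition`, `condition`.
#' @slot conditionMap named character of length 2 mapping C labels to
#'   condition names; never returned by any reveal step.
#' @slot recording character vector of original recording ids, parallel
#'   to the rows of `key`.
#' @export
setClass("BlindKey", representation(
  key          = "data.frame",
  conditionMap = "character",
  recording    = "character"
))

setValidity("BlindKey", function(object) {
  k <- object@key
  msg <- character()
  need <- c("case_id", "pair", "participant", "participant_condition", "condition")
  if (!all(need %in% names(k))) return(paste("key needs columns", paste(need, collapse = ", ")))
  card <- c(case_id = 54L, participant = 9L, condition = 2L,
            participant_condition = 18L, pair = 27L)
  if (nrow(k) != 54L) msg <- c(msg, sprintf("key has %d rows, expected 54", nrow(k)))
  for (col in names(card)) {
    n <- length(unique(k[[col]]))
    if (n != card[[col]]) {
      msg <- c(msg, sprintf("%s has %d distinct labels, expected %d", col, n, card[[col]]))
    }
  }
  if (!length(msg)) {
    if (any(table(k$participant) != 6L)) msg <- c(msg, "each participant must own 6 cases")
    if (any(table(k$participant, k$condition) != 3L)) {
      msg <- c(msg, "each participant needs 3 cases per condition")
    }
    pc <- table(k$pair, k$condition)
    if (any(pc != 1L)) msg <- c(msg, "each pair needs one case of each condition")
    pp <- tapply(k$participant, k$pair, function(x) length(unique(x)))
    if (any(pp != 1L)) msg <- c(msg, "pair members must share a participant")
  }
  if (!setequal(sort(unique(k$condition)), names(object@conditionMap)) ||
      !setequal(object@conditionMap, c("dreamful", "dreamless"))) {
    msg <- c(msg, "conditionMap must map the two C labels onto dreamful/dreamless")
  }
  if (length(object@recording) != nrow(k)) msg <- c(msg, "recording must parallel key rows")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: cases-by-features container
#'
#' Extends \linkS4class{SummarizedExperiment}; the single assay `"values"`
#' is stored features-by-cases.  `transforms` records provenance flags
#' (`"log"`, `"studentized"`).
#'
#' @slot transforms character vector of transform flags.
#' @export
setClass("FeatureMatrix",
         contains = "SummarizedExperiment",
         representation(transforms = "character"))

setValidity("FeatureMatrix", function(object) {
  a <- SummarizedExperiment::assay(object)
  msg <- character()
  if (anyNA(a)) msg <- c(msg, "feature values must not contain NA")
  if (anyDuplicated(rownames(a))) msg <- c(msg, "feature names must be unique")
  if (is.null(colnames(a))) msg <- c(msg, "case ids (colnames) are required")
  if (length(msg)) msg else TRUE
})

#' CoAssocMatrix: weighted co-association similarity
#'
#' Symmetric matrix of ensemble co-association frequencies in [0, 1]
#' with unit diagonal.
#'
#' @slot values numeric matrix.
#' @export
setClass("CoAssocMatrix", representation(values = "matrix"))

setValidity("CoAssocMatrix", function(object) {
  m <- object@values
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
  else {
    if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "must be symmetric")
    if (any(m < -1e-8) || any(m > 1 + 1e-8)) msg <- c(msg, "entries must lie in [0, 1]")
    if (any(abs(diag(m) - 1) > 1e-8)) msg <- c(msg, "diagonal must be 1")
    if (is.null(rownames(m))) msg <- c(msg, "case ids (dimnames) are required")
  }
  if (length(msg)) msg else TRUE
})

#' DataTeamOracle: the scoring side of the blinded protocol
#'
#' Holds the truth table and the blinding key.  Analysis code may only
#' request step-wise reveals and accuracy scores; the truth itself is
#' guarded ([truthTable()] on an oracle is an error).
#'
#' @slot truth data.frame with columns `case_id`, `participant`,
#'   `session`, `condition` (condition names, never shown to analysis).
#' @slot key a \linkS4class{BlindKey}.
#' @export
setClass("DataTeamOracle", representation(truth = "data.frame", key = "BlindKey"))
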