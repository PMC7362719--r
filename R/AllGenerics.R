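#' @rdname PsgCase-class
#' @param object,x a \linkS4class{PsgCase} (or other object, per method).
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname PsgCase-class
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' @rdname PsgCase-class
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname PsgCase-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname PsgCase-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Reveal blinded case information for a given step
#'
#' Returns the view of a blinding key the Analysis Team is allowed to see
#' at a given step of the protocol (see [revealLevel()] for the schedule).
#' Condition *names* (dreamful/dreamless) are never exposed by any step.
#'
#' @param key a \linkS4class{BlindKey} or \linkS4class{DataTeamOracle}.
#' @param step integer 1--5.
#' @return data.frame with `case_id` plus the columns disclosed at `step`.
#' @export
setGeneric("reveal", function(key, step) standardGeneric("reveal"))

#' @rdname FeatureMatrix
#' @param x a \linkS4class{FeatureMatrix}.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix
#' @export
setGeneric("transforms", function(x) standardGeneric("transforms"))

#' @rdname CoAssocMatrix-class
#' @param x a \linkS4class{CoAssocMatrix}.
#' @export
setGeneric("coAssocValues", function(x) standardGeneric("coAssocValues"))

#' Guarded access to the truth table
#'
#' For a \linkS4class{DataTeamOracle} this is always an error: the truth
#' never crosses to the analysis side.  It succeeds only on the plain
#' truth data.frame returned by [synthCohort()], which by contract is
#' kept out of analysis inputs.
#'
#' @param x an object holding (or guarding) ground truth.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' Score a submitted classification at a step's decision granularity
#'
#' @param oracle a \linkS4class{DataTeamOracle}.
#' @param predictions named character vector of predicted condition names
#'   (`"dreamful"`/`"dreamless"`) per case id.
#' @param step integer 1--5; sets the decision granularity
#'   (case / pair / pair / participant / condition group).
#' @return a one-row data.frame (`StepResult`): step, decisions, correct,
#'   accuracy (percent) and two-tailed binomial p.
#' @export
setGeneric("scoreStep", function(oracle, predictions, step) standardGeneric("scoreStep"))
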