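#' Standard 29-channel polysomnogram montage
#'
#' The montage used for synthetic cohorts and expected of standard input
#' cohorts: 25 EEG channels on a 10-20/10-10 subset plus 2 EOG and 2 EMG
#' channels.  EEG position tags are nominal scalp regions (`frontal`,
#' `central`, `temporal`, `parieto-occipital`) used by the regional
#' feature definitions.
#'
#' @return data.frame with columns `name`, `modality`, `position`.
#' @export
standardMontage <- function() {
  eeg <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
           "FT7", "FC3", "FCz", "FC4", "FT8",
           "T7", "C3", "Cz", "C4", "T8",
           "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
  pos <- c(Fp1 = "frontal", Fp2 = "frontal", F7 = "frontal", F3 = "frontal",
           Fz = "frontal", F4 = "frontal", F8 = "frontal",
           FT7 = "temporal", FC3 = "frontal", FCz = "frontal", FC4 = "frontal",
           FT8 = "temporal",
           T7 = "temporal", C3 = "central", Cz = "central", C4 = "central",
           T8 = "temporal",
           P7 = "temporal", P3 = "parieto-occipital", Pz = "parieto-occipital",
           P4 = "parieto-occipital", P8 = "temporal",
           O1 = "parieto-occipital", Oz = "parieto-occipital", O2 = "parieto-occipital")
  data.frame(
    name = c(eeg, "EOG1", "EOG2", "EMG1", "EMG2"),
    modality = c(rep("EEG", 25L), "EOG", "EOG", "EMG", "EMG"),
    position = c(unname(pos[eeg]), NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Named electrode groups used by regional features
#'
#' Electrode groups derived from the standard montage: the broad position
#' tags plus the finer groups needed by the literature-derived ("hot
#' zone") features.  `fusiform-proxy` is a posterior-temporal stand-in
#' for a source-level region that scalp channels cannot isolate.
#'
#' @param group one of `"parieto-occipital"`, `"frontal"`, `"central"`,
#'   `"temporal"`, `"lateral-frontal"`, `"left-fronto-temporal"`,
#'   `"occipital"`, `"fusiform-proxy"`.
#' @param channels channel data.frame (default [standardMontage()]).
#' @return character vector of EEG channel names.
#' @export
electrodeGroup <- function(group, channels = standardMontage()) {
  eeg <- channels[channels$modality == "EEG", , drop = FALSE]
  byPos <- function(p) eeg$name[!is.na(eeg$position) & eeg$position == p]
  fixed <- list(
    "lateral-frontal"      = c("F7", "F8", "FT7", "FT8"),
    "left-fronto-temporal" = c("Fp1", "F7", "F3", "FT7", "T7"),
    "occipital"            = c("O1", "Oz", "O2"),
    "fusiform-proxy"       = c("P7", "P8", "T7", "T8")
  )
  out <- if (group %in% names(fixed)) intersect(fixed[[group]], eeg$name) else byPos(group)
  if (!length(out)) .fail("montage has no channels for position group '%s'", group)
  out
}

#' Construct a PsgCase
#'
#' @param caseId case label, e.g. `"ID01"`.
#' @param samples numeric matrix, samples by channels, microvolts.
#' @param rate sampling rate (Hz).
#' @param channels channel data.frame (`name`, `modality`, `position`);
#'   defaults to [standardMontage()] when the column count matches.
#' @return a \linkS4class{PsgCase}.
#' @export
PsgCase <- function(caseId, samples, rate, channels = NULL) {
  if (is.null(channels)) {
    std <- standardMontage()
    if (ncol(samples) != nrow(std)) {
      .fail("case %s: %d sample columns but no channel table given", caseId, ncol(samples))
    }
    channels <- std
  }
  colnames(samples) <- channels$name
  new("PsgCase", caseId = as.character(caseId), channels = channels,
      samples = samples, rate = as.numeric(rate))
}

#' @rdname PsgCase-class
#' @export
setMethod("caseId", "PsgCase", function(x) x@caseId)

#' @rdname PsgCase-class
#' @export
setMethod("channelInfo", "PsgCase", function(x) x@channels)

#' @rdname PsgCase-class
#' @export
setMethod("samples", "PsgCase", function(x) x@samples)

#' @rdname PsgCase-class
#' @export
setMethod("samplingRate", "PsgCase", function(x) x@rate)

#' @rdname PsgCase-class
#' @export
setMethod("duration", "PsgCase", function(x) nrow(x@samples) / x@rate)

setMethod("show", "PsgCase", function(object) {
  tab <- table(object@channels$modality)
  cat(sprintf("PsgCase %s: %.6g s @ %g Hz, %s\n", object@caseId,
              duration(object), object@rate,
              paste(sprintf("%d %s", tab, names(tab)), collapse = " + ")))
})

# Extract the samples matrix restricted to one modality (or channel names).
#' @rdname PsgCase-class
#' @param modality one of "EEG", "EOG", "EMG".
#' @export
modalitySamples <- function(x, modality) {
  sel <- x@channels$modality == modality
  if (!any(sel)) .fail("case %s has no %s channels", x@caseId, modality)
  x@samples[, sel, drop = FALSE]
}

#' Check that a case satisfies the standard-cohort contract
#'
#' 60 s duration, 25 EEG + 2 EOG + 2 EMG channels, no missing samples.
#' Errors name the case and the violated constraint.
#'
#' @param case a \linkS4class{PsgCase}.
#' @return invisibly `TRUE`.
#' @export
assertStandardCase <- function(case) {
  d <- duration(case)
  if (abs(d - 60) > 1 / case@rate) {
    .fail("case %s: duration %.4g s violates the 60 s contract", case@caseId, d)
  }
  want <- c(EEG = 25L, EOG = 2L, EMG = 2L)
  have <- table(factor(case@channels$modality, levels = names(want)))
  for (m in names(want)) {
    if (have[[m]] != want[[m]]) {
      .fail("case %s: %d %s channels present, %d required (absent/extra modality)",
            case@caseId, have[[m]], m, want[[m]])
    }
  }
  invisible(TRUE)
}
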