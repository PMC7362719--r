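#' Disclosure schedule of the five-step protocol
#'
#' Cumulative disclosure per step: nothing beyond case ids at Step 1,
#' pairs at Step 2, participants at Step 3, participant-condition groups
#' at Step 4, condition groups at Step 5.  Condition *names* are never
#' disclosed.
#'
#' @param step integer 1--5.
#' @return list with elements `step` and `disclosed` (character vector).
#' @export
revealLevel <- function(step) {
  step <- as.integer(step)
  if (length(step) != 1L || is.na(step) || step < 1L || step > 5L) {
    .fail("step must be an integer in 1..5")
  }
  sched <- list(
    character(0),
    "pair",
    c("pair", "participant"),
    c("pair", "participant", "participant_condition"),
    c("pair", "participant", "participant_condition", "condition")
  )
  list(step = step, disclosed = sched[[step]])
}

#' Randomly blind a balanced cohort's metadata
#'
#' Emulates the Data Team's labeling: random bijections from true
#' identities onto consecutive blinded labels (ID01--ID54, S1--S9,
#' C1--C2, G01--G18, P01--P27).  The metadata must describe a balanced
#' 9 participants x 3 sessions x 2 conditions design.
#'
#' @param truth data.frame with columns `recording` (unique id),
#'   `participant`, `session` (1--3) and `condition`
#'   (`"dreamful"`/`"dreamless"`).
#' @param seed integer seed; fixed seed gives an identical key.
#' @return a \linkS4class{BlindKey}.
#' @export
applyBlinding <- function(truth, seed) {
  need <- c("recording", "participant", "session", "condition")
  if (!all(need %in% names(truth))) .fail("truth needs columns %s", paste(need, collapse = ", "))
  parts <- sort(unique(truth$participant))
  sess <- sort(unique(truth$session))
  conds <- sort(unique(truth$condition))
  if (length(parts) != 9L || length(sess) != 3L ||
      !setequal(conds, c("dreamful", "dreamless")) || nrow(truth) != 54L ||
      any(table(truth$participant, truth$session, truth$condition) != 1L)) {
    .fail("metadata must be a balanced 9 participants x 3 sessions x 2 conditions design")
  }
  withSeed(seed, {
    idPerm <- sample.int(54L)
    sPerm <- sample.int(9L)
    cPerm <- sample.int(2L)
    gPerm <- sample.int(18L)
    pPerm <- sample.int(27L)
    caseId <- sprintf("ID%02d", idPerm)
    pIdx <- match(truth$participant, parts)
    cIdx <- match(truth$condition, conds)
    sIdx <- match(truth$session, sess)
    key <- data.frame(
      case_id = caseId,
      pair = sprintf("P%02d", pPerm[(pIdx - 1L) * 3L + sIdx]),
      participant = sprintf("S%d", sPerm[pIdx]),
      participant_condition = sprintf("G%02d", gPerm[(pIdx - 1L) * 2L + cIdx]),
      condition = sprintf("C%d", cPerm[cIdx]),
      stringsAsFactors = FALSE
    )
    cmap <- setNames(conds, sprintf("C%d", cPerm))
    cmap <- cmap[order(names(cmap))]
    ord <- order(key$case_id)
    key <- key[ord, , drop = FALSE]
    rownames(key) <- NULL
    new("BlindKey", key = key,
        conditionMap = cmap, recording = as.character(truth$recording)[ord])
  })
}

#' @describeIn reveal step-restricted view of a blinding key.
#' @export
setMethod("reveal", "BlindKey", function(key, step) {
  lv <- revealLevel(step)
  out <- key@key[, c("case_id", lv$disclosed), drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @rdname truthTable
#' @export
setMethod("truthTable", "BlindKey", function(x) {
  .fail("blinded: a BlindKey never returns the condition name mapping")
})

setMethod("show", "BlindKey", function(object) {
  cat(sprintf("BlindKey: %d cases, %d pairs, %d participants (condition map withheld)\n",
              nrow(object@key), length(unique(object@key$pair)),
              length(unique(object@key$participant))))
})

#' Write / read a blinding key as CSV
#'
#' The key CSV has header
#' `case_id,pair,participant,participant_condition,condition` and
#' round-trips exactly.  The condition name map is *not* written; use
#' [writeTruth()] for the separate truth file that analysis code never
#' reads.
#'
#' @param key a \linkS4class{BlindKey}.
#' @param path CSV file path.
#' @export
writeBlindKey <- function(key, path) {
  write.csv(key@key, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBlindKey
#' @param conditionMap,recording optional slots when reconstructing a
#'   scoring-capable key; reading a key CSV alone yields a view-only
#'   data.frame.
#' @export
readBlindKeyTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write the truth table kept apart from analysis inputs
#'
#' @param truth data.frame (`recording`/`case_id`, `participant`,
#'   `session`, `condition`).
#' @param path CSV file path.
#' @export
writeTruth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
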