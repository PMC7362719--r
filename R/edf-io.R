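# Minimal continuous-EDF writer/reader (16-bit, one data record per
# second) plus a lossless float64 + JSON-header fallback.  EDF is the
# polysomnography interchange standard; its 16-bit quantization makes the
# raw fallback the right choice when tests need exact round-trips.

.padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write one case to an EDF file
#'
#' Continuous EDF, one 1-s data record per second of signal, physical
#' units uV, digital range -32768..32767.  The channel label encodes the
#' modality as `"<MOD> <name>"` (e.g. `"EEG Fp1"`).
#'
#' @param case a \linkS4class{PsgCase}; the sampling rate must be an
#'   integer and the duration a whole number of seconds.
#' @param path output file.
#' @return invisibly the per-channel quantization step (uV).
#' @export
writeEdf <- function(case, path) {
  x <- samples(case)
  rate <- samplingRate(case)
  if (rate != round(rate)) .fail("EDF export requires an integer sampling rate")
  nRec <- nrow(x) / rate
  if (nRec != round(nRec)) .fail("EDF export requires a whole number of seconds")
  ns <- ncol(x)
  physMax <- signif(pmax(apply(abs(x), 2, max), 1e-6), 6)
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(v, w) writeChar(paste0(vapply(v, .padField, "", width = w), collapse = ""),
                                 con, eos = NULL)
  wf("0", 8); wf(caseId(case), 80); wf("dreamcatcher synthetic PSG", 80)
  wf("01.01.20", 8); wf("00.00.00", 8)
  wf(256 + ns * 256, 8); wf("", 44); wf(nRec, 8); wf(1, 8); wf(ns, 4)
  ch <- channelInfo(case)
  wf(paste(ch$modality, ch$name), 16)
  wf(rep("", ns), 80); wf(rep("uV", ns), 8)
  wf(sprintf("%.6g", -physMax), 8); wf(sprintf("%.6g", physMax), 8)
  wf(rep(-32768L, ns), 8); wf(rep(32767L, ns), 8)
  wf(rep("", ns), 80); wf(rep(rate, ns), 8); wf(rep("", ns), 32)
  scale <- (2 * physMax) / (32767 - (-32768))
  dig <- matrix(0L, nrow(x), ns)
  for (j in seq_len(ns)) {
    dig[, j] <- as.integer(pmax(-32768, pmin(32767, round((x[, j] - (-physMax[j])) / scale[j]) - 32768)))
  }
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    writeBin(as.integer(as.vector(dig[idx, ])), con, size = 2L, endian = "little")
  }
  invisible(scale)
}

.parseEdfLabel <- function(label) {
  parts <- strsplit(trimws(label), "\\s+")[[1]]
  if (length(parts) < 2L || !parts[1] %in% c("EEG", "EOG", "EMG")) {
    .fail("channel label '%s' does not parse into a modality + name", label)
  }
  c(modality = parts[1], name = paste(parts[-1], collapse = " "))
}

#' Read one EDF file as a PsgCase
#'
#' @param path EDF file written by [writeEdf()] or compatible
#'   single-rate continuous EDF with `"<MOD> <name>"` channel labels.
#' @return a \linkS4class{PsgCase}.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); pid <- rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8)); recDur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    .fail("case %s: inconsistent sampling rate across channels (%s)",
          pid, paste(unique(spr), collapse = ", "))
  }
  rate <- spr[1] / recDur
  parsed <- t(vapply(labels, .parseEdfLabel, c(modality = "", name = "")))
  std <- standardMontage()
  channels <- data.frame(name = parsed[, "name"], modality = parsed[, "modality"],
                         position = std$position[match(parsed[, "name"], std$name)],
                         stringsAsFactors = FALSE)
  out <- matrix(0, nRec * spr[1], ns)
  for (r in seq_len(nRec)) {
    block <- readBin(con, "integer", n = sum(spr), size = 2L, endian = "little")
    if (length(block) < sum(spr)) .fail("case %s: truncated record %d", pid, r)
    m <- matrix(block, spr[1], ns)
    out[((r - 1) * spr[1] + 1):(r * spr[1]), ] <- m
  }
  for (j in seq_len(ns)) {
    out[, j] <- physMin[j] + (out[, j] - digMin[j]) *
      (physMax[j] - physMin[j]) / (digMax[j] - digMin[j])
  }
  PsgCase(pid, out, rate, channels)
}

.writeRaw <- function(case, stem) {
  hdr <- list(case_id = caseId(case), rate = samplingRate(case),
              n_samples = nrow(samples(case)), channels = channelInfo(case))
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(samples(case)), con, size = 8L, endian = "little")
}

.readRaw <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  ch <- as.data.frame(hdr$channels, stringsAsFactors = FALSE)
  if (!"position" %in% names(ch)) ch$position <- NA_character_
  ch$position[!is.na(ch$position) & ch$position == "NA"] <- NA
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = hdr$n_samples * nrow(ch), size = 8L, endian = "little")
  if (length(v) < hdr$n_samples * nrow(ch)) {
    .fail("case %s: truncated raw record", hdr$case_id)
  }
  PsgCase(hdr$case_id, matrix(v, hdr$n_samples, nrow(ch)), hdr$rate, ch)
}

#' Write a blinded cohort to disk
#'
#' One file per case (EDF by default, or the exact float64 `raw`
#' format), plus the blinding key as `key.csv`.  The truth map is never
#' written by this function.
#'
#' @param cases list of \linkS4class{PsgCase} (a full standard cohort).
#' @param key a \linkS4class{BlindKey}.
#' @param path output directory (created if needed).
#' @param format `"edf"` (16-bit quantized) or `"raw"` (lossless).
#' @return invisibly `path`.
#' @export
writeCohort <- function(cases, key, path, format = c("edf", "raw")) {
  format <- match.arg(format)
  if (length(cases) != 54L) .fail("a standard cohort has 54 cases, got %d", length(cases))
  for (cs in cases) assertStandardCase(cs)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (cs in cases) {
    if (format == "edf") writeEdf(cs, file.path(path, paste0(caseId(cs), ".edf")))
    else .writeRaw(cs, file.path(path, caseId(cs)))
  }
  writeBlindKey(key, file.path(path, "key.csv"))
  invisible(path)
}

#' Read a cohort directory
#'
#' Reads every case file in a directory written by [writeCohort()] and
#' checks the standard-cohort contract per case.
#'
#' @param path directory of `.edf` (or `.json`/`.dat`) case files.
#' @param format `"edf"` or `"raw"`.
#' @return list of \linkS4class{PsgCase} sorted by case id.
#' @export
readCohort <- function(path, format = c("edf", "raw")) {
  format <- match.arg(format)
  files <- if (format == "edf") {
    sort(list.files(path, pattern = "\\.edf$", full.names = TRUE))
  } else {
    sub("\\.json$", "", sort(list.files(path, pattern = "\\.json$", full.names = TRUE)))
  }
  files <- files[!grepl("key|truth", basename(files))]
  if (!length(files)) .fail("no case files found under %s", path)
  cases <- lapply(files, if (format == "edf") readEdf else .readRaw)
  for (cs in cases) assertStandardCase(cs)
  cases[order(vapply(cases, caseId, ""))]
}
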