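#' Write / read a recording as CSV
#'
#' The CSV dialect stores one column per channel (header row = channel
#' names) and one row per sample, in microvolts.  Recording metadata
#' (sampling rate, label, condition, subject) lives in the cohort manifest,
#' not the CSV, and must be supplied when reading a file on its own.
#'
#' @param rec An \linkS4class{EEGRecording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  m <- t(eegData(rec))
  colnames(m) <- channelNames(rec)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecordingCSV
#' @param fs Sampling rate in Hz.
#' @param label,condition,subjectId Recording metadata.
#' @export
readRecordingCSV <- function(path, fs, label, condition = "baseline",
                             subjectId = basename(path)) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  new("EEGRecording", data = t(m), fs = fs,
      channelNames = colnames(m), label = label, condition = condition,
      subjectId = subjectId)
}

#' Write a cohort to disk
#'
#' Writes one CSV per recording plus a tab-separated manifest
#' (subject_id, file, label, condition, fs, seed) that
#' \code{\link{readCohort}} consumes.
#'
#' @param recs List of \linkS4class{EEGRecording}.
#' @param dir Output directory (created if needed).
#' @param seeds Optional per-recording seeds to log in the manifest.
#' @return Manifest path, invisibly.
#' @export
writeCohort <- function(recs, dir, seeds = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(seq_along(recs), function(i) {
    f <- sprintf("%s_%s.csv", subjectId(recs[[i]]), condition(recs[[i]]))
    writeRecordingCSV(recs[[i]], file.path(dir, f))
    f
  }, "")
  manifest <- data.frame(
    subject_id = vapply(recs, subjectId, ""),
    file = files,
    label = vapply(recs, stressLabel, ""),
    condition = vapply(recs, condition, ""),
    fs = vapply(recs, samplingRate, numeric(1)),
    seed = seeds, stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' @rdname writeCohort
#' @param manifest Path to a manifest.tsv written by \code{writeCohort}.
#' @export
readCohort <- function(manifest) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "file", "label", "condition", "fs")
  if (!all(need %in% names(man)))
    .stopf("manifest lacks column(s): %s", paste(setdiff(need, names(man)), collapse = ", "))
  lapply(seq_len(nrow(man)), function(i)
    readRecordingCSV(file.path(dirname(manifest), man$file[i]), man$fs[i],
                     man$label[i], man$condition[i], man$subject_id[i]))
}

#' Write a region feature table as TSV
#'
#' @param featureTable data.frame from \code{\link{extractRegionFeatures}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(featureTable, path) {
  utils::write.table(featureTable, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
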