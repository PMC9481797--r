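#' @title EEG trial sets
#' @description A `trial_set` bundles single-trial EEG matrices (sensors x
#'   samples, microvolts) with their metadata: binary label (1 = "buy",
#'   0 = "no-buy"), subject id, group id (the stimulus/product a trial
#'   belongs to — groups are the unit of train/test splitting), and the
#'   common sampling rate.
#' @name trialset
NULL

#' Construct a trial set
#'
#' @param trials list of numeric matrices, sensors in rows; all trials must
#'   share the sensor count.
#' @param label integer vector of 0/1 class labels.
#' @param subject subject id per trial.
#' @param group group (stimulus/product) id per trial.
#' @param fs sampling rate in Hz.
#' @param trial_id optional trial identifiers (default `"t1"`, `"t2"`, ...).
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(trials, label, subject, group, fs, trial_id = NULL) {
  n <- length(trials)
  if (n == 0) stop_invalid("empty trial list")
  if (length(label) != n || length(subject) != n || length(group) != n)
    stop_invalid("metadata length must match the number of trials")
  if (!all(vapply(trials, is.matrix, logical(1))))
    stop_invalid("each trial must be a numeric matrix")
  S <- nrow(trials[[1]])
  if (!all(vapply(trials, nrow, integer(1)) == S))
    stop_invalid("inconsistent sensor count across trials")
  if (!all(label %in% c(0, 1))) stop_invalid("labels must be binary 0/1")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_invalid("fs must be a positive scalar (Hz)")
  structure(list(
    trials = trials,
    label = as.integer(label),
    subject = as.character(subject),
    group = as.character(group),
    fs = fs,
    trial_id = as.character(trial_id %||% paste0("t", seq_len(n)))
  ), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials, %d sensors, fs = %g Hz, %d subject(s), %d group(s); labels: %d/%d (1/0)\n",
    length(x$trials), nrow(x$trials[[1]]), x$fs,
    length(unique(x$subject)), length(unique(x$group)),
    sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' Subset a trial set by trial index
#'
#' @param ts a `trial_set`.
#' @param idx integer or logical index over trials.
#' @return a `trial_set` with metadata pairing preserved.
#' @export
subset_trials <- function(ts, idx) {
  stopifnot(inherits(ts, "trial_set"))
  trial_set(ts$trials[idx], ts$label[idx], ts$subject[idx], ts$group[idx],
            ts$fs, ts$trial_id[idx])
}

#' Read a trial set from a JSON-lines manifest
#'
#' The manifest has one JSON object per line with fields `trial_id`,
#' `subject`, `group`, `label`, `fs` and `file`; `file` is the path (relative
#' to the manifest) of a whitespace-delimited matrix, sensors in rows.
#'
#' @param manifest path to the manifest file.
#' @return a `trial_set`.
#' @export
read_trialset <- function(manifest) {
  lines <- readLines(manifest)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_invalid("empty manifest: ", manifest)
  recs <- lapply(lines, jsonlite::fromJSON)
  base <- dirname(manifest)
  trials <- lapply(recs, function(r)
    as.matrix(utils::read.table(file.path(base, r$file))))
  trials <- lapply(trials, function(m) {
    dimnames(m) <- NULL
    m
  })
  fs <- unique(vapply(recs, function(r) as.numeric(r$fs), numeric(1)))
  if (length(fs) != 1) stop_invalid("manifest mixes sampling rates")
  trial_set(trials,
            label = vapply(recs, function(r) as.integer(r$label), integer(1)),
            subject = vapply(recs, function(r) as.character(r$subject), character(1)),
            group = vapply(recs, function(r) as.character(r$group), character(1)),
            fs = fs,
            trial_id = vapply(recs, function(r) as.character(r$trial_id), character(1)))
}

#' Write a trial set as manifest plus delimited matrix files
#'
#' @param ts a `trial_set`.
#' @param dir output directory (created if needed); the manifest is written
#'   as `manifest.jsonl`, trials as `<trial_id>.tsv`.
#' @return the manifest path, invisibly.
#' @export
write_trialset <- function(ts, dir) {
  stopifnot(inherits(ts, "trial_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(dir, "manifest.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  for (i in seq_along(ts$trials)) {
    f <- paste0(ts$trial_id[i], ".tsv")
    utils::write.table(ts$trials[[i]], file.path(dir, f),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    writeLines(jsonlite::toJSON(list(
      trial_id = ts$trial_id[i], subject = ts$subject[i], group = ts$group[i],
      label = ts$label[i], fs = ts$fs, file = f), auto_unbox = TRUE), con)
  }
  invisible(manifest)
}
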