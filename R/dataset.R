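#' The 32 EEG channel labels of the DEAP preprocessed layout
#'
#' The published DEAP (Geneva) electrode ordering for the first 32 rows of
#' each trial array, 10-20 system names. Named electrodes elsewhere in the
#' package resolve to row indices through this vector.
#'
#' @return Character vector of length 32.
#' @export
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' The 8-electrode frontal/temporal/parietal preset
#'
#' The reduced montage used for channel-reduction experiments:
#' Fp1, Fp2, F7, F8, T7, T8, P7, P8.
#'
#' @return Character vector of length 8.
#' @export
channels_preset8 <- function() {
  c("Fp1", "Fp2", "F7", "F8", "T7", "T8", "P7", "P8")
}

#' Construct a per-subject trial dataset
#'
#' Bundles one subject's trials (multichannel signals at a common sampling
#' rate) with their self-assessed valence and arousal ratings on the 1-9
#' scale.
#'
#' @param subject_id Character scalar.
#' @param signals List of numeric matrices, one per trial, each
#'   channels x samples; all trials must share the channel count.
#' @param valence,arousal Numeric vectors of per-trial ratings in `[1, 9]`.
#' @param channel_labels Character vector of channel names, one per row.
#' @param fs Sampling rate in Hz, > 0. Default 128.
#' @return A list of class `"trial_dataset"`.
#' @export
trial_dataset <- function(subject_id, signals, valence, arousal,
                          channel_labels, fs = 128) {
  if (!length(signals)) abort_invalid_input("`signals` must contain >= 1 trial")
  ncs <- vapply(signals, nrow, integer(1))
  if (length(unique(ncs)) != 1) {
    abort_invalid_input("all trials must share one channel count")
  }
  if (ncs[1] != length(channel_labels)) {
    abort_invalid_input("`channel_labels` length must match channel count")
  }
  if (length(valence) != length(signals) || length(arousal) != length(signals)) {
    abort_invalid_input("one valence and one arousal rating per trial required")
  }
  if (any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9)) {
    abort_invalid_input("ratings must lie in [1, 9]")
  }
  if (!is.numeric(fs) || fs <= 0) abort_invalid_input("`fs` must be > 0")
  signals <- lapply(unname(signals), function(m) {
    rownames(m) <- channel_labels
    m
  })
  structure(
    list(subject_id = as.character(subject_id), signals = signals,
         valence = as.numeric(valence), arousal = as.numeric(arousal),
         channel_labels = channel_labels, fs = fs),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset '%s': %d trials, %d channels, %d samples/trial @ %g Hz>\n",
              x$subject_id, length(x$signals), length(x$channel_labels),
              ncol(x$signals[[1]]), x$fs))
  invisible(x)
}

#' Binarize a 1-9 affective rating at the midpoint
#'
#' Ratings below 5 map to `"low"`, ratings of 5 or more to `"high"` —
#' the standard split of the 9-point self-assessment scale.
#'
#' @param rating Numeric vector of ratings in `[1, 9]`.
#' @return Factor with levels `c("low", "high")`.
#' @examples
#' binarize_rating(c(4.99, 5, 9))
#' @export
binarize_rating <- function(rating) {
  check_numeric_finite(rating, "rating")
  if (any(rating < 1 | rating > 9)) {
    abort_invalid_input("ratings must lie in [1, 9]")
  }
  factor(ifelse(rating < 5, "low", "high"), levels = c("low", "high"))
}

#' Cut a trial into non-overlapping fixed-length segments
#'
#' Windows are anchored at the trial start; leftover tail samples shorter
#' than one window are dropped. A 60-s trial at 128 Hz with 5-s windows
#' yields 12 segments of 640 samples.
#'
#' @param trial Numeric matrix, channels x samples.
#' @param window_sec Window length in seconds.
#' @param fs Sampling rate in Hz.
#' @return A list of channels x `window_sec * fs` matrices (possibly empty,
#'   with a warning, when the trial is shorter than one window).
#' @export
segment_trial <- function(trial, window_sec = 5, fs = 128) {
  if (!is.matrix(trial) || !is.numeric(trial)) {
    abort_invalid_input("`trial` must be a numeric matrix (channels x samples)")
  }
  w <- as.integer(round(window_sec * fs))
  if (w < 1) abort_invalid_input("window must span >= 1 sample")
  n <- ncol(trial)
  k <- n %/% w
  if (k == 0) {
    warning("trial shorter than one window; returning no segments")
    return(list())
  }
  lapply(seq_len(k), function(i) trial[, ((i - 1L) * w + 1L):(i * w), drop = FALSE])
}

#' Build a trial dataset from the DEAP preprocessed per-subject arrays
#'
#' Accepts the documented preprocessed layout: a `data` array of
#' 40 trials x 40 channels x 8064 samples (63 s at 128 Hz) and a `labels`
#' array of 40 trials x 4 ratings. Only the first 32 rows (the EEG
#' electrodes, in the published ordering of [deap_channels()]) are kept.
#' When trials carry 8064 samples the 3-s pretrial baseline (first 384
#' samples) is dropped so trials are 60 s = 7680 samples; arrays already
#' holding 7680-sample trials are accepted as-is. The first two label
#' columns are read as (valence, arousal) by default; `label_order` remaps
#' them if a file follows a different convention.
#'
#' @param data Numeric 3-d array, trials x channels x samples.
#' @param labels Numeric matrix, trials x >= 2 rating columns.
#' @param subject_id Character scalar. Default `"s01"`.
#' @param label_order Character vector naming the first label columns; must
#'   contain `"valence"` and `"arousal"`. Default `c("valence", "arousal")`.
#' @param fs Sampling rate, Hz. Default 128.
#' @return A [trial_dataset()] with 32 channels and 7680-sample trials.
#' @export
deap_trial_dataset <- function(data, labels, subject_id = "s01",
                               label_order = c("valence", "arousal"),
                               fs = 128) {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort_format("`data` must be a 3-d array (trials x channels x samples)")
  }
  d <- dim(data)
  if (d[1] != 40 || d[2] < 32 || !(d[3] %in% c(8064L, 7680L))) {
    abort_format(sprintf(
      "expected 40 trials x >=32 channels x 8064 (or 7680) samples, found %d x %d x %d",
      d[1], d[2], d[3]))
  }
  if (!is.matrix(labels) || nrow(labels) != d[1] || ncol(labels) < 2) {
    abort_format(sprintf(
      "expected a %d x >=2 labels matrix, found %s",
      d[1], paste(dim(labels), collapse = " x ")))
  }
  iv <- match("valence", label_order)
  ia <- match("arousal", label_order)
  if (is.na(iv) || is.na(ia)) {
    abort_invalid_input("`label_order` must name both 'valence' and 'arousal'")
  }
  drop0 <- if (d[3] == 8064L) 384L else 0L
  keep <- (drop0 + 1L):d[3]
  signals <- lapply(seq_len(d[1]), function(tr) {
    m <- data[tr, 1:32, keep, drop = TRUE]
    matrix(m, nrow = 32, dimnames = list(deap_channels(), NULL))
  })
  trial_dataset(subject_id, signals,
                valence = labels[, iv], arousal = labels[, ia],
                channel_labels = deap_channels(), fs = fs)
}

#' Write a trial dataset to the package's delimited container
#'
#' Two tab-separated text files are written under `dir`: `signals.tsv`
#' (columns `trial` then one column per channel, rows = samples in trial
#' order; doubles serialized with 17 significant digits so the round trip is
#' bit-exact) and `ratings.tsv` (`trial`, `valence`, `arousal`).
#'
#' @param dataset A [trial_dataset()].
#' @param dir Directory to write into (created if absent).
#' @return `dir`, invisibly.
#' @seealso [read_trial_dataset()]
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig_path <- file.path(dir, "signals.tsv")
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  con <- file(sig_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("trial", dataset$channel_labels), collapse = "\t"), con)
  for (tr in seq_along(dataset$signals)) {
    m <- dataset$signals[[tr]]  # channels x samples -> rows = samples
    body <- cbind(as.character(tr), matrix(fmt(t(m)), ncol = nrow(m)))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  ratings <- data.frame(trial = seq_along(dataset$signals),
                        valence = fmt(dataset$valence),
                        arousal = fmt(dataset$arousal))
  utils::write.table(ratings, file.path(dir, "ratings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # tiny sidecar with scalars the tables cannot carry
  writeLines(c(paste0("subject_id\t", dataset$subject_id),
               paste0("fs\t", fmt(dataset$fs))),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read a trial dataset from the package's delimited container
#'
#' @param dir Directory written by [write_trial_dataset()].
#' @return A [trial_dataset()].
#' @export
read_trial_dataset <- function(dir) {
  sig_path <- file.path(dir, "signals.tsv")
  if (!file.exists(sig_path)) abort_format(paste("no signals.tsv under", dir))
  sig <- utils::read.table(sig_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "numeric")
  ratings <- utils::read.table(file.path(dir, "ratings.tsv"), header = TRUE,
                               sep = "\t")
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            col.names = c("key", "value"),
                            colClasses = "character")
  channel_labels <- setdiff(names(sig), "trial")
  signals <- lapply(split(sig[channel_labels], sig$trial),
                    function(d) t(as.matrix(d)))
  trial_dataset(meta$value[meta$key == "subject_id"],
                signals[as.character(sort(unique(sig$trial)))],
                valence = ratings$valence[order(ratings$trial)],
                arousal = ratings$arousal[order(ratings$trial)],
                channel_labels = channel_labels,
                fs = as.numeric(meta$value[meta$key == "fs"]))
}
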