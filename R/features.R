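#' Mean absolute first difference of a series
#'
#' `D_t = (1/(N-1)) * sum |x(n+1) - x(n)|` — the intensity of change of an
#' IMF's time series. A signed mean of first differences would telescope to
#' `(last - first)/(N-1)` and carry no fluctuation information, so the
#' magnitude is taken inside the sum.
#'
#' @param series Numeric vector, length >= 2, finite.
#' @return A single nonnegative number.
#' @examples
#' first_difference(c(0, 1, 3, 2)) # (1 + 2 + 1) / 3
#' @export
first_difference <- function(series) {
  check_numeric_finite(series, "series")
  if (length(series) < 2) abort_invalid_input("`series` must have length >= 2")
  mean(abs(diff(series)))
}

#' Mean absolute first difference of an unwrapped phase
#'
#' `D_p = (1/(N-1)) * sum |phi(n+1) - phi(n)|`, in radians per sample. On the
#' unwrapped analytic phase of a band-limited IMF this is the mean magnitude
#' of the instantaneous frequency (times `2*pi/fs`). The phase must already
#' be unwrapped (see [analytic_signal()]).
#'
#' @param phase Numeric vector of unwrapped phase values (radians), length >= 2.
#' @return A single nonnegative number, radians/sample.
#' @export
phase_first_difference <- function(phase) {
  check_numeric_finite(phase, "phase")
  if (length(phase) < 2) abort_invalid_input("`phase` must have length >= 2")
  mean(abs(diff(phase)))
}

#' Normalized energy of an IMF
#'
#' `E_norm = sum(imf^2) / sum(source^2)` — the weight of the oscillation
#' component relative to the raw segment it came from.
#'
#' @param imf Numeric vector.
#' @param source Numeric vector of the same length (the raw segment).
#' @return A single nonnegative number.
#' @export
normalized_energy <- function(imf, source) {
  check_numeric_finite(imf, "imf")
  check_numeric_finite(source, "source")
  if (length(imf) != length(source)) {
    abort_invalid_input("`imf` and `source` must have equal length")
  }
  denom <- sum(source^2)
  if (denom <= 0) abort_degenerate_signal("zero-energy source segment")
  sum(imf^2) / denom
}

#' Natural log of a normalized energy
#'
#' The classifier consumes `log(E_norm)` rather than `E_norm`. Nonpositive
#' inputs (possible only for an identically-zero IMF) are clamped to a floor
#' of 1e-12 before the log, with a warning.
#'
#' @param e_norm A nonnegative number.
#' @return `log(e_norm)` (natural log).
#' @export
log_normalized_energy <- function(e_norm) {
  if (!is.numeric(e_norm) || length(e_norm) != 1 || is.na(e_norm)) {
    abort_invalid_input("`e_norm` must be a single number")
  }
  if (e_norm <= 0) {
    warning("nonpositive normalized energy clamped to 1e-12 before log")
    e_norm <- 1e-12
  }
  log(e_norm)
}

# feature triple for one IMF of one channel; fill value used when the
# decomposition produced fewer levels than requested
.missing_feature_triple <- function() {
  c(Dt = 0, Dp = 0, logEnorm = log(1e-12))
}

.imf_feature_triple <- function(imf, source) {
  if (is.null(imf) || all(imf == 0)) return(.missing_feature_triple())
  az <- analytic_signal(imf)
  c(Dt = first_difference(imf),
    Dp = phase_first_difference(az$phase),
    logEnorm = log_normalized_energy(normalized_energy(imf, source)))
}

#' Extract the per-IMF feature vector from one multichannel segment
#'
#' For every requested `(channel, imf_level)` pair the channel's segment is
#' decomposed by [emd()], and three features are computed on the IMF at that
#' level: `Dt` ([first_difference()] of the IMF samples), `Dp`
#' ([phase_first_difference()] of its unwrapped analytic phase), and
#' `logEnorm` (log of [normalized_energy()] against the channel's raw
#' segment). Levels the decomposition did not reach are filled with the
#' deterministic sentinel triple `(0, 0, log(1e-12))`, flagged by its extreme
#' energy value.
#'
#' @param segment Numeric matrix, channels x samples, with `rownames` giving
#'   channel labels; >= 8 samples.
#' @param channels Character vector of channel labels to use, or `"all"`.
#' @param imf_levels Integer vector of IMF levels (1 = fastest). Default 1.
#' @param config A [sift_config()]; its `max_imfs` is raised to
#'   `max(imf_levels)` if necessary.
#' @return A tibble with columns `channel`, `imf_level`, `feature`
#'   (`"Dt"`, `"Dp"`, `"logEnorm"` in that fixed order), `value`; rows ordered
#'   by channel (in the order given), then level ascending, then feature.
#'   `nrow = n_channels * n_levels * 3`.
#' @examples
#' seg <- rbind(a = sin(2 * pi * 8 * (0:639) / 128),
#'              b = sin(2 * pi * 8 * (0:639) / 128))
#' extract_features(seg, imf_levels = 1)
#' @export
extract_features <- function(segment, channels = "all", imf_levels = 1L,
                             config = sift_config()) {
  if (!is.matrix(segment) || !is.numeric(segment)) {
    abort_invalid_input("`segment` must be a numeric matrix (channels x samples)")
  }
  if (ncol(segment) < 8) abort_invalid_input("segment must have >= 8 samples")
  labels <- rownames(segment)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(segment)))
  if (identical(channels, "all")) channels <- labels
  missing <- setdiff(channels, labels)
  if (length(missing)) {
    abort_missing_channel(paste("channel(s) not present:",
                                paste(missing, collapse = ", ")))
  }
  imf_levels <- sort(unique(as.integer(imf_levels)))
  if (any(imf_levels < 1)) abort_invalid_input("`imf_levels` must be >= 1")
  if (config$max_imfs < max(imf_levels)) {
    config$max_imfs <- max(imf_levels)
  }
  rows <- purrr::map_dfr(channels, function(ch) {
    x <- segment[match(ch, labels), ]
    dec <- emd(x, config)
    purrr::map_dfr(imf_levels, function(lvl) {
      imf <- if (lvl <= length(dec$imfs)) dec$imfs[[lvl]] else NULL
      tri <- .imf_feature_triple(imf, x)
      tibble::tibble(channel = ch, imf_level = lvl,
                     feature = .feature_names, value = unname(tri))
    })
  })
  rows$feature <- factor(rows$feature, levels = .feature_names)
  rows
}

# column name for one wide feature: e.g. "Fp1_imf1_Dt"
.feature_col <- function(channel, imf_level, feature) {
  paste(channel, paste0("imf", imf_level), feature, sep = "_")
}

#' Build the labelled per-segment feature table for a dataset
#'
#' Segments every trial of a [trial_dataset()] (or a list of them) into
#' non-overlapping windows, extracts the per-IMF features of each segment
#' with [extract_features()], and returns one wide row per segment together
#' with trial bookkeeping, raw ratings and binarized labels. This is the
#' table consumed by [rank_channels()] and [loto_evaluate()].
#'
#' @param data A `trial_dataset` or a list of them (multiple subjects).
#' @param channels Channel labels to use, or `"all"`.
#' @param imf_levels Integer vector of IMF levels. Default 1.
#' @param window_sec Segment length in seconds. Default 5.
#' @param config A [sift_config()].
#' @return A tibble with columns `subject_id`, `trial`, `segment`,
#'   `valence_rating`, `arousal_rating`, `valence_label`, `arousal_label`
#'   (factors low/high), then one numeric column per
#'   `(channel, imf_level, feature)` named like `"Fp1_imf1_Dt"`.
#' @export
feature_table <- function(data, channels = "all", imf_levels = 1L,
                          window_sec = 5, config = sift_config()) {
  datasets <- if (inherits(data, "trial_dataset")) list(data) else data
  purrr::map_dfr(datasets, function(ds) {
    stopifnot(inherits(ds, "trial_dataset"))
    ch <- if (identical(channels, "all")) ds$channel_labels else channels
    purrr::imap_dfr(ds$signals, function(sig, tr) {
      segs <- segment_trial(sig, window_sec = window_sec, fs = ds$fs)
      purrr::imap_dfr(segs, function(seg, si) {
        long <- extract_features(seg, channels = ch, imf_levels = imf_levels,
                                 config = config)
        wide <- stats::setNames(
          as.list(long$value),
          .feature_col(long$channel, long$imf_level, as.character(long$feature))
        )
        tibble::tibble(
          subject_id = ds$subject_id,
          trial = as.integer(tr),
          segment = as.integer(si),
          valence_rating = ds$valence[tr],
          arousal_rating = ds$arousal[tr],
          valence_label = binarize_rating(ds$valence[tr]),
          arousal_label = binarize_rating(ds$arousal[tr]),
          !!!wide
        )
      })
    })
  })
}
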