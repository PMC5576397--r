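#' Deterministic multi-tone test signal
#'
#' @param freqs Numeric vector of tone frequencies, Hz; all must be below
#'   the Nyquist frequency `fs/2`.
#' @param amps Amplitudes, recycled to `length(freqs)`. Default 1.
#' @param fs Sampling rate, Hz.
#' @param duration Seconds.
#' @param phases Initial phases in radians, recycled. Default 0.
#' @return Numeric vector of `fs * duration` samples.
#' @examples
#' x <- make_tone(c(32, 4), fs = 128, duration = 5) # the two-tone EMD fixture
#' @export
make_tone <- function(freqs, amps = 1, fs = 128, duration = 5, phases = 0) {
  if (any(freqs >= fs / 2)) {
    abort_invalid_input("tone frequency at or above Nyquist (fs/2)")
  }
  n <- as.integer(round(fs * duration))
  t <- (seq_len(n) - 1) / fs
  amps <- rep_len(amps, length(freqs))
  phases <- rep_len(phases, length(freqs))
  out <- numeric(n)
  for (i in seq_along(freqs)) {
    out <- out + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  }
  out
}

#' Specification of a synthetic DEAP-shaped two-class dataset
#'
#' Defaults emulate the geometry of the preprocessed DEAP recordings: 40
#' one-minute trials of 32 channels at 128 Hz with ratings in `[1, 9]`.
#' Class structure: on `informative_channels`, high-class trials carry extra
#' band-limited 16-45 Hz power, scaled so that the expected 16-45 Hz band
#' power ratio between high and low trials is `1 + separation`; all other
#' channels and all low-class trials are pure 4-45 Hz band-limited 1/f
#' background. `separation = 3` (the documented default) makes the classes
#' cleanly separable by first-IMF features; `separation = 0` removes all
#' class information.
#'
#' @param n_subjects Number of subjects to generate. Default 1.
#' @param n_trials Trials per subject. Default 40.
#' @param trial_sec Trial duration, seconds. Default 60.
#' @param fs Sampling rate, Hz. Default 128.
#' @param n_channels Channels. Default 32.
#' @param class_balance Fraction of high-class trials. Default 0.5.
#' @param separation Nonnegative class-separation control. Default 3.
#' @param informative_channels Integer indices of channels carrying class
#'   information. Default: the [channels_preset8()] positions within
#'   [deap_channels()] when `n_channels == 32`, else the first two channels.
#' @param noise_sd Background standard deviation (arbitrary units). Default 1.
#' @param seed Integer RNG seed; the dataset is a pure function of the spec.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 1L, n_trials = 40L, trial_sec = 60,
                           fs = 128, n_channels = 32L, class_balance = 0.5,
                           separation = 3, informative_channels = NULL,
                           noise_sd = 1, seed = 1L) {
  if (separation < 0) abort_invalid_input("`separation` must be >= 0")
  if (abs(fs * trial_sec - round(fs * trial_sec)) > 1e-9) {
    abort_invalid_input("`fs * trial_sec` must be integral")
  }
  if (is.null(informative_channels)) {
    informative_channels <- if (n_channels == 32) {
      match(channels_preset8(), deap_channels())
    } else {
      seq_len(min(2L, n_channels))
    }
  }
  if (any(informative_channels < 1 | informative_channels > n_channels)) {
    abort_invalid_input("`informative_channels` out of channel range")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         trial_sec = trial_sec, fs = fs, n_channels = as.integer(n_channels),
         class_balance = class_balance, separation = separation,
         informative_channels = as.integer(informative_channels),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# FFT synthesis of band-limited noise with amplitude spectrum `shape(f)`
# on [f_lo, f_hi], random phases, scaled to standard deviation `target_sd`
.band_noise <- function(n, fs, f_lo, f_hi, target_sd, shape = function(f) 1 / f) {
  freqs <- (0:(n %/% 2)) * fs / n
  amp <- ifelse(freqs >= f_lo & freqs <= f_hi, shape(pmax(freqs, 1e-9)), 0)
  ph <- stats::runif(length(amp), 0, 2 * pi)
  half <- amp * exp(1i * ph)
  half[1] <- 0
  spec <- c(half, Conj(rev(half[2:(n - length(half) + 1)])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * target_sd
}

#' Generate a seeded synthetic DEAP-shaped two-class dataset
#'
#' Per trial and channel, a 4-45 Hz band-limited 1/f background is
#' synthesized in the frequency domain (random phases, deterministic from
#' the spec's seed). High-class trials additionally receive, on the
#' informative channels only, an independent flat-spectrum 16-45 Hz
#' component whose variance equals `separation` times the background's
#' 16-45 Hz band power, so the programmed high/low band-power ratio is
#' `1 + separation`. Ratings are drawn class-first — high trials uniform on
#' `[5, 9]`, low trials uniform on `[1, 5)` — for both valence and arousal,
#' so the binarized labels recover the generating class exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of [trial_dataset()] objects, one per subject, each with
#'   attribute `"class"` (factor low/high per trial).
#' @export
make_two_class_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- as.integer(round(spec$fs * spec$trial_sec))
  labels <- if (spec$n_channels == 32) deap_channels() else
    sprintf("ch%02d", seq_len(spec$n_channels))
  # fraction of background variance inside 16-45 Hz, from the 1/f shape
  freqs <- (0:(n %/% 2)) * spec$fs / n
  amp2 <- ifelse(freqs >= 4 & freqs <= 45, (1 / pmax(freqs, 1e-9))^2, 0)
  band_frac <- sum(amp2[freqs >= 16 & freqs <= 45]) / sum(amp2)
  extra_sd <- sqrt(spec$separation * band_frac) * spec$noise_sd
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(sj) {
      n_high <- round(spec$n_trials * spec$class_balance)
      cls <- factor(rep("low", spec$n_trials), levels = c("low", "high"))
      cls[sample.int(spec$n_trials, n_high)] <- "high"
      valence <- ifelse(cls == "high", stats::runif(spec$n_trials, 5, 9),
                        stats::runif(spec$n_trials, 1, 5 - 1e-9))
      arousal <- ifelse(cls == "high", stats::runif(spec$n_trials, 5, 9),
                        stats::runif(spec$n_trials, 1, 5 - 1e-9))
      signals <- lapply(seq_len(spec$n_trials), function(tr) {
        m <- matrix(0, spec$n_channels, n, dimnames = list(labels, NULL))
        for (c1 in seq_len(spec$n_channels)) {
          x <- .band_noise(n, spec$fs, 4, 45, spec$noise_sd)
          if (cls[tr] == "high" && c1 %in% spec$informative_channels &&
              extra_sd > 0) {
            x <- x + .band_noise(n, spec$fs, 16, 45, extra_sd,
                                 shape = function(f) rep(1, length(f)))
          }
          m[c1, ] <- x
        }
        m
      })
      ds <- trial_dataset(sprintf("sim%02d", sj), signals, valence, arousal,
                          labels, fs = spec$fs)
      attr(ds, "class_labels") <- cls
      ds
    })
  })
}
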