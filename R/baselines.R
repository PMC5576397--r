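#' Configuration for the classical comparison features
#'
#' @param sampen_m Sample-entropy embedding length. Default 2.
#' @param sampen_r Tolerance as a fraction of the series' standard
#'   deviation. Default 0.2.
#' @param sampen_window Window length in samples over which sample entropy is
#'   computed (a 640-sample segment is split into non-overlapping windows of
#'   this length and the finite window values are averaged). Default 128.
#' @param fd_scales Box sizes (fractions of the unit square) for box
#'   counting. Default `2^-(1:6)`, dyadic over just above one decade.
#' @param wavelet Wavelet name; only `"db4"` is implemented.
#' @param bands Named list of nominal band edges in Hz. At 128 Hz sampling,
#'   detail level 1 spans 32-64 Hz (Gamma) and level 2 spans 16-32 Hz
#'   (Beta); bands are addressed by decomposition level, so input that was
#'   low-pass filtered below the nominal upper edge simply yields a
#'   band-limited detail.
#' @return A list of class `"baseline_config"`.
#' @export
baseline_config <- function(sampen_m = 2L, sampen_r = 0.2,
                            sampen_window = 128L,
                            fd_scales = 2^-(1:6),
                            wavelet = "db4",
                            bands = list(Beta = c(16, 32), Gamma = c(32, 64))) {
  if (sampen_m < 1) abort_invalid_input("`sampen_m` must be >= 1")
  if (sampen_r <= 0 || sampen_r >= 1) abort_invalid_input("`sampen_r` must be in (0, 1)")
  if (length(fd_scales) < 2) abort_invalid_input("need >= 2 box scales")
  wavelet <- match.arg(wavelet, "db4")
  structure(list(sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
                 sampen_window = as.integer(sampen_window),
                 fd_scales = fd_scales, wavelet = wavelet, bands = bands),
            class = "baseline_config")
}

#' Box-counting fractal dimension of a series' graph
#'
#' The graph of the (linearly interpolated) series is normalized to the unit
#' square; for each box size `s` the plane is tiled with `s x s` boxes and
#' the boxes intersected by the curve are counted column by column (each
#' time-column contributes the vertical span of the curve inside it). The
#' dimension is the least-squares slope of `log N(s)` against `log(1/s)`.
#' A constant series is a flat line and returns 1 directly.
#'
#' @param series Numeric vector, length >= 64.
#' @param scales Box sizes in (0, 1), at least 3, spanning at least a
#'   decade. Default `2^-(1:6)`.
#' @return Estimated dimension, typically in `[1, 2]` for a curve.
#' @export
fractal_dimension_boxcount <- function(series, scales = 2^-(1:6)) {
  check_numeric_finite(series, "series")
  if (length(series) < 64) abort_invalid_input("`series` must have length >= 64")
  if (length(scales) < 3) abort_invalid_input("need >= 3 box scales")
  if (max(scales) / min(scales) < 10) {
    abort_invalid_input("box scales must span at least one decade")
  }
  n <- length(series)
  rng <- range(series)
  if (diff(rng) == 0) return(1.0)
  tt <- (seq_len(n) - 1) / (n - 1)
  y <- (series - rng[1]) / diff(rng)
  counts <- vapply(scales, function(s) {
    col <- pmin(floor(tt / s), ceiling(1 / s) - 1)
    # vertical span of the interpolated curve per time-column: include the
    # boundary samples of adjacent columns so the curve is connected
    lo <- tapply(y, col, min)
    hi <- tapply(y, col, max)
    idx <- as.integer(names(lo))
    # extend spans with interpolated values at column boundaries
    brk <- which(diff(col) != 0)
    if (length(brk)) {
      tb <- (idx[-1]) * s  # boundary times between consecutive occupied cols
      yb <- stats::approx(tt, y, xout = pmin(tb, 1))$y
      lo[-1] <- pmin(lo[-1], yb); hi[-1] <- pmax(hi[-1], yb)
      lo[-length(lo)] <- pmin(lo[-length(lo)], yb)
      hi[-length(hi)] <- pmax(hi[-length(hi)], yb)
    }
    sum(floor(hi / s) - floor(lo / s) + 1)
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(1 / scales))
  unname(stats::coef(fit)[2])
}

#' Sample entropy
#'
#' `SampEn(m, r, N) = -log(A / B)` where `B` counts pairs of `m`-length
#' templates within Chebyshev distance `r = r_frac * sd(series)` and `A`
#' counts pairs of `(m+1)`-length templates, both over templates
#' `1 .. N - m`, self-matches excluded (Richman-Moorman convention). When no
#' `(m+1)`-template pair matches, `Inf` is returned with attribute
#' `flagged = TRUE`.
#'
#' @param series Numeric vector, length >= `2 * (m + 1)`.
#' @param m Embedding length. Default 2.
#' @param r_frac Tolerance fraction of `sd(series)`. Default 0.2.
#' @return A nonnegative number (possibly `Inf`, flagged).
#' @examples
#' sample_entropy(rep(c(1, 2), 64)) # 0: perfectly predictable
#' @export
sample_entropy <- function(series, m = 2L, r_frac = 0.2) {
  check_numeric_finite(series, "series")
  m <- as.integer(m)
  n <- length(series)
  if (n < 2 * (m + 1)) abort_invalid_input("series too short for the embedding")
  s <- stats::sd(series)
  if (s == 0) abort_degenerate_signal("constant series: tolerance r would be 0")
  r <- r_frac * s
  count_matches <- function(mm) {
    nt <- n - m  # same template count for both lengths, so A/B is a probability
    d <- matrix(0, nt, nt)
    for (k in 0:(mm - 1)) {
      xk <- series[(1:nt) + k]
      d <- pmax(d, abs(outer(xk, xk, "-")))
    }
    (sum(d <= r) - nt) / 2  # off-diagonal unordered pairs
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (B == 0 || A == 0) {
    return(structure(Inf, flagged = TRUE))
  }
  -log(A / B)
}

# mean sample entropy over non-overlapping windows; Inf windows are dropped
# (all-Inf gives Inf)
sample_entropy_windowed <- function(series, m = 2L, r_frac = 0.2, window = 128L) {
  k <- length(series) %/% window
  if (k == 0) return(sample_entropy(series, m, r_frac))
  vals <- vapply(seq_len(k), function(i) {
    as.numeric(sample_entropy(series[((i - 1) * window + 1):(i * window)],
                              m, r_frac))
  }, numeric(1))
  fin <- vals[is.finite(vals)]
  if (!length(fin)) return(structure(Inf, flagged = TRUE))
  mean(fin)
}

# db4 analysis filters (orthonormal; scaling filter sums to sqrt(2))
.db4_h <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

# one analysis level with periodic extension: returns approximation and
# detail coefficient vectors of length n/2
.dwt_step <- function(x) {
  h <- .db4_h
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror wavelet filter
  n <- length(x)
  xp <- c(x, x[seq_len(L)])  # periodic pad
  a <- vapply(seq(1, n, by = 2), function(i) sum(h * xp[i:(i + L - 1)]), numeric(1))
  d <- vapply(seq(1, n, by = 2), function(i) sum(g * xp[i:(i + L - 1)]), numeric(1))
  list(a = a, d = d)
}

#' Differential entropy of a db4 wavelet band
#'
#' Decomposes the series with the db4 discrete wavelet transform and returns
#' the differential entropy of the requested band's detail coefficients
#' under the Gaussian closed form `0.5 * log(2 * pi * e * sigma^2)`. At
#' `fs = 128` Hz, detail level 1 covers 32-64 Hz (Gamma) and detail level 2
#' covers 16-32 Hz (Beta).
#'
#' @param series Numeric vector; length must be divisible by `2^level` for
#'   the requested band.
#' @param fs Sampling rate, Hz; band-to-level mapping requires 128.
#' @param band `"Beta"` (16-32 Hz, level 2) or `"Gamma"` (32-64 Hz, level 1).
#' @return Differential entropy in nats.
#' @export
dwt_differential_entropy <- function(series, fs = 128, band = c("Beta", "Gamma")) {
  band <- match.arg(band)
  check_numeric_finite(series, "series")
  if (fs != 128) {
    abort_invalid_input("band-to-level mapping is defined for fs = 128 Hz")
  }
  level <- switch(band, Gamma = 1L, Beta = 2L)
  if (length(series) %% (2^level) != 0 || length(series) < 2^level * 8) {
    abort_invalid_input("series length must be a (sufficiently large) multiple of 2^level")
  }
  x <- series
  d <- NULL
  for (l in seq_len(level)) {
    st <- .dwt_step(x)
    x <- st$a
    d <- st$d
  }
  v <- stats::var(d)
  if (v <= 0) abort_degenerate_signal("zero-variance band coefficients")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Per-segment baseline feature table
#'
#' Same layout as [feature_table()] but with the classical comparison
#' features instead of the per-IMF triple: one column per channel holding
#' box-counting fractal dimension (`method = "fd"`), windowed sample entropy
#' (`"sampen"`), or db4 differential entropy of the Beta or Gamma band
#' (`"dwt_de_beta"`, `"dwt_de_gamma"`).
#'
#' @inheritParams feature_table
#' @param method One of `"fd"`, `"sampen"`, `"dwt_de_beta"`, `"dwt_de_gamma"`.
#' @param config A [baseline_config()].
#' @return A tibble with the same bookkeeping columns as [feature_table()]
#'   and one feature column per channel.
#' @export
baseline_feature_table <- function(data, method = c("fd", "sampen",
                                                    "dwt_de_beta", "dwt_de_gamma"),
                                   channels = "all", window_sec = 5,
                                   config = baseline_config()) {
  method <- match.arg(method)
  datasets <- if (inherits(data, "trial_dataset")) list(data) else data
  seg_feature <- function(x, fs) {
    switch(method,
      fd = fractal_dimension_boxcount(x, config$fd_scales),
      sampen = {
        v <- sample_entropy_windowed(x, config$sampen_m, config$sampen_r,
                                     config$sampen_window)
        if (!is.finite(v)) NA_real_ else as.numeric(v)
      },
      dwt_de_beta = dwt_differential_entropy(x, fs, "Beta"),
      dwt_de_gamma = dwt_differential_entropy(x, fs, "Gamma")
    )
  }
  purrr::map_dfr(datasets, function(ds) {
    ch <- if (identical(channels, "all")) ds$channel_labels else channels
    missing <- setdiff(ch, ds$channel_labels)
    if (length(missing)) {
      abort_missing_channel(paste("channel(s) not present:",
                                  paste(missing, collapse = ", ")))
    }
    purrr::imap_dfr(ds$signals, function(sig, tr) {
      segs <- segment_trial(sig, window_sec = window_sec, fs = ds$fs)
      purrr::imap_dfr(segs, function(seg, si) {
        vals <- vapply(ch, function(c1) {
          seg_feature(seg[match(c1, ds$channel_labels), ], ds$fs)
        }, numeric(1))
        tibble::tibble(
          subject_id = ds$subject_id, trial = as.integer(tr),
          segment = as.integer(si),
          valence_rating = ds$valence[tr], arousal_rating = ds$arousal[tr],
          valence_label = binarize_rating(ds$valence[tr]),
          arousal_label = binarize_rating(ds$arousal[tr]),
          !!!stats::setNames(as.list(vals), paste0(ch, "_", method))
        )
      })
    })
  })
}
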