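#' Sifting configuration for empirical mode decomposition
#'
#' Controls the inner sifting loop and the outer decomposition loop of
#' [emd()]. The stop rule is threefold: sifting of one candidate IMF ends as
#' soon as (a) the Cauchy-type ratio `SD = sum((h_old - h_new)^2) / sum(h_old^2)`
#' drops to `sd_threshold` or below, (b) the candidate already satisfies the
#' two intrinsic-mode-function admissibility conditions (see [is_imf()]) at
#' tolerance `zero_mean_tol`, or (c) `max_sift_iterations` is reached. The
#' strict two-condition test alone can cycle indefinitely in floating point,
#' hence the classical `SD` guard (0.2 is Huang's conventional value).
#'
#' @param sd_threshold Dimensionless sifting stop ratio, > 0. Default 0.2.
#' @param max_sift_iterations Maximum sifting passes per IMF, >= 1. Default 100.
#' @param max_imfs Maximum number of IMFs to extract, >= 1. Default 5 (feature
#'   extraction downstream only ever uses the first five levels).
#' @param boundary_mode Spline end treatment; only `"mirror_extrema"` is
#'   implemented: the two extrema nearest each end are reflected across the
#'   first/last sample before envelope fitting, the standard remedy for
#'   spline end swings.
#' @param zero_mean_tol Relative tolerance for the envelope-mean-zero
#'   admissibility condition. Default 0.05.
#'
#' @return A list of class `"sift_config"`.
#' @examples
#' sift_config(max_imfs = 1) # fastest: only the highest-frequency mode
#' @export
sift_config <- function(sd_threshold = 0.2,
                        max_sift_iterations = 100L,
                        max_imfs = 5L,
                        boundary_mode = "mirror_extrema",
                        zero_mean_tol = 0.05) {
  if (!is.numeric(sd_threshold) || sd_threshold <= 0) {
    abort_invalid_input("`sd_threshold` must be > 0")
  }
  if (max_sift_iterations < 1) abort_invalid_input("`max_sift_iterations` must be >= 1")
  if (max_imfs < 1) abort_invalid_input("`max_imfs` must be >= 1")
  boundary_mode <- match.arg(boundary_mode, "mirror_extrema")
  structure(
    list(
      sd_threshold = sd_threshold,
      max_sift_iterations = as.integer(max_sift_iterations),
      max_imfs = as.integer(max_imfs),
      boundary_mode = boundary_mode,
      zero_mean_tol = zero_mean_tol
    ),
    class = "sift_config"
  )
}

#' Locate local extrema of a sampled signal
#'
#' Returns the strictly interior local maxima and minima. A plateau (a run of
#' tied samples that is locally extremal against both neighbouring runs)
#' contributes exactly one extremum, placed at the floor of the run's midpoint
#' index — a deterministic convention shared by common EMD implementations.
#'
#' @param samples Numeric vector, length >= 3, all finite.
#' @return A list with integer vectors `max_idx`, `min_idx` (1-based, strictly
#'   increasing) and numeric vectors `max_val`, `min_val`.
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0)) # maximum at 2, minimum at 4
#' @export
find_extrema <- function(samples) {
  check_numeric_finite(samples, "samples")
  if (length(samples) < 3) abort_invalid_input("`samples` must have length >= 3")
  r <- rle(samples)
  v <- r$values
  n_runs <- length(v)
  if (n_runs < 3) {
    return(list(max_idx = integer(), max_val = numeric(),
                min_idx = integer(), min_val = numeric()))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(n_runs - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  mid <- function(j) as.integer((starts[j] + ends[j]) %/% 2L)
  mx <- mid(i[is_max])
  mn <- mid(i[is_min])
  list(max_idx = mx, max_val = samples[mx],
       min_idx = mn, min_val = samples[mn])
}

# count sign changes; exact zeros are skipped so ties are deterministic
zero_crossings <- function(samples) {
  s <- sign(samples)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# mirror the k extrema nearest each end across the boundary samples, then
# return the knot set for spline fitting (deduplicated, sorted)
mirror_knots <- function(idx, val, n, k = 2L) {
  m <- length(idx)
  kl <- min(k, m)
  left_i <- 2L - idx[seq_len(kl)]
  left_v <- val[seq_len(kl)]
  right_sel <- m - seq_len(kl) + 1L
  right_i <- 2L * n - idx[right_sel]
  right_v <- val[right_sel]
  xs <- c(left_i, idx, right_i)
  ys <- c(left_v, val, right_v)
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  keep <- !duplicated(xs)
  list(x = xs[keep], y = ys[keep])
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' Fits natural cubic splines through the (boundary-extended) maxima and
#' minima and returns their pointwise mean `m(t) = (e_max(t) + e_min(t)) / 2`.
#' Note the envelopes are interpolants, not bounds: near the ends `e_max`
#' can dip below `e_min` and no ordering is guaranteed pointwise.
#'
#' @inheritParams find_extrema
#' @param boundary_mode End treatment, see [sift_config()].
#' @return Numeric vector of the same length as `samples`.
#' @examples
#' t <- (0:639) / 128
#' m <- envelope_mean(sin(2 * pi * 8 * t)) # ~0 in the interior
#' @export
envelope_mean <- function(samples, boundary_mode = "mirror_extrema") {
  check_numeric_finite(samples, "samples")
  boundary_mode <- match.arg(boundary_mode, "mirror_extrema")
  n <- length(samples)
  ex <- find_extrema(samples)
  if (length(ex$max_idx) < 2 || length(ex$min_idx) < 2) {
    abort_not_enough_extrema()
  }
  up <- mirror_knots(ex$max_idx, ex$max_val, n)
  lo <- mirror_knots(ex$min_idx, ex$min_val, n)
  fu <- stats::splinefun(up$x, up$y, method = "natural")
  fl <- stats::splinefun(lo$x, lo$y, method = "natural")
  (fu(seq_len(n)) + fl(seq_len(n))) / 2
}

#' Test the two intrinsic-mode-function admissibility conditions
#'
#' An IMF must (1) have extrema and zero-crossing counts equal or differing by
#' at most one, and (2) have an upper/lower envelope mean that is zero
#' everywhere — tested here as `max |m(t)| <= zero_mean_tol * max |samples|`.
#' When envelopes cannot be built (fewer than two maxima or minima) the
#' signal cannot oscillate and the test returns `FALSE`.
#'
#' @inheritParams find_extrema
#' @param zero_mean_tol Relative envelope-mean tolerance. Default 0.05.
#' @return `TRUE` or `FALSE`.
#' @export
is_imf <- function(samples, zero_mean_tol = 0.05) {
  check_numeric_finite(samples, "samples")
  if (length(samples) < 3) abort_invalid_input("`samples` must have length >= 3")
  ex <- find_extrema(samples)
  n_ext <- length(ex$max_idx) + length(ex$min_idx)
  if (abs(n_ext - zero_crossings(samples)) > 1) return(FALSE)
  m <- tryCatch(envelope_mean(samples),
                emdeeg_error_not_enough_extrema = function(e) NULL)
  if (is.null(m)) return(FALSE)
  max(abs(m)) <= zero_mean_tol * max(abs(samples))
}

#' One sifting pass
#'
#' Subtracts the envelope mean from the working signal:
#' `h_new(t) = h_old(t) - m(t)`.
#'
#' @param h_old Numeric vector, the current sifting candidate.
#' @inheritParams envelope_mean
#' @return Numeric vector of the same length.
#' @export
sift_once <- function(h_old, boundary_mode = "mirror_extrema") {
  h_old - envelope_mean(h_old, boundary_mode)
}

#' Empirical mode decomposition of a single-channel epoch
#'
#' Decomposes `samples` into intrinsic mode functions by iterative sifting:
#' repeatedly subtract the cubic-spline envelope mean until the candidate
#' satisfies the admissibility conditions (or the `SD` ratio / iteration cap
#' stops it, see [sift_config()]), peel the IMF off, and continue on the
#' remainder. Extraction ends when the remainder has fewer than three extrema
#' (it can no longer oscillate) or `max_imfs` modes have been taken. The
#' identity `sum(imfs) + residual == samples` holds to floating-point
#' rounding by construction.
#'
#' @param samples Numeric vector, length >= 8, all finite.
#' @param config A [sift_config()].
#' @return An object of class `"imf_decomposition"`: a list with `imfs` (list
#'   of numeric vectors, fastest-oscillating first), `residual`,
#'   `source_length`, and the `config` used.
#' @examples
#' t <- (0:639) / 128
#' dec <- emd(sin(2 * pi * 32 * t) + sin(2 * pi * 4 * t))
#' length(dec$imfs)
#' @export
emd <- function(samples, config = sift_config()) {
  check_numeric_finite(samples, "samples")
  if (length(samples) < 8) {
    abort_invalid_input("epoch too short: need at least 8 samples")
  }
  stopifnot(inherits(config, "sift_config"))
  r <- samples
  imfs <- list()
  for (k in seq_len(config$max_imfs)) {
    h <- r
    ok <- TRUE
    for (it in seq_len(config$max_sift_iterations)) {
      m <- tryCatch(envelope_mean(h, config$boundary_mode),
                    emdeeg_error_not_enough_extrema = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      # admissibility check reuses the envelope mean already in hand
      ex <- find_extrema(h)
      n_ext <- length(ex$max_idx) + length(ex$min_idx)
      two_cond <- abs(n_ext - zero_crossings(h)) <= 1 &&
        max(abs(m)) <= config$zero_mean_tol * max(abs(h))
      if (two_cond) break
      sd_ratio <- sum(m^2) / sum(h^2)
      h <- h - m
      if (sd_ratio <= config$sd_threshold) break
    }
    if (!ok && k == 1L) break  # input itself has too few extrema: all residual
    if (!ok) break
    imfs[[k]] <- h
    r <- r - h
    ex <- find_extrema(r)
    if (length(ex$max_idx) + length(ex$min_idx) < 3) break
  }
  structure(
    list(imfs = imfs, residual = r, source_length = length(samples),
         config = config),
    class = "imf_decomposition"
  )
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition: %d IMF(s) + residual, %d samples>\n",
              length(x$imfs), x$source_length))
  zc <- vapply(x$imfs, zero_crossings, integer(1))
  if (length(zc)) cat("  zero crossings per IMF:", paste(zc, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an IMF decomposition into a long tibble
#'
#' @param x An `"imf_decomposition"`.
#' @param ... Unused.
#' @return A tibble with columns `component` (`"imf1"`, ..., `"residual"`),
#'   `sample` (1-based index) and `value`.
#' @method tidy imf_decomposition
#' @export
tidy.imf_decomposition <- function(x, ...) {
  comps <- c(stats::setNames(x$imfs, paste0("imf", seq_along(x$imfs))),
             list(residual = x$residual))
  purrr::imap_dfr(comps, function(v, nm) {
    tibble::tibble(component = nm, sample = seq_along(v), value = v)
  })
}

#' Plot an IMF decomposition as stacked panels
#'
#' @param object An `"imf_decomposition"`.
#' @param ... Unused.
#' @return A ggplot object, one facet per component.
#' @method autoplot imf_decomposition
#' @export
autoplot.imf_decomposition <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = unique(d$component))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL)
}
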