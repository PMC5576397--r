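# shared fixtures: analytic test signals and small synthetic datasets,
# all built in code at test time

fs_default <- 128
t5 <- (0:639) / fs_default          # 5 s at 128 Hz
interior <- 65:576                  # central 80% of a 640-sample epoch

tone <- function(f, fs = fs_default, n = 640, phase = 0, cosine = FALSE) {
  t <- (seq_len(n) - 1) / fs
  if (cosine) cos(2 * pi * f * t + phase) else sin(2 * pi * f * t + phase)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# small DEAP-shaped dataset used by the pipeline tests; sizes chosen for
# test-suite runtime, class structure identical to the full geometry
small_spec <- function(separation = 3, seed = 1, n_trials = 16,
                       trial_sec = 20, n_channels = 4,
                       informative = c(2, 3)) {
  synthetic_spec(
    n_trials = n_trials, trial_sec = trial_sec, n_channels = n_channels,
    informative_channels = informative, separation = separation, seed = seed
  )
}

# IMF-level evaluation of one synthetic subject on its informative channels
eval_synthetic <- function(spec, dimension = "valence", imf_levels = 1L) {
  ds <- make_two_class_dataset(spec)[[1]]
  ch <- ds$channel_labels[spec$informative_channels]
  ft <- feature_table(ds, channels = ch, imf_levels = imf_levels)
  loto_evaluate(ft, dimension)
}

# independent O(N^2) sample-entropy oracle: naive double loop,
# Richman-Moorman convention, Chebyshev distance
sampen_oracle <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  count <- function(mm) {
    nt <- n - m
    total <- 0L
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) total <- total + 1L
      }
    }
    total
  }
  B <- count(m)
  A <- count(m + 1L)
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}
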