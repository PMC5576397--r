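test_that("find_extrema locates peaks, troughs and plateau midpoints", {
  ex <- find_extrema(c(0, 1, 0, -1, 0))
  expect_equal(ex$max_idx, 2L)
  expect_equal(ex$min_idx, 4L)
  expect_equal(ex$max_val, 1)

  # monotone ramp: no interior extrema
  ex <- find_extrema(c(0, 1, 2, 3))
  expect_length(ex$max_idx, 0)
  expect_length(ex$min_idx, 0)

  # a plateau contributes exactly one extremum at its floor-midpoint
  ex <- find_extrema(c(0, 1, 1, 0))
  expect_equal(ex$max_idx, 2L)
  ex <- find_extrema(c(0, 1, 1, 1, 0))
  expect_equal(ex$max_idx, 3L)
  ex <- find_extrema(c(1, 0, 0, 1))
  expect_equal(ex$min_idx, 2L)

  # indices strictly increasing on an oscillation
  ex <- find_extrema(tone(8))
  expect_true(all(diff(ex$max_idx) > 0))
  expect_true(all(diff(ex$min_idx) > 0))

  expect_error(find_extrema(c(0, NA, 1)), class = "emdeeg_error_invalid_input")
  expect_error(find_extrema(c(0, 1)), class = "emdeeg_error_invalid_input")
})

test_that("envelope mean of a sinusoid is flat at its offset", {
  x <- tone(8)  # >= 4 full cycles
  m <- envelope_mean(x)
  expect_length(m, length(x))
  expect_lt(max(abs(m[interior])), 0.05)

  m2 <- envelope_mean(x + 3)
  expect_lt(max(abs(m2[interior] - 3)), 0.05)

  expect_error(envelope_mean(seq(0, 1, length.out = 100)),
               class = "emdeeg_error_not_enough_extrema")
})

test_that("IMF admissibility test accepts tones and rejects offsets and ramps", {
  expect_true(is_imf(tone(8)))
  expect_false(is_imf(tone(8) + 0.5))
  expect_false(is_imf(seq(0, 1, length.out = 64)))
})

test_that("one sifting pass removes an additive offset and is near-idempotent on a tone", {
  x <- tone(8)
  h1 <- sift_once(x + 2)
  expect_lt(max(abs(h1[interior] - x[interior])), 0.05)

  # an admissible IMF is barely changed
  d1 <- max(abs(sift_once(x) - x))
  expect_lt(d1, 0.05 * max(abs(x)))

  # sifting twice moves a pure tone less than sifting an offset tone once
  d2 <- max(abs(sift_once(sift_once(x)) - x))
  doff <- max(abs(sift_once(x + 2) - (x + 2)))
  expect_lt(d2, doff)
})

test_that("emd recovers a mono-component and separates well-spaced tones", {
  x <- tone(8)
  dec <- emd(x)
  expect_s3_class(dec, "imf_decomposition")
  expect_gt(cor(dec$imfs[[1]], x), 0.99)
  expect_lt(max(abs(dec$residual)), 0.05 * max(abs(x)))

  hi <- tone(32); lo <- tone(4)
  dec2 <- emd(hi + lo)
  expect_gte(length(dec2$imfs), 2)
  expect_gt(cor(dec2$imfs[[1]][interior], hi[interior]), 0.95)
  expect_gt(cor(dec2$imfs[[2]][interior], lo[interior]), 0.95)

  expect_error(emd(rnorm(5)), class = "emdeeg_error_invalid_input")
})

test_that("reconstruction identity holds on random inputs", {
  for (s in 1:25) {
    set.seed(s)
    x <- rnorm(256)
    dec <- emd(x)
    recon <- Reduce(`+`, dec$imfs, accumulate = FALSE) + dec$residual
    expect_lt(rel_l2(recon, x), 1e-9)
  }
})

test_that("IMFs come out fastest-oscillating first on broadband noise", {
  rates <- sapply(1:20, function(s) {
    set.seed(100 + s)
    dec <- emd(rnorm(640))
    zc <- vapply(dec$imfs, emdeeg:::zero_crossings, integer(1))
    c(length(zc), all(diff(zc) <= 0))
  })
  # ordering must hold on average: mean zero-crossing rate non-increasing
  mean_ok <- mean(rates[2, ])
  expect_gte(mean_ok, 0.95)
})

test_that("decomposition is amplitude-equivariant and shifts constants to the residual", {
  set.seed(11)
  x <- rnorm(640)
  base <- emd(x)
  for (c1 in c(2, 10)) {
    sc <- emd(c1 * x)
    expect_equal(length(sc$imfs), length(base$imfs))
    for (k in seq_along(base$imfs)) {
      expect_lt(rel_l2(sc$imfs[[k]], c1 * base$imfs[[k]]), 1e-6)
    }
  }
  # additive offset: first IMF unchanged in the interior, constant in the tail
  off <- emd(x + 5)
  tol <- 0.05 * max(abs(x))
  expect_lt(max(abs(off$imfs[[1]][interior] - base$imfs[[1]][interior])), tol)
  recon_tail <- off$residual + Reduce(`+`, off$imfs[-1], accumulate = FALSE)
  expect_gt(mean(recon_tail[interior]), 4)
})

test_that("sift_config validates its inputs and emd respects max_imfs", {
  expect_error(sift_config(sd_threshold = 0), class = "emdeeg_error_invalid_input")
  expect_error(sift_config(max_imfs = 0), class = "emdeeg_error_invalid_input")
  set.seed(3)
  dec <- emd(rnorm(640), sift_config(max_imfs = 2))
  expect_lte(length(dec$imfs), 2)
})

test_that("tidy() gives one row per component sample", {
  dec <- emd(tone(32) + tone(4))
  td <- tidy(dec)
  expect_equal(nrow(td), (length(dec$imfs) + 1) * dec$source_length)
  expect_setequal(unique(td$component),
                  c(paste0("imf", seq_along(dec$imfs)), "residual"))
})
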