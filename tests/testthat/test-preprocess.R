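test_that("band-pass keeps in-band tones, rejects out-of-band tones, and is linear", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  in_band <- sin(2 * pi * 10 * t)
  out_band <- sin(2 * pi * 60 * t)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  amp <- function(x) max(abs(x[mid]))
  yi <- bandpass(in_band, fs, 0.5, 45)
  expect_lt(abs(amp(yi) - 1), 0.05)
  yo <- bandpass(out_band, fs, 0.5, 45)
  expect_lt(amp(yo), 0.1)               # >= 90% attenuation at 60 Hz
  expect_equal(bandpass(numeric(length(t)) , fs, 0.5, 45), numeric(length(t)))
  # linearity; tolerance reflects the roundoff conditioning of an 8-pole
  # Butterworth realized in transfer-function form near its low band edge
  a <- rnorm(length(t)); b <- rnorm(length(t))
  lhs <- bandpass(2 * a + 3 * b, fs, 0.5, 45)
  rhs <- 2 * bandpass(a, fs, 0.5, 45) + 3 * bandpass(b, fs, 0.5, 45)
  expect_lt(max(abs(lhs - rhs)), 1e-4)
  expect_error(bandpass(a, fs, 0.5, 300), class = "hbnet_argument_error")
})

test_that("resampling has the right length and inverts on slow signals", {
  x <- matrix(rnorm(3000), 3, 1000)
  expect_identical(resample_signal(x, 200, 200), x)
  expect_equal(ncol(resample_signal(x, 1000, 200)), 200)
  # 11 -> 200 -> 11 Hz round trip on a 0.1 Hz sinusoid
  t <- seq(0, 60, by = 1 / 11)
  s <- sin(2 * pi * 0.1 * t)
  up <- resample_signal(s, 11, 200)
  back <- resample_signal(up, 200, 11)
  m <- seq(round(length(s) * 0.1), round(length(s) * 0.9))  # ignore edge taper
  expect_lt(max(abs(back[m] - s[m])), 0.01)
  expect_error(resample_signal(matrix(0, 1, 0), 10, 20), class = "hbnet_argument_error")
})

test_that("Beer-Lambert conversion inverts the forward extinction model", {
  E <- extinction_coefficients()
  d <- 2; n <- 50
  hbo <- matrix(rnorm(d * n), d, n)
  hbr <- matrix(rnorm(d * n), d, n)
  scale <- 3 * 6   # distance_cm * dpf
  od <- matrix(0, 2 * d, n)
  for (i in seq_len(d)) {
    od[2 * i - 1, ] <- (E[1, 1] * hbo[i, ] + E[1, 2] * hbr[i, ]) * scale
    od[2 * i, ]     <- (E[2, 1] * hbo[i, ] + E[2, 2] * hbr[i, ]) * scale
  }
  out <- mbll(raw_fnirs(od, 11, signal_kind = "optical_density"))
  expect_equal(out$data, hbo, tolerance = 1e-12)
  expect_equal(attr(out, "hbr"), hbr, tolerance = 1e-12)
  expect_equal(out$signal_kind, "hbo")
  # zero optical density maps to zero concentration
  z <- mbll(raw_fnirs(matrix(0, 2, 10), 11, signal_kind = "optical_density"))
  expect_true(all(z$data == 0))
  # 2x2 inversion agrees with a generic dense solve
  dod <- c(0.013, 0.021)
  ours <- solve(E) %*% dod / scale
  generic <- qr.solve(E * scale, dod)
  expect_lt(max(abs(ours - generic)), 1e-12)
  expect_error(mbll(raw_fnirs(od, 11, signal_kind = "optical_density"),
                    extinction = matrix(1, 2, 2)),
               class = "hbnet_numerical_error")
})

test_that("baseline correction subtracts the baseline-window mean", {
  x <- matrix(5, 2, 100)
  out <- baseline_correct(x, 100, c(0, 0.5))
  expect_true(all(out == 0))
  y <- matrix(rnorm(200), 2, 100)
  expect_equal(baseline_correct(y + 5, 100, c(0, 1)),
               baseline_correct(y, 100, c(0, 1)))
  idx <- 1:50
  out2 <- baseline_correct(y, 100, c(0, 0.5))
  expect_lt(max(abs(rowMeans(out2[, idx]))), 1e-12)
  expect_error(baseline_correct(y, 100, c(2, 3)), class = "hbnet_argument_error")
})

test_that("segmentation yields floor((n-r)/step)+1 aligned windows", {
  x <- matrix(rnorm(2 * 12000), 2, 12000)   # 60 s at 200 Hz
  w <- segment_windows(x, 200)
  expect_length(w, 39)
  expect_equal(vapply(w, `[[`, numeric(1), "t_start"), seq(0, by = 1.5, length.out = 39))
  expect_equal(dim(w[[1]]$data), c(600L, 2L))
  expect_length(segment_windows(x[, 1:600, drop = FALSE], 200), 1)
  expect_warning(out <- segment_windows(x[, 1:580, drop = FALSE], 200),
                 "shorter than one window")
  expect_length(out, 0)
  # alignment across modality streams of one trial
  y <- matrix(rnorm(3 * 12000), 3, 12000)
  wy <- segment_windows(y, 200)
  expect_equal(vapply(wy, `[[`, numeric(1), "t_start"),
               vapply(w, `[[`, numeric(1), "t_start"))
})

test_that("common-average re-reference zeroes the channel mean", {
  x <- matrix(rnorm(50), 5, 10)
  out <- rereference_car(x)
  expect_lt(max(abs(colMeans(out))), 1e-12)
})
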