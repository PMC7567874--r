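# Hilbert filter design, analytic signal, filter bank, power normalization,
# display smoothing.

test_that("sigmoid-flank filter gain hits its design points", {
  fs <- 500
  n <- 5000
  band <- band_spec(65, 115)
  g <- design_filter(n, fs, band)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  at <- function(f0) g[which.min(abs(f - f0))] / 2   # analytic doubling
  expect_gt(at(90), 0.99)
  expect_equal(at(65), 0.5, tolerance = 0.02)
  expect_equal(at(115), 0.5, tolerance = 0.02)
  expect_lt(at(65 - 3), 0.01 + 0.01)
  expect_lt(g[1], 1e-6)                              # DC
  expect_lt(abs(g[n / 2 + 1]), 1e-6)                 # Nyquist
  expect_true(all(g[f > fs / 2] == 0))               # one-sided
  # half-width 1 Hz: 0.12 -> 0.88 transition over 2 Hz
  expect_equal(at(64), 0.12, tolerance = 0.01)
  expect_equal(at(66), 0.88, tolerance = 0.01)
  expect_error(design_filter(n, fs, band_spec(200, 260)), "Nyquist")
})

test_that("analytic signal recovers amplitude, phase rate, and modulators", {
  fs <- 500
  t <- (0:2499) / fs
  band <- band_spec(5, 15)
  ep <- as_series_epochs(sin(2 * pi * 10 * t), fs)
  dec <- analytic_signal(ep, band)
  mid <- 500:2000
  expect_equal(mean(dec$amplitude[1, 1, mid]), 1, tolerance = 0.02)
  dphi <- diff(unwrap_phase <- cumsum(c(dec$phase[1, 1, 1],
    atan2(sin(diff(dec$phase[1, 1, ])), cos(diff(dec$phase[1, 1, ]))))))
  expect_equal(mean(dphi[mid]) * fs / (2 * pi), 10, tolerance = 0.05)
  # out-of-band energy is rejected
  ep2 <- as_series_epochs(sin(2 * pi * 10 * t) + 2 * sin(2 * pi * 60 * t), fs)
  dec2 <- analytic_signal(ep2, band)
  expect_equal(mean(dec2$amplitude[1, 1, mid]),
               mean(dec$amplitude[1, 1, mid]), tolerance = 0.05)
  # AM carrier: extracted amplitude tracks the modulator
  mod <- 1 + 0.5 * sin(2 * pi * 1 * t)
  dec3 <- analytic_signal(as_series_epochs(mod * sin(2 * pi * 10 * t), fs), band)
  expect_gt(cor(dec3$amplitude[1, 1, mid], mod[mid]), 0.99)
  expect_warning(analytic_signal(as_series_epochs(sin(2 * pi * 10 * t[1:40]), fs),
                                 band), "unreliable")
})

test_that("filtering is linear and phase ignores amplitude scale", {
  fs <- 500
  set.seed(5)
  a <- rnorm(1000); b <- rnorm(1000)
  band <- band_spec(8, 12)
  da <- analytic_signal(as_series_epochs(a, fs), band)
  db <- analytic_signal(as_series_epochs(b, fs), band)
  dab <- analytic_signal(as_series_epochs(a + b, fs), band)
  za <- da$amplitude * exp(1i * da$phase)
  zb <- db$amplitude * exp(1i * db$phase)
  zab <- dab$amplitude * exp(1i * dab$phase)
  expect_equal(zab, za + zb, tolerance = 1e-8)
  d1 <- analytic_signal(as_series_epochs(a, fs), band)
  d2 <- analytic_signal(as_series_epochs(5 * a, fs), band)
  expect_equal(d1$phase, d2$phase, tolerance = 1e-8)
})

test_that("the filter bank spans 2-16 Hz log-spaced and localizes resets", {
  fs <- 200
  arr <- array(rnorm(2 * 3 * 400), c(2, 3, 400))
  ep <- as_epoch_set(arr, fs)
  fb <- filter_bank(ep, n_bands = 10)
  expect_equal(fb$centers[1], 2)
  expect_equal(fb$centers[10], 16)
  expect_true(all(diff(fb$centers) > 0))
  expect_equal(diff(log(fb$centers)), rep(diff(log(fb$centers))[1], 9),
               tolerance = 1e-9)
  expect_equal(range(fb$widths), c(1, 4), tolerance = 1e-9)
  # a 6 Hz phase-reset fixture concentrates ITC in bands nearest 6 Hz
  set.seed(6)
  n_tr <- 30
  t <- (0:399) / fs
  ph0 <- runif(n_tr, -pi, pi)
  x <- array(0, c(1, n_tr, 400))
  for (tr in seq_len(n_tr)) {
    ph <- ifelse(t < 1, 2 * pi * 6 * t + ph0[tr], 2 * pi * 6 * t)
    x[1, tr, ] <- cos(ph) + 0.3 * rnorm(400)
  }
  fb2 <- filter_bank(as_epoch_set(x, fs), n_bands = 10)
  post <- t >= 1.2 & t < 1.8
  itc_by_band <- vapply(1:10, function(b)
    mean(itc(fb2$phase[b, 1, , ])[post]), 0)
  expect_equal(fb2$centers[which.max(itc_by_band)], 6, tolerance = 1.5)
})

test_that("percent-change power normalizes to the baseline window", {
  fs <- 100
  t <- (0:299) / fs - 1
  amp <- ifelse(t >= 0, 2, 1)
  dec <- structure(list(amplitude = array(rep(amp, each = 1),
                                          c(1, 1, length(t))),
                        phase = NULL, time = t, sample_rate_hz = fs,
                        baseline_window_s = c(-0.9, -0.1)),
                   class = "band_decomposition")
  pc <- percent_change_power(dec)
  expect_equal(pc[1, 1, t < -0.1 & t >= -0.9], rep(0, sum(t < -0.1 & t >= -0.9)))
  expect_equal(unique(pc[1, 1, t >= 0]), 300)
  # constant amplitude: zero percent change everywhere
  dec$amplitude[] <- 3
  expect_true(all(percent_change_power(dec) == 0))
  # random fixture: baseline mean is zero by construction
  set.seed(7)
  dec$amplitude <- array(abs(rnorm(4 * 5 * length(t))) + 0.1,
                         c(4, 5, length(t)))
  pc3 <- percent_change_power(dec)
  base_mean <- apply(pc3[, , t < -0.1 & t >= -0.9], c(1, 2), mean)
  expect_lt(max(abs(base_mean)), 1e-9)
  dec$amplitude[] <- 0
  expect_error(percent_change_power(dec), "zero baseline")
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  fs <- 1000
  t <- seq(-1, 1, length.out = 501)
  cubic <- 2 + t - 3 * t^2 + 0.5 * t^3
  sm <- smooth_for_display(cubic, fs)
  inner <- 50:450
  expect_equal(sm[inner], cubic[inner], tolerance = 1e-9)
  expect_equal(smooth_for_display(rep(4, 200), fs), rep(4, 200),
               tolerance = 1e-9)
  expect_error(smooth_for_display(cubic, 30, order = 3, frame_ms = 83),
               "exceed")
  # white-noise variance shrinks by the filter's theoretical factor
  h <- signal::sgolay(p = 3, n = 83)[42, ]
  set.seed(8)
  x <- rnorm(50000)
  v_ratio <- var(smooth_for_display(x, fs)[100:49900]) / var(x)
  expect_equal(v_ratio, sum(h^2), tolerance = 0.1)
})

test_that("ITC conclusions agree between Hilbert and FIR implementations", {
  fs <- 200
  set.seed(9)
  n_tr <- 25
  t <- (0:599) / fs
  x <- array(0, c(1, n_tr, 600))
  for (tr in seq_len(n_tr)) {
    ph0 <- runif(1, -pi, pi)
    ph <- ifelse(t < 1.5, 2 * pi * 6 * t + ph0, 2 * pi * 6 * t)
    x[1, tr, ] <- cos(ph) + 0.5 * rnorm(600)
  }
  ep <- as_epoch_set(x, fs)
  dec <- analytic_signal(ep, band_spec(4, 8))
  itc_h <- itc(dec$phase[1, , ])
  # independent route: FIR bandpass + full-band analytic signal
  fir <- signal::fir1(64, c(4, 8) / (fs / 2), type = "pass")
  ph_f <- apply(x[1, , ], 1, function(s) {
    y <- signal::filtfilt(fir, s)
    n <- length(y)
    gain <- c(1, rep(2, floor((n - 1) / 2)), rep(0, ceiling((n - 1) / 2)))
    if (n %% 2 == 0) gain[n / 2 + 1] <- 1
    Arg(fft(fft(y) * gain, inverse = TRUE) / n)
  })
  itc_f <- itc(t(ph_f))
  pre <- t < 1.2; post <- t >= 1.6
  expect_gt(mean(itc_h[post]) - mean(itc_h[pre]), 0.2)
  expect_gt(mean(itc_f[post]) - mean(itc_f[pre]), 0.2)
  expect_gt(cor(itc_h, itc_f), 0.8)
})
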