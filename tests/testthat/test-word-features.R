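test_that("phase-space reconstruction lays out delay vectors", {
  ps <- reconstruct_phase_space(c(1, 2, 3, 4), 1, 2)
  expect_equal(unclass(ps)[, 1], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(unclass(ps)[, 2], c(2, 3, 4), ignore_attr = TRUE)
  expect_equal(nrow(reconstruct_phase_space(1:10, 2, 2)), 8)
  cps <- reconstruct_phase_space(rep(5, 20), 3, 4)
  expect_true(all(cps == 5))
  expect_error(reconstruct_phase_space(1:4, 2, 3),
               class = "voicelevel_too_short_error")
})

test_that("Higuchi dimension hits the analytic anchors", {
  expect_equal(higuchi_fd(seq_len(1000), 8), 1, tolerance = 0.02)
  set.seed(30)
  d_noise <- vapply(1:20, function(i) higuchi_fd(rnorm(5000), 8), 0)
  expect_equal(mean(d_noise), 2, tolerance = 0.1)
  sine <- sin(2 * pi * 5 * seq_len(5000) / 5000)
  expect_equal(higuchi_fd(sine, 8), 1, tolerance = 0.1)
  expect_error(higuchi_fd(rnorm(100), 1), class = "voicelevel_parameter_error")
})

test_that("Higuchi dimension is affine-invariant and complexity-ordered", {
  set.seed(31)
  x <- rnorm(2000)
  d <- higuchi_fd(x)
  expect_equal(higuchi_fd(3.7 * x - 11), d, tolerance = 1e-10)
  expect_equal(higuchi_fd(-0.2 * x + 5), d, tolerance = 1e-10)
  # sine (D=1) < Brownian noise (D=1.5) < white noise (D=2), over 20 seeds
  ord_ok <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 2000
    white <- rnorm(n)
    brown <- cumsum(rnorm(n))
    sine <- sin(2 * pi * 3 * seq_len(n) / n + runif(1))
    d <- c(higuchi_fd(sine), higuchi_fd(brown), higuchi_fd(white))
    all(diff(d) > 0)
  }, TRUE)
  expect_true(mean(ord_ok) >= 0.95)
})

test_that("Lyapunov exponent of the logistic map matches ln 2", {
  set.seed(5)
  x <- numeric(2000); x[1] <- 0.4
  for (i in 2:2000) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  # analytic value ln 2, cross-checked by the orbit-derivative average
  orbit <- mean(log(abs(4 - 8 * x)))
  expect_equal(orbit, log(2), tolerance = 0.02)
  lam <- largest_lyapunov(x, delay = 1, dimension = 2, fit_range = 4,
                          theiler = 10)
  expect_equal(lam, log(2), tolerance = 0.05 / log(2))
  expect_lt(abs(lam - orbit), 0.05)
})

test_that("Lyapunov sign semantics separate periodic, damped and chaotic", {
  t <- seq_len(3000)
  sine <- sin(2 * pi * t / 50)
  expect_lte(largest_lyapunov(sine, delay = 12, dimension = 3,
                              fit_range = 50), 0.02)
  damped <- exp(-t / 150) * sin(2 * pi * t / 25)
  expect_lt(largest_lyapunov(damped, delay = 6, dimension = 3,
                             fit_range = 100), 0)
  expect_error(largest_lyapunov(rnorm(50)), class = "voicelevel_too_short_error")
})

test_that("wavelet energies equal the direct-summation reference", {
  set.seed(40)
  scales <- c(4L, 5L, 6L)  # smaller dyadic scales keep the oracle affordable
  for (i in 1:10) {
    x <- rnorm(1500)
    got <- wavelet_energy(x, scales = scales)
    want <- oracle_wavelet_energy(x, scales)
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
  # and once at the production scales 7..9
  x <- rnorm(8000)
  expect_equal(unname(wavelet_energy(x)), oracle_wavelet_energy(x, 7:9),
               tolerance = 1e-6)
})

test_that("wavelet energy is quadratic in amplitude and zero for silence", {
  expect_equal(unname(wavelet_energy(rep(0, 8000))), rep(0, 3))
  set.seed(41)
  x <- rnorm(8000)
  expect_equal(wavelet_energy(3 * x), 9 * wavelet_energy(x), tolerance = 1e-9)
  expect_error(wavelet_energy(rnorm(100)), class = "voicelevel_too_short_error")
})

test_that("wavelet energies track spectral content across scales", {
  fs <- 44100; n <- 22050
  t <- seq_len(n) / fs
  tone <- sin(2 * pi * 100 * t)
  chirp <- sin(2 * pi * (50 + (5000 - 50) * t / max(t) / 2) * t)
  e_tone <- wavelet_energy(tone); e_chirp <- wavelet_energy(chirp)
  # the 100 Hz tone loads the coarsest scale far more than the chirp does
  expect_gt(e_tone["s9"] / sum(e_tone), e_chirp["s9"] / sum(e_chirp))
})

test_that("word_features returns the five named features", {
  w <- test_vowel(f0 = 240, seed = 13)
  wv <- word_features(trim_endpoints(w))
  expect_equal(names(wv),
               c("fractal_dim", "lyapunov", "wav_s7", "wav_s8", "wav_s9"))
  expect_true(all(is.finite(wv)))
  expect_gte(wv["fractal_dim"], 1)
  expect_lte(wv["fractal_dim"], 2)
  expect_true(all(wv[3:5] >= 0))
})
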