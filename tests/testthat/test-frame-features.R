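test_that("autocorrelation pitch tracking recovers known fundamentals", {
  fs <- 44100
  n <- 1103
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  sine <- sin(2 * pi * 200 * (0:(n - 1)) / fs) * win
  expect_equal(estimate_f0(sine, fs), 200, tolerance = 1 / 200)

  set.seed(11)
  expect_equal(estimate_f0(rnorm(n) * win, fs), 0)  # unvoiced

  # glottal pulse train synthesized at 250 Hz
  w <- test_vowel(f0 = 250, seed = 9)
  fm <- frame_signal(trim_endpoints(w))
  f0s <- apply(fm$frames[5:10, ], 1, estimate_f0, sample_rate = fs)
  expect_true(all(abs(f0s - 250) < 2.5))

  expect_error(estimate_f0(sine, fs, fmin = 500, fmax = 200),
               class = "voicelevel_parameter_error")
})

test_that("pitch estimate is invariant to amplitude scaling", {
  fs <- 44100
  w <- test_vowel(f0 = 180, seed = 4)
  fm <- frame_signal(trim_endpoints(w))
  for (t in c(3, 8, 15)) {
    f <- fm$frames[t, ]
    for (c in c(0.01, 1, 37)) {
      expect_equal(estimate_f0(c * f, fs), estimate_f0(f, fs),
                   tolerance = 1e-9)
    }
  }
})

test_that("LPC root-solving recovers resonator formants within 5%", {
  fs <- 10000
  targets <- c(700, 1220, 2600); bws <- c(130, 70, 160)
  n <- 4000
  set.seed(2)
  src <- numeric(n); src[seq(1, n, by = round(fs / 120))] <- 1
  x <- src
  for (j in 1:3)
    x <- voicelevel:::.resonator_tv_cpp(x, rep(targets[j], n), rep(bws[j], n), fs)
  frame <- x[2001:2400] * (0.54 - 0.46 * cos(2 * pi * (0:399) / 399))
  f <- estimate_formants(frame, fs, lpc_order = 12)
  expect_true(all(abs(f - targets) / targets < 0.05))

  # single resonator: only f1 defined
  x1 <- voicelevel:::.resonator_tv_cpp(src, rep(500, n), rep(80, n), fs)
  f1 <- estimate_formants(x1[2001:2400], fs, lpc_order = 10)
  expect_equal(unname(f1["f1"]), 500, tolerance = 0.05)
  expect_true(is.na(f1["f3"]))

  expect_true(all(is.na(estimate_formants(rep(0, 400), fs))))
  expect_error(estimate_formants(rnorm(10), fs, lpc_order = 12),
               class = "voicelevel_parameter_error")
})

test_that("relative intensity is a max-normalized RMS ratio", {
  m <- rbind(rep(2, 100), rep(1, 100), rep(0.5, 100))
  ri <- relative_intensity(m)
  expect_equal(ri, c(1, 0.5, 0.25))
  expect_equal(max(ri), 1)
  # constant-amplitude tone: all frames near 1
  w <- waveform(sin(2 * pi * 300 * seq_len(16000) / 16000), 16000)
  ri2 <- relative_intensity(frame_signal(w))
  expect_true(all(ri2 > 0.99))
  expect_error(relative_intensity(matrix(0, 3, 10)),
               class = "voicelevel_empty_utterance_error")
})

test_that("nasality score is the capped reciprocal of the f1 - 1 kHz gap", {
  fs <- 11025
  w <- test_vowel(f0 = 200, nasal_db = 0, seed = 3)
  xd <- signal::decimate(trim_endpoints(w)$samples, 4)
  fm <- frame_signal(waveform(xd, fs))
  mid <- round(nrow(fm$frames) / 2)
  f1 <- estimate_formants(fm$frames[mid, ], fs)["f1"]
  ns <- nasality_score(fm$frames[mid, ], fs, f1)
  expect_equal(ns$diff_db, ns$amp_f1_db - ns$amp_1k_db)
  expect_equal(ns$score, 1 / max(ns$diff_db, 0.5))
  # degenerate gap is capped at 1/eps
  expect_lte(ns$score, 2)
  # undefined f1 propagates as missing
  expect_true(is.na(nasality_score(fm$frames[mid, ], fs, NA_real_)$score))
})

test_that("an injected 1 kHz resonance raises the nasality score", {
  fs <- 11025
  score_at <- function(gain_db) {
    w <- test_vowel(f0 = 210, nasal_db = gain_db, seed = 12, snr_db = 40)
    xd <- signal::decimate(trim_endpoints(w)$samples, 4)
    fm <- frame_signal(waveform(xd, fs))
    mids <- seq(round(nrow(fm$frames) * 0.3), round(nrow(fm$frames) * 0.7))
    d <- vapply(mids, function(t) {
      f1 <- estimate_formants(fm$frames[t, ], fs)["f1"]
      nasality_score(fm$frames[t, ], fs, f1)$diff_db
    }, 0)
    median(d, na.rm = TRUE)
  }
  gaps <- vapply(c(0, 6, 12, 18), score_at, 0)
  expect_true(all(diff(gaps) < 0))  # gap shrinks as the nasal peak grows
})

test_that("approximate entropy matches the brute-force double loop", {
  expect_equal(approximate_entropy(rep(3.2, 50)), 0)
  alt <- rep(c(1, -1), 50)
  expect_equal(approximate_entropy(alt, 2, 0.2),
               oracle_apen(alt, 2, 0.2 * sd(alt)), tolerance = 1e-10)
  set.seed(8)
  for (n in c(40, 120, 200)) {
    x <- rnorm(n)
    expect_equal(approximate_entropy(x, 2, 0.2),
                 oracle_apen(x, 2, 0.2 * sd(x)), tolerance = 1e-10)
    x2 <- sin(seq_len(n) / 3) + rnorm(n, 0, 0.05)
    expect_equal(approximate_entropy(x2, 3, 0.5),
                 oracle_apen(x2, 3, 0.5 * sd(x2)), tolerance = 1e-10)
  }
  expect_error(approximate_entropy(rnorm(50), r = 0),
               class = "voicelevel_parameter_error")
})

test_that("ApEn separates irregular from regular signals", {
  set.seed(21)
  noise <- vapply(1:5, function(i) approximate_entropy(rnorm(1000)), 0)
  sine <- approximate_entropy(sin(2 * pi * 7 * seq_len(1000) / 1000))
  expect_true(all(noise > sine))
})

test_that("frame feature sequences are complete 8-column matrices", {
  w <- test_vowel(f0 = 230, seed = 6)
  ff <- frame_features(trim_endpoints(w))
  expect_equal(colnames(ff),
               c("f0", "f1", "f2", "f3", "f1f2", "ri", "nasality", "apen"))
  expect_true(all(is.finite(ff)))
  expect_equal(max(ff[, "ri"]), 1)
  voiced <- ff[, "f0"] > 0
  expect_equal(ff[voiced, "f1f2"],
               ff[voiced, "f1"] / ff[voiced, "f2"], tolerance = 1e-9)
  expect_true(all(ff[, "f1"] < ff[, "f2"] & ff[, "f2"] < ff[, "f3"]))
})
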