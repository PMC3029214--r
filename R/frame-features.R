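#' Estimate fundamental frequency of one frame by autocorrelation
#'
#' Normalized autocorrelation is searched over the lag range corresponding to
#' `[fmin, fmax]`; the highest peak is refined by parabolic interpolation.
#' Frames whose peak normalized autocorrelation falls below
#' `voicing_threshold` are reported unvoiced (returned as 0), the encoding the
#' downstream HMM observation vectors use.
#'
#' @param frame numeric vector of (windowed) samples.
#' @param sample_rate sampling rate in Hz.
#' @param fmin,fmax pitch search range in Hz; defaults 100-600 Hz cover
#'   children's voices.
#' @param voicing_threshold minimum peak normalized autocorrelation for a
#'   frame to count as voiced (default 0.45).
#' @param window_correction divide by the Hamming window's autocorrelation
#'   before peak picking (default `TRUE`); this removes the downward lag
#'   bias the window taper introduces.
#' @return f0 in Hz, or 0 for unvoiced frames.
#' @export
estimate_f0 <- function(frame, sample_rate, fmin = 100, fmax = 600,
                        voicing_threshold = 0.45, window_correction = TRUE) {
  if (fmin >= fmax) vl_stop("fmin must be < fmax", "parameter")
  if (fmax >= sample_rate / 2) vl_stop("fmax must be < sample_rate/2", "parameter")
  x <- frame - mean(frame)
  n <- length(x)
  r <- autocorr_fft(x)
  if (r[1] <= 0) return(0)
  r <- r / r[1]
  if (window_correction) r <- r / pmax(window_autocorr(n), 0.1)
  lmin <- max(2L, floor(sample_rate / fmax))
  lmax <- min(n - 1L, ceiling(sample_rate / fmin))
  if (lmax <= lmin) return(0)
  seg <- r[(lmin + 1L):(lmax + 1L)]
  i <- which.max(seg)
  if (seg[i] < voicing_threshold) return(0)
  lag <- lmin + i - 1L
  # parabolic refinement around the peak
  if (lag > lmin && lag < lmax) {
    y1 <- r[lag]; y2 <- seg[i]; y3 <- r[lag + 2L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / den
  }
  sample_rate / lag
}

autocorr_fft <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, rep(0, nfft - n)))
  Re(fft(X * Conj(X), inverse = TRUE))[1:n] / nfft
}

# normalized autocorrelation of the Hamming window, cached per length
.vl_cache <- new.env(parent = emptyenv())
window_autocorr <- function(n) {
  key <- as.character(n)
  rw <- .vl_cache[[key]]
  if (is.null(rw)) {
    rw <- autocorr_fft(hamming_window(n))
    rw <- rw / rw[1]
    .vl_cache[[key]] <- rw
  }
  rw
}

#' Estimate the first three formants of a frame by LPC root-solving
#'
#' The vocal tract is modelled as an all-pole (autoregressive) filter fitted
#' by the autocorrelation method; formants are the AR polynomial roots with
#' positive imaginary part and bandwidth below `max_bw_hz`, converted to Hz
#' and sorted ascending. The frame is pre-emphasized before fitting. For
#' reliable estimates the frame should be at a sampling rate near 10 kHz (see
#' [corpus_features()], which decimates before calling this).
#'
#' @param frame numeric vector of (windowed) samples.
#' @param sample_rate sampling rate in Hz.
#' @param lpc_order AR model order (default 14, suited to ~10-11 kHz audio
#'   with a tilted glottal source).
#' @param max_bw_hz maximum formant bandwidth in Hz (default 400).
#' @return named numeric vector `c(f1, f2, f3)` in Hz; missing formants are
#'   `NA` (an all-zero or degenerate frame yields all `NA`).
#' @export
estimate_formants <- function(frame, sample_rate, lpc_order = 14,
                              max_bw_hz = 400) {
  if (lpc_order >= length(frame)) vl_stop("lpc_order must be < frame length", "parameter")
  out <- c(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_)
  x <- frame - 0.97 * c(0, frame[-length(frame)])  # pre-emphasis
  if (sum(x^2) <= 1e-20) return(out)
  r <- autocorr_fft(x)[1:(lpc_order + 1)]
  r[1] <- r[1] * (1 + 1e-9)  # ridge against singular Toeplitz
  a <- tryCatch(solve(stats::toeplitz(r[1:lpc_order]), -r[2:(lpc_order + 1)]),
                error = function(e) NULL)
  if (is.null(a) || any(!is.finite(a))) return(out)
  # roots of z^p + a1 z^(p-1) + ... + ap
  z <- tryCatch(polyroot(c(rev(a), 1)), error = function(e) NULL)
  if (is.null(z)) return(out)
  z <- z[Im(z) > 0]
  if (length(z) == 0L) return(out)
  f <- Arg(z) * sample_rate / (2 * pi)
  bw <- -log(pmin(Mod(z), 1 - 1e-12)) * sample_rate / pi
  keep <- f > 90 & f < sample_rate / 2 - 50 & bw < max_bw_hz
  f <- sort(f[keep])
  if (length(f) >= 1L) out["f1"] <- f[1]
  if (length(f) >= 2L) out["f2"] <- f[2]
  if (length(f) >= 3L) out["f3"] <- f[3]
  out
}

#' Relative intensity of each frame
#'
#' Frame intensity is RMS energy; relative intensity is the ratio to the
#' loudest frame of the word, so the maximum over frames is exactly 1.
#'
#' @param frames a `"frame_matrix"` from [frame_signal()], or a plain T x L
#'   matrix.
#' @return numeric vector of per-frame relative intensities in `(0, 1]`.
#' @export
relative_intensity <- function(frames) {
  m <- if (inherits(frames, "frame_matrix")) frames$frames else frames
  rms <- sqrt(rowMeans(m^2))
  mx <- max(rms)
  if (mx <= 0) vl_stop("all-zero word: relative intensity undefined", "empty_utterance")
  rms / mx
}

#' Spectral nasality score of a frame
#'
#' Hypernasal voicing shows an extra spectral peak near 1 kHz together with a
#' reduced first-formant amplitude. The score is the reciprocal of the dB
#' difference between the smoothed-spectrum peak at the first formant and the
#' largest peak in the 900-1100 Hz band, capped at `1/eps` so it stays finite:
#' larger score = more nasal.
#'
#' @param frame numeric vector of (windowed) samples.
#' @param sample_rate sampling rate in Hz.
#' @param f1_hz first-formant frequency of the frame (Hz), or `NA`.
#' @param eps cap on the dB difference (default 0.5 dB): differences at or
#'   below `eps` score `1/eps`.
#' @param nfft FFT length (default 2048).
#' @return list with `amp_f1_db`, `amp_1k_db`, `diff_db`, `score` (all `NA`
#'   when `f1_hz` is missing).
#' @export
nasality_score <- function(frame, sample_rate, f1_hz, eps = 0.5, nfft = 2048) {
  miss <- list(amp_f1_db = NA_real_, amp_1k_db = NA_real_,
               diff_db = NA_real_, score = NA_real_)
  # the score needs a first formant clearly below the 900-1100 Hz band,
  # otherwise the f1 peak and the "extra" 1 kHz peak are the same peak
  if (is.na(f1_hz) || f1_hz >= 850) return(miss)
  n <- length(frame)
  if (n > nfft) nfft <- 2^ceiling(log2(n))
  spec <- Mod(fft(c(frame, rep(0, nfft - n))))[1:(nfft / 2)]
  db <- 20 * log10(spec + 1e-12)
  # ~60 Hz moving-average smoothing removes pitch harmonics ripple
  halfw <- max(1L, round(30 / (sample_rate / nfft)))
  k <- 2L * halfw + 1L
  sm <- stats::filter(c(rep(db[1], halfw), db, rep(db[length(db)], halfw)),
                      rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)[(halfw + 1L):(halfw + length(db))]
  freqs <- (seq_along(sm) - 1L) * sample_rate / nfft
  pk <- which(diff(sign(diff(sm))) < 0) + 1L  # local maxima
  amp_f1 <- if (length(pk)) {
    near <- pk[which.min(abs(freqs[pk] - f1_hz))]
    if (abs(freqs[near] - f1_hz) <= 250) sm[near] else sm[which.min(abs(freqs - f1_hz))]
  } else sm[which.min(abs(freqs - f1_hz))]
  band <- which(freqs >= 900 & freqs <= 1100)
  if (length(band) == 0L) return(miss)
  amp_1k <- max(sm[band])
  diff_db <- amp_f1 - amp_1k
  list(amp_f1_db = amp_f1, amp_1k_db = amp_1k, diff_db = diff_db,
       score = 1 / max(diff_db, eps))
}

#' Approximate entropy of a sample sequence
#'
#' Standard ApEn with self-matches: `Phi_m(r) - Phi_(m+1)(r)`, where `Phi_m`
#' is the mean log fraction of length-`m` templates within max-norm distance
#' `r*SD(x)`. Regular signals score near 0, irregular ones higher; it
#' remains usable on the short (~100-sample) per-frame series this package
#' feeds it.
#'
#' @param x numeric sample sequence with `length(x) > m + 1`.
#' @param m template (embedding) length, default 2.
#' @param r tolerance in units of `SD(x)`, default 0.2.
#' @return ApEn in nats (>= 0 up to rounding).
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2) {
  if (r <= 0) vl_stop("tolerance r must be > 0", "parameter")
  if (length(x) <= m + 1L) vl_stop("sequence too short for ApEn", "too_short")
  .apen_cpp(as.numeric(x), as.integer(m), r * sd(x))
}

#' Feature-extraction configuration
#'
#' Collects the tunable constants of frame- and word-level feature
#' extraction with their defaults.
#'
#' @param f0_fmin,f0_fmax pitch search range, Hz.
#' @param voicing_threshold autocorrelation voicing threshold.
#' @param lpc_order AR order for formant analysis (on decimated audio).
#' @param formant_fs target sampling rate for formant analysis, Hz; the
#'   waveform is decimated by an integer factor to at most this rate.
#' @param apen_m,apen_r ApEn template length and tolerance (units of SD).
#' @param apen_decim extra decimation factor for the per-frame ApEn series.
#' @param nasality_eps cap (dB) for the reciprocal nasality score.
#' @param frame_length_s,overlap framing convention.
#' @param trim_db,trim_subframe_s endpoint-trimming parameters.
#' @param higuchi_kmax Higuchi maximum subsampling interval.
#' @param lyap_dim,lyap_delay,lyap_fit Lyapunov embedding dimension, delay
#'   (`NA` = first autocorrelation minimum), and divergence-fit horizon in
#'   steps (`NA` = one mean period).
#' @param lyap_maxn cap on series length for the Lyapunov neighbour search.
#' @param wavelet_order Gaussian-derivative mother wavelet order.
#' @param wavelet_scales dyadic scale indices j (scale = a0^j samples).
#' @param wavelet_a0 scale base.
#' @return a named list of class `"vl_config"`.
#' @export
feature_config <- function(f0_fmin = 100, f0_fmax = 600,
                           voicing_threshold = 0.45,
                           lpc_order = 14, formant_fs = 11025,
                           apen_m = 2L, apen_r = 0.2, apen_decim = 2L,
                           nasality_eps = 0.5,
                           frame_length_s = 0.025, overlap = 0.75,
                           trim_db = -35, trim_subframe_s = 0.01,
                           higuchi_kmax = 8L,
                           lyap_dim = 5L, lyap_delay = NA, lyap_fit = NA,
                           lyap_maxn = 2000L,
                           wavelet_order = 5L, wavelet_scales = c(7L, 8L, 9L),
                           wavelet_a0 = 2) {
  structure(as.list(environment()), class = "vl_config")
}

#' Frame-based feature sequence of one utterance
#'
#' Computes the eight per-frame features forming the HMM observation vector:
#' f0, f1, f2, f3, f1/f2, relative intensity, nasality score and approximate
#' entropy. Formants (and nasality, which needs f1) are computed on the
#' waveform decimated to ~11 kHz; ApEn on the decimated frame subsampled once
#' more. Missing values (unvoiced/degenerate frames) are filled by carrying
#' the last defined value forward, then by the word median, so every
#' observation vector is complete; f0 keeps 0 as its unvoiced code.
#'
#' @param w a (trimmed) [waveform()].
#' @param config a [feature_config()].
#' @return T x 8 numeric matrix with columns `f0, f1, f2, f3, f1f2, ri,
#'   nasality, apen`.
#' @export
frame_features <- function(w, config = feature_config()) {
  fm <- frame_signal(w, config$frame_length_s, config$overlap)
  Tn <- nrow(fm$frames)
  # decimated copy for formant/nasality/ApEn analysis
  dec <- max(1L, floor(w$sample_rate / config$formant_fs))
  wd <- if (dec > 1L) {
    # FIR anti-aliasing: the IIR (Chebyshev) default rings near its cutoff,
    # which the AR fit then mistakes for a high formant
    waveform(signal::decimate(w$samples, dec, ftype = "fir"),
             w$sample_rate / dec)
  } else w
  fmd <- frame_signal(wd, config$frame_length_s, config$overlap)
  Tn <- min(Tn, nrow(fmd$frames))

  f0 <- vapply(seq_len(Tn), function(t)
    estimate_f0(fm$frames[t, ], fm$sample_rate, config$f0_fmin, config$f0_fmax,
                config$voicing_threshold), 0)
  frm <- t(vapply(seq_len(Tn), function(t)
    estimate_formants(fmd$frames[t, ], fmd$sample_rate, config$lpc_order),
    c(f1 = 0, f2 = 0, f3 = 0)))
  ri <- relative_intensity(fm$frames[seq_len(Tn), , drop = FALSE])
  nas <- vapply(seq_len(Tn), function(t)
    nasality_score(fmd$frames[t, ], fmd$sample_rate, frm[t, "f1"],
                   config$nasality_eps)$score, 0)
  ad <- max(1L, config$apen_decim)
  apen <- vapply(seq_len(Tn), function(t) {
    xs <- fmd$frames[t, seq(1, ncol(fmd$frames), by = ad)]
    if (sd(xs) <= 0) 0 else approximate_entropy(xs, config$apen_m, config$apen_r)
  }, 0)

  out <- cbind(f0 = f0, f1 = frm[, "f1"], f2 = frm[, "f2"], f3 = frm[, "f3"],
               f1f2 = frm[, "f1"] / frm[, "f2"], ri = ri, nasality = nas,
               apen = apen)
  fill_missing(out)
}

# carry last defined value forward, backfill the head, then column medians;
# a column undefined everywhere falls back to 0 (it is z-scored away later)
fill_missing <- function(m) {
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (!anyNA(v)) next
    ok <- which(!is.na(v))
    if (length(ok) == 0L) { m[, j] <- 0; next }
    idx <- findInterval(seq_along(v), ok)
    med <- median(v[ok])
    filled <- ifelse(idx >= 1L, v[ok[pmax(idx, 1L)]], med)
    m[, j] <- filled
  }
  m
}
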