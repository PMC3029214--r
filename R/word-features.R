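#' Delay-embed a scalar series into phase space
#'
#' Point `i` is `(x_i, x_(i+tau), ..., x_(i+(m-1)tau))`; the reconstruction
#' exposes the attractor geometry of the speech production system.
#'
#' @param x numeric sample sequence.
#' @param delay embedding delay tau in samples.
#' @param dimension embedding dimension m (>= 2).
#' @return an N x m matrix of class `"phase_space"` with attributes `delay`
#'   and `dimension`; `N = length(x) - (m - 1) * delay`.
#' @export
reconstruct_phase_space <- function(x, delay = 1L, dimension = 2L) {
  delay <- as.integer(delay); dimension <- as.integer(dimension)
  if (delay < 1L || dimension < 2L)
    vl_stop("delay must be >= 1 and dimension >= 2", "parameter")
  n <- length(x) - (dimension - 1L) * delay
  if (n < 1L) vl_stop("series too short for this embedding", "too_short")
  emb <- vapply(0:(dimension - 1L), function(k) x[(1:n) + k * delay],
                numeric(n))
  structure(matrix(emb, nrow = n), class = "phase_space",
            delay = delay, dimension = dimension)
}

#' Higuchi fractal dimension
#'
#' Curve length `L(k)` of the `k`-subsampled series scales as `k^(-D)`; D is
#' minus the slope of the least-squares line through `(log k, log L(k))`.
#' D is 1 for a smooth curve and approaches 2 for white noise.
#'
#' @param x numeric sample sequence, `length(x) >= 2 * kmax`.
#' @param kmax maximum subsampling interval (default 8).
#' @return the fractal dimension (dimensionless).
#' @export
higuchi_fd <- function(x, kmax = 8L) {
  kmax <- as.integer(kmax)
  if (kmax < 2L) vl_stop("kmax must be >= 2", "parameter")
  n <- length(x)
  if (n < 2L * kmax) vl_stop("series too short for this kmax", "too_short")
  Lk <- vapply(1:kmax, function(k) {
    mean(vapply(1:k, function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      norm <- (n - 1) / ((length(idx) - 1L) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, 0), na.rm = TRUE)
  }, 0)
  -unname(coef(lm(log(Lk) ~ log(1:kmax)))[2])
}

#' Largest Lyapunov exponent (Rosenstein small-data method)
#'
#' Each embedded point is paired with its nearest neighbour outside a Theiler
#' window of one mean period; the slope of the mean log divergence of these
#' pairs over the initial `fit_range` steps estimates the largest exponent.
#' Positive values indicate chaotic (exponentially diverging) dynamics,
#' near-zero periodic/aperiodic dynamics, negative converging dynamics.
#'
#' @param x numeric sample sequence.
#' @param delay embedding delay in samples; `NA` picks the first minimum of
#'   the autocorrelation function (fallback 1).
#' @param dimension embedding dimension (default 5).
#' @param fit_range number of divergence steps used in the slope fit; `NA`
#'   uses one mean period (dominant spectral peak).
#' @param theiler temporal exclusion window for the neighbour search; `NA`
#'   uses one mean period.
#' @return the exponent in 1/sample (per step of `x`).
#' @export
largest_lyapunov <- function(x, delay = NA, dimension = 5L, fit_range = NA,
                             theiler = NA) {
  x <- as.numeric(x)
  if (is.na(delay)) delay <- first_acf_minimum(x)
  emb <- reconstruct_phase_space(x, delay, dimension)
  if (nrow(emb) < 100L) vl_stop("too few embedded points (< 100)", "too_short")
  mp <- mean_period(x)
  if (is.na(theiler)) theiler <- mp
  if (is.na(fit_range)) fit_range <- max(3L, mp)
  maxt <- min(as.integer(fit_range), nrow(emb) - 1L)
  div <- .lyap_divergence_cpp(unclass(emb), as.integer(theiler), maxt)
  t <- 0:maxt
  ok <- is.finite(div)
  if (sum(ok) < 3L) vl_stop("divergence curve degenerate", "too_short")
  unname(coef(lm(div[ok] ~ t[ok]))[2])
}

first_acf_minimum <- function(x, max_lag = min(length(x) - 2L, 500L)) {
  a <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  i <- which(diff(a) > 0)
  if (length(i) == 0L) 1L else max(1L, i[1])
}

# dominant-spectral-peak period in samples (>= 1)
mean_period <- function(x) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[2:floor(n / 2)]
  if (length(sp) < 2L || max(sp) <= 0) return(1L)
  f <- which.max(sp) / n
  max(1L, round(1 / f))
}

#' Mean energy of continuous wavelet coefficients at dyadic scales
#'
#' The mother wavelet is an order-`order` Gaussian derivative; the analysis
#' family is `psi_jk(t) = a0^(-j/2) psi(a0^(-j) t - k b0)` with unit
#' translation steps `b0 = 1` (so translations step by `a0^j` raw samples).
#' The coefficient `d_jk` is the discrete inner product of the signal with
#' `psi_jk`, and the feature is the mean of `d_jk^2` over k for each scale
#' index j.
#'
#' @param x numeric sample sequence.
#' @param scales dyadic scale indices j (default 7, 8, 9).
#' @param order Gaussian-derivative order of the mother wavelet (default 5).
#' @param a0 scale base (default 2).
#' @param b0 translation step in scaled time units (default 1).
#' @return named numeric vector of per-scale mean energies (`s7`, `s8`, ...).
#' @export
wavelet_energy <- function(x, scales = c(7L, 8L, 9L), order = 5L, a0 = 2,
                           b0 = 1) {
  if (order < 1L) vl_stop("wavelet order must be >= 1", "parameter")
  n <- length(x)
  half <- 5  # e^(-u^2) support radius in scaled units
  widest <- (2 * half + 1) * a0^max(scales)
  if (n < widest)
    vl_stop(sprintf("signal (%d) shorter than widest wavelet support (%d)",
                    n, as.integer(widest)), "too_short")
  out <- vapply(scales, function(j) {
    a <- a0^j
    u <- seq(-half * a, half * a) / a
    psi <- gauss_derivative(u, order)
    step <- max(1L, as.integer(round(b0 * a)))
    # d_k = a^(-1/2) * sum_t x_t psi(t/a - k b0): full cross-correlation,
    # sampled at centres t = k*a*b0 whose wavelet support lies inside x
    cc <- conv_full(x, rev(psi))
    valid <- cc[seq(length(psi), n)]
    d <- valid[seq(step, length(valid), by = step)] / sqrt(a)
    mean(d^2)
  }, 0)
  names(out) <- paste0("s", scales)
  out
}

# n-th derivative of exp(-u^2) via Hermite polynomials:
# d^n/du^n e^(-u^2) = (-1)^n H_n(u) e^(-u^2)
gauss_derivative <- function(u, order) {
  h <- list(rep(1, length(u)), 2 * u)
  if (order >= 2) for (k in 2:order)
    h[[k + 1]] <- 2 * u * h[[k]] - 2 * (k - 1) * h[[k - 1]]
  (-1)^order * h[[order + 1]] * exp(-u^2)
}

conv_full <- function(x, y) {
  nf <- length(x) + length(y) - 1L
  nfft <- 2^ceiling(log2(nf))
  Re(fft(fft(c(x, rep(0, nfft - length(x)))) *
           fft(c(y, rep(0, nfft - length(y)))), inverse = TRUE))[1:nf] / nfft
}

#' Word-level feature vector of one utterance
#'
#' Computes the five word-based features: Higuchi fractal dimension, largest
#' Lyapunov exponent, and the mean wavelet-coefficient energies at scale
#' indices 7, 8 and 9. Nonlinear features are computed on the waveform
#' decimated to ~11 kHz (capped at `lyap_maxn` centre samples for the
#' neighbour search); the signal is peak-normalized before the wavelet
#' energies so they reflect spectral shape rather than recording gain.
#'
#' @param w a (trimmed) [waveform()].
#' @param config a [feature_config()].
#' @return named numeric vector `c(fractal_dim, lyapunov, wav_s7, wav_s8,
#'   wav_s9)` (wavelet names follow `config$wavelet_scales`).
#' @export
word_features <- function(w, config = feature_config()) {
  dec <- max(1L, floor(w$sample_rate / config$formant_fs))
  xs <- if (dec > 1L) signal::decimate(w$samples, dec, ftype = "fir")
        else w$samples
  fd <- higuchi_fd(xs, config$higuchi_kmax)
  xl <- xs
  if (length(xl) > config$lyap_maxn) {  # centred excerpt for O(N^2) search
    from <- floor((length(xl) - config$lyap_maxn) / 2) + 1L
    xl <- xl[from:(from + config$lyap_maxn - 1L)]
  }
  ly <- tryCatch(
    largest_lyapunov(xl, config$lyap_delay, config$lyap_dim, config$lyap_fit),
    voicelevel_error = function(e) 0)
  xn <- w$samples / max(abs(w$samples), 1e-12)
  we <- wavelet_energy(xn, config$wavelet_scales, config$wavelet_order,
                       config$wavelet_a0)
  c(fractal_dim = fd, lyapunov = ly, stats::setNames(we, paste0("wav_", names(we))))
}
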