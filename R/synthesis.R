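#' Specification of one synthetic utterance
#'
#' Parameters of the source-filter synthesizer: a jittered/shimmered glottal
#' impulse train drives a cascade of time-varying second-order formant
#' resonators, optionally augmented by a nasal resonance near 1 kHz, plus
#' additive white noise at a given SNR.
#'
#' @param f0_mean mean fundamental frequency, Hz (100-600).
#' @param f0_jitter fractional period perturbation per glottal cycle.
#' @param formant_targets list with `times` (fractions of the utterance in
#'   `[0,1]`), `f` (targets x 3 formant centre matrix, Hz) and `bw`
#'   (targets x 3 bandwidths, Hz); trajectories are linearly interpolated.
#' @param nasal_peak_gain_db gain of the added 1 kHz nasal resonance in dB
#'   (0 = no nasal branch).
#' @param shimmer fractional amplitude perturbation per glottal cycle.
#' @param noise_snr_db additive white-noise SNR in dB.
#' @param duration_s utterance duration in seconds (> 0.2).
#' @param sample_rate sampling rate, Hz (default 44100, the recording rate
#'   the grading task assumes).
#' @param seed integer seed; the waveform is deterministic given the spec.
#' @return a list of class `"synth_spec"`.
#' @export
synth_spec <- function(f0_mean = 250, f0_jitter = 0.01,
                       formant_targets = vowel_targets("a"),
                       nasal_peak_gain_db = 0, shimmer = 0.03,
                       noise_snr_db = 30, duration_s = 0.5,
                       sample_rate = 44100, seed = 1L) {
  if (f0_mean < 100 || f0_mean > 600)
    vl_stop("f0_mean must be within 100-600 Hz", "parameter")
  if (duration_s <= 0.2) vl_stop("duration must exceed 0.2 s", "parameter")
  if (any(apply(formant_targets$f, 1, diff) <= 0))
    vl_stop("formant centres must be ascending", "parameter")
  if (any(formant_targets$bw <= 0))
    vl_stop("resonator bandwidths must be positive", "parameter")
  structure(as.list(environment()), class = "synth_spec")
}

#' Formant target table for a vowel sequence
#'
#' Child-like vowel formant targets; multi-vowel sequences get evenly spaced
#' target times with brief onset/offset holds.
#'
#' @param vowels character vector from `"a","i","u","o","e"`.
#' @return list with `times`, `f`, `bw` as used by [synth_spec()].
#' @export
vowel_targets <- function(vowels) {
  tab <- list(a = c(900, 1400, 2900), i = c(400, 2500, 3400),
              u = c(450, 1150, 2600), o = c(550, 1000, 2700),
              e = c(550, 2100, 3100))
  bad <- setdiff(vowels, names(tab))
  if (length(bad)) vl_stop(paste0("unknown vowel(s): ", paste(bad, collapse = ",")),
                           "parameter")
  f <- do.call(rbind, tab[vowels])
  if (nrow(f) == 1L) { f <- rbind(f, f); }
  k <- nrow(f)
  times <- seq(0.1, 0.9, length.out = k)
  list(times = c(0, times, 1), f = rbind(f[1, ], f, f[k, ]),
       bw = matrix(rep(c(90, 110, 170), k + 2), ncol = 3, byrow = TRUE))
}

#' Synthesize one utterance from a spec
#'
#' @param spec a [synth_spec()].
#' @return a [waveform()] with peak amplitude 0.9.
#' @export
synthesize_utterance <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    fs <- spec$sample_rate
    n <- round(spec$duration_s * fs)
    # glottal source: jittered impulse train with shimmer, -6 dB/oct tilt
    src <- numeric(n)
    pos <- 1 + runif(1) * fs / spec$f0_mean
    while (pos <= n) {
      src[round(pos)] <- 1 * (1 + spec$shimmer * rnorm(1))
      period <- (fs / spec$f0_mean) * (1 + spec$f0_jitter * rnorm(1))
      pos <- pos + max(period, 2)
    }
    src <- as.numeric(stats::filter(src, 0.98, method = "recursive"))
    # time-varying formant cascade
    tt <- seq(0, 1, length.out = n)
    y <- src
    for (j in 1:3) {
      fj <- approx(spec$formant_targets$times, spec$formant_targets$f[, j],
                   tt, rule = 2)$y
      bj <- approx(spec$formant_targets$times, spec$formant_targets$bw[, j],
                   tt, rule = 2)$y
      y <- .resonator_tv_cpp(y, fj, bj, fs)
    }
    g <- 10^(spec$nasal_peak_gain_db / 20) - 1
    if (g > 0) {
      nas <- .resonator_tv_cpp(src, rep(1000, n), rep(120, n), fs)
      y <- y + g * nas * sqrt(mean(y^2)) / max(sqrt(mean(nas^2)), 1e-12)
    }
    # raised-cosine onset/offset envelope (30 ms)
    ramp <- min(round(0.03 * fs), floor(n / 4))
    env <- c(0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp),
             rep(1, n - 2 * ramp),
             0.5 + 0.5 * cos(pi * seq_len(ramp) / ramp))
    y <- y * env
    noise <- rnorm(n) * sqrt(mean(y^2) / 10^(spec$noise_snr_db / 10))
    y <- y + noise
    waveform(0.9 * y / max(abs(y)), fs)
  })
}

#' Severity-level parameter profile of the synthetic corpus
#'
#' Encodes the acoustic signature of each severity level (1 = most severe,
#' 4 = typical hearing): severe levels have higher and more variable
#' fundamental frequency, more jitter and shimmer, a stronger nasal peak,
#' more additive noise, and formant trajectories flattened toward a neutral
#' schwa. Means decrease (or flattening decreases) monotonically from level
#' 1 to level 4.
#'
#' @param separation multiplier on the between-level separation of all
#'   severity-linked parameters (1 = default profile; 0 collapses all levels
#'   onto the level-4 values).
#' @return a list of class `"level_profile"`: per-level parameter means and
#'   SDs (`child_sd` between children, `utt_sd` between repetitions) and the
#'   per-word vowel templates.
#' @export
level_profile <- function(separation = 1) {
  blend <- function(severe, normal) normal + separation * (severe - normal)
  params <- list(
    f0_mean  = list(mean = blend(c(400, 340, 295, 260), 260),
                    child_sd = 22, utt_sd = 8),
    f0_jitter = list(mean = blend(c(0.035, 0.022, 0.012, 0.006), 0.006),
                     child_sd = 0.004, utt_sd = 0.002),
    shimmer  = list(mean = blend(c(0.14, 0.09, 0.05, 0.025), 0.025),
                    child_sd = 0.015, utt_sd = 0.008),
    nasal_peak_gain_db = list(mean = blend(c(18, 12, 6, 0), 0),
                              child_sd = 1.5, utt_sd = 1),
    noise_snr_db = list(mean = blend(c(14, 18, 23, 28), 28),
                        child_sd = 2, utt_sd = 1),
    traj_flatten = list(mean = blend(c(0.5, 0.33, 0.17, 0), 0),
                        child_sd = 0.05, utt_sd = 0.03),
    duration_s = list(mean = blend(c(0.58, 0.53, 0.49, 0.45), 0.45),
                      child_sd = 0.04, utt_sd = 0.025))
  words <- list(mashin = vowel_targets(c("a", "i")),
                mar = vowel_targets("a"),
                moosh = vowel_targets("u"),
                gav = vowel_targets(c("a", "o")),
                mouz = vowel_targets(c("o", "u")))
  structure(list(params = params, words = words, separation = separation),
            class = "level_profile")
}

# pull formant targets toward schwa by fraction `flatten`
flatten_targets <- function(targets, flatten) {
  schwa <- c(600, 1500, 2500)
  f <- targets$f
  for (j in 1:3) f[, j] <- f[, j] + flatten * (schwa[j] - f[, j])
  # keep ascending order with a minimal gap
  f[, 2] <- pmax(f[, 2], f[, 1] + 150)
  f[, 3] <- pmax(f[, 3], f[, 2] + 250)
  list(times = targets$times, f = f, bw = targets$bw)
}

#' Generate a labelled synthetic corpus
#'
#' Mirrors the study geometry by default: 6 children in each of levels 1-3,
#' 12 in level 4, each uttering the five words 7 times, giving 1050
#' utterances. Each child draws level-conditional random effects for every
#' severity-linked parameter; each repetition adds utterance-level noise.
#'
#' @param profile a [level_profile()].
#' @param n_children integer vector of children per level (default
#'   `c(6, 6, 6, 12)`).
#' @param reps_per_word repetitions of each word per child (default 7).
#' @param sample_rate sampling rate of the synthesized audio, Hz.
#' @param seed integer seed; manifests and audio are reproducible.
#' @param dir optional directory: when given, WAV files, `manifest.csv` and
#'   `truth.tsv` are written there.
#' @return an `utterance_corpus` (see [read_corpus()]) with attribute
#'   `"truth"`, a data.frame of the generating parameters per utterance.
#' @export
generate_corpus <- function(profile = level_profile(),
                            n_children = c(6L, 6L, 6L, 12L),
                            reps_per_word = 7L, sample_rate = 44100,
                            seed = 1L, dir = NULL) {
  stopifnot(inherits(profile, "level_profile"))
  draws <- with_seed(seed, {
    rows <- list(); ri <- 0L
    for (lev in vl_levels) {
      for (ci in seq_len(n_children[lev])) {
        child <- sprintf("L%d_C%02d", lev, ci)
        ceff <- lapply(profile$params, function(p)
          rnorm(1, p$mean[lev], p$child_sd))
        for (word in names(profile$words)) {
          for (rep in seq_len(reps_per_word)) {
            u <- lapply(names(profile$params), function(nm) {
              p <- profile$params[[nm]]
              ceff[[nm]] + rnorm(1, 0, p$utt_sd)
            })
            names(u) <- names(profile$params)
            ri <- ri + 1L
            rows[[ri]] <- c(list(child_id = child, level = lev, word = word,
                                 repetition = rep,
                                 seed = sample.int(.Machine$integer.max, 1)), u)
          }
        }
      }
    }
    rows
  })
  recs <- vector("list", length(draws))
  truth <- do.call(rbind, lapply(draws, function(r)
    data.frame(r[names(r) != "seed"], stringsAsFactors = FALSE)))
  for (i in seq_along(draws)) {
    r <- draws[[i]]
    spec <- synth_spec(
      f0_mean = min(max(r$f0_mean, 120), 580),
      f0_jitter = max(r$f0_jitter, 0.001),
      formant_targets = flatten_targets(profile$words[[r$word]],
                                        min(max(r$traj_flatten, 0), 0.9)),
      nasal_peak_gain_db = max(r$nasal_peak_gain_db, 0),
      shimmer = max(r$shimmer, 0.003),
      noise_snr_db = min(max(r$noise_snr_db, 5), 40),
      duration_s = min(max(r$duration_s, 0.35), 0.8),
      sample_rate = sample_rate, seed = r$seed)
    recs[[i]] <- utterance_record(synthesize_utterance(spec), r$word, r$level,
                                  r$child_id, r$repetition)
  }
  corpus <- structure(recs, class = "utterance_corpus", truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    man <- corpus_manifest(corpus)
    man$path <- sprintf("%s_%s_r%02d.wav", man$child_id, man$word,
                        man$repetition)
    for (i in seq_along(recs))
      write_wav(recs[[i]]$wave, file.path(dir, man$path[i]))
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  corpus
}
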