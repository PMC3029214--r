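#' Construct a waveform object
#'
#' A waveform is a numeric sample vector (nominally in `[-1, 1]`) plus its
#' sampling rate in Hz. All audio entering the feature extractors is carried in
#' this form.
#'
#' @param samples numeric vector of at least one finite sample.
#' @param sample_rate sampling rate in Hz (positive).
#' @return an object of class `"waveform"` with fields `samples` and
#'   `sample_rate`.
#' @export
waveform <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) vl_stop("waveform needs at least one sample", "format")
  if (any(!is.finite(samples))) vl_stop("waveform contains non-finite samples", "format")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    vl_stop("sample_rate must be a positive scalar", "format")
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Read a RIFF PCM WAV file
#'
#' Reads uncompressed PCM (8/16/24/32-bit integer or 32/64-bit float) WAV
#' audio. Stereo is mixed to mono by channel averaging and integer samples are
#' rescaled to `[-1, 1]`.
#'
#' @param path path to a `.wav` file.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) vl_stop(paste0("no such file: ", path), "format")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF"))
    vl_stop(paste0("not a RIFF/WAV file: ", path), "format")
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    vl_stop(paste0("not a RIFF/WAV file: ", path), "format")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      blk <- readBin(con, "raw", size)
      if (length(blk) < 16L) vl_stop(paste0("truncated fmt chunk: ", path), "format")
      u16 <- function(i) sum(as.integer(blk[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.integer(blk[i:(i + 3)]) * c(1, 256, 65536, 16777216))
      fmt <- list(format = u16(1), channels = u16(3), rate = u32(5),
                  bits = u16(15))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    vl_stop(paste0("truncated or chunk-less WAV file: ", path), "format")
  if (!fmt$format %in% c(1L, 3L))
    vl_stop(paste0("unsupported (compressed) WAV encoding ", fmt$format, ": ", path),
            "format")
  bytes <- fmt$bits / 8
  n <- floor(length(data_raw) / bytes)
  if (n < 1L) vl_stop(paste0("empty WAV data chunk: ", path), "format")
  x <- if (fmt$format == 3L) {
    readBin(data_raw, "double", n, size = bytes, endian = "little")
  } else if (fmt$bits == 8L) {
    (as.integer(data_raw[seq_len(n)]) - 128) / 128
  } else if (fmt$bits == 24L) {
    b <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else {
    readBin(data_raw, "integer", n, size = bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bits - 1)
  }
  if (fmt$channels > 1L) {
    nf <- floor(length(x) / fmt$channels)
    x <- rowMeans(matrix(x[seq_len(nf * fmt$channels)], ncol = fmt$channels,
                         byrow = TRUE))
  }
  waveform(x, fmt$rate)
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param w a [waveform()]; samples are clipped to `[-1, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(w$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")  # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Trim leading and trailing silence from an utterance
#'
#' Short-time energy is computed on non-overlapping sub-frames; the waveform is
#' cut to the span from the first to the last sub-frame whose energy exceeds
#' `threshold_db` relative to the loudest sub-frame.
#'
#' @param w a [waveform()].
#' @param threshold_db energy threshold in dB relative to the maximum
#'   sub-frame energy (default -35).
#' @param subframe_s sub-frame length in seconds (default 0.01).
#' @return the trimmed [waveform()].
#' @export
trim_endpoints <- function(w, threshold_db = -35, subframe_s = 0.01) {
  stopifnot(inherits(w, "waveform"))
  L <- max(1L, floor(subframe_s * w$sample_rate))
  n <- length(w$samples)
  nsub <- max(1L, floor(n / L))
  idx <- seq_len(nsub * L)
  en <- colSums(matrix(w$samples[idx]^2, nrow = L))
  emax <- max(en)
  if (emax <= 0) vl_stop("utterance is silent: no frame above threshold", "empty_utterance")
  keep <- which(10 * log10(en / emax) > threshold_db)
  if (length(keep) == 0L)
    vl_stop("utterance is silent: no frame above threshold", "empty_utterance")
  from <- (min(keep) - 1L) * L + 1L
  to <- min(n, max(keep) * L)
  if (min(keep) == 1L && max(keep) == nsub) to <- n
  waveform(w$samples[from:to], w$sample_rate)
}

#' Cut a waveform into Hamming-windowed frames
#'
#' Frames are 25 ms with 75% overlap by default (the analysis convention used
#' throughout the package). Frame length is `floor(frame_length_s * fs)`
#' samples, the hop is `round(L * (1 - overlap))`, and a trailing partial frame
#' is dropped.
#'
#' @param w a [waveform()].
#' @param frame_length_s frame length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return an object of class `"frame_matrix"`: list with `frames` (T x L
#'   matrix of windowed samples), `hop`, `frame_length_s`, `overlap`,
#'   `sample_rate`.
#' @export
frame_signal <- function(w, frame_length_s = 0.025, overlap = 0.75) {
  stopifnot(inherits(w, "waveform"))
  if (overlap < 0 || overlap >= 1) vl_stop("overlap must be in [0, 1)", "parameter")
  L <- floor(frame_length_s * w$sample_rate)
  n <- length(w$samples)
  if (n < L) vl_stop("signal shorter than one frame", "too_short")
  hop <- max(1L, as.integer(floor(L * (1 - overlap) + 0.5)))
  nT <- floor((n - L) / hop) + 1L
  starts <- (seq_len(nT) - 1L) * hop
  win <- hamming_window(L)
  frames <- matrix(w$samples[outer(seq_len(L), starts, `+`)], ncol = L,
                   byrow = TRUE) * rep(win, each = nT)
  structure(list(frames = frames, hop = hop, frame_length_s = frame_length_s,
                 overlap = overlap, sample_rate = w$sample_rate),
            class = "frame_matrix")
}

# symmetric Hamming window (0.54 - 0.46 cos), the common speech convention
hamming_window <- function(L) {
  if (L == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' Read a corpus manifest and its audio
#'
#' The manifest is a CSV with columns `path`, `child_id`, `word`, `level`,
#' `repetition`; paths are resolved relative to the manifest's directory.
#'
#' @param manifest path to the manifest CSV.
#' @return an `utterance_corpus`: list of records, each with fields `wave`,
#'   `word`, `level`, `child_id`, `repetition`.
#' @export
read_corpus <- function(manifest) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path", "child_id", "word", "level", "repetition")
  if (!all(need %in% names(tab)))
    vl_stop(paste0("manifest must have columns ", paste(need, collapse = ", ")),
            "format")
  root <- dirname(normalizePath(manifest))
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(root, tab$path[i])
    utterance_record(read_wav(p), tab$word[i], tab$level[i], tab$child_id[i],
                     tab$repetition[i])
  })
  structure(recs, class = "utterance_corpus")
}

#' Construct one labelled utterance record
#'
#' @param wave a [waveform()].
#' @param word one of [vl_words].
#' @param level severity level in 1..4 (1 = most severe).
#' @param child_id opaque child identifier.
#' @param repetition repetition index (>= 1).
#' @return a list of class `"utterance_record"`.
#' @export
utterance_record <- function(wave, word, level, child_id, repetition = 1L) {
  if (!word %in% vl_words)
    vl_stop(paste0("unknown word '", word, "'"), "format")
  level <- as.integer(level)
  if (!level %in% vl_levels) vl_stop("level must be in 1..4", "format")
  structure(list(wave = wave, word = word, level = level,
                 child_id = as.character(child_id),
                 repetition = as.integer(repetition)),
            class = "utterance_record")
}

#' Manifest of an in-memory corpus
#'
#' @param corpus an `utterance_corpus`.
#' @return data.frame with one row per utterance: `child_id`, `word`, `level`,
#'   `repetition`.
#' @export
corpus_manifest <- function(corpus) {
  data.frame(
    child_id = vapply(corpus, `[[`, "", "child_id"),
    word = vapply(corpus, `[[`, "", "word"),
    level = vapply(corpus, `[[`, 0L, "level"),
    repetition = vapply(corpus, `[[`, 0L, "repetition"),
    stringsAsFactors = FALSE)
}

#' @export
print.utterance_corpus <- function(x, ...) {
  m <- corpus_manifest(x)
  cat(sprintf("<utterance_corpus: %d utterances, %d children, %d words, levels %s>\n",
              nrow(m), length(unique(m$child_id)), length(unique(m$word)),
              paste(sort(unique(m$level)), collapse = ",")))
  invisible(x)
}
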