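#' Extract all features of a corpus
#'
#' Trims each utterance's endpoints, then computes the frame-based feature
#' sequence (HMM observations) and the word-based feature vector (MLP input)
#' for every utterance. This is the expensive step; its result can be reused
#' across cross-validation repetitions because models are retrained on index
#' subsets of it.
#'
#' @param corpus an `utterance_corpus` ([generate_corpus()], [read_corpus()]).
#' @param config a [feature_config()].
#' @return an object of class `"corpus_features"`: a list with one element
#'   per utterance (`frames` T x 8 matrix, `wordvec` 5-vector, plus the
#'   labels), and the manifest as attribute `"manifest"`.
#' @export
corpus_features <- function(corpus, config = feature_config()) {
  recs <- lapply(corpus, function(rec) {
    w <- trim_endpoints(rec$wave, config$trim_db, config$trim_subframe_s)
    list(frames = frame_features(w, config),
         wordvec = word_features(w, config),
         word = rec$word, level = rec$level, child_id = rec$child_id,
         repetition = rec$repetition)
  })
  structure(recs, class = "corpus_features",
            manifest = corpus_manifest(corpus), config = config)
}

#' Write per-utterance features to TSV files
#'
#' One frame-feature TSV per utterance (a row per frame, Table-style header)
#' plus a single word-feature table with metadata columns.
#'
#' @param features a [corpus_features()] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_features <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wf <- NULL
  for (i in seq_along(features)) {
    f <- features[[i]]
    base <- sprintf("%s_%s_r%02d", f$child_id, f$word, f$repetition)
    write.table(round(f$frames, 6), file.path(dir, paste0(base, ".frames.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    wf <- rbind(wf, data.frame(child_id = f$child_id, word = f$word,
                               level = f$level, repetition = f$repetition,
                               t(f$wordvec)))
  }
  write.table(wf, file.path(dir, "word_features.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Fit the hierarchical voice-severity grader
#'
#' Trains the full first-stage classifier bank on (a subset of) a featurized
#' corpus: one continuous left-right GMM-HMM per (word, level) — 20 models
#' for the five-word, four-level task — on the z-scored frame-feature
#' sequences, plus one word-feature perceptron pooled over words. Frame
#' features are z-scored per feature with statistics computed on the training
#' subset only and stored in the model.
#'
#' @param features a [corpus_features()] object.
#' @param subset integer indices of training utterances (default: all).
#' @param n_states,n_mix HMM topology (defaults 8 states, 4 mixtures).
#' @param n_hidden hidden units of the word-feature perceptron (default 10).
#' @param max_iter,tol Baum-Welch stopping rule.
#' @param mlp_epochs,mlp_lr perceptron training parameters.
#' @param seed integer seed driving k-means and weight initialization.
#' @return an object of class `"voice_grader"`.
#' @export
voice_grader <- function(features, subset = NULL, n_states = 8L, n_mix = 4L,
                         n_hidden = 10L, max_iter = 50L, tol = 1e-5,
                         mlp_epochs = 2000L, mlp_lr = 0.01, seed = 1L) {
  stopifnot(inherits(features, "corpus_features"))
  if (is.null(subset)) subset <- seq_along(features)
  tr <- features[subset]
  words <- sort(unique(vapply(tr, `[[`, "", "word")))
  allX <- do.call(rbind, lapply(tr, `[[`, "frames"))
  norm <- list(mu = colMeans(allX), sd = apply(allX, 2, sd))
  norm$sd[norm$sd <= 0] <- 1
  zscore <- function(X) scale(X, norm$mu, norm$sd)

  hmms <- list()
  for (w in words) {
    hmms[[w]] <- vector("list", length(vl_levels))
    for (lev in vl_levels) {
      idx <- which(vapply(tr, function(f) f$word == w && f$level == lev, TRUE))
      if (length(idx) == 0L)
        vl_stop(sprintf("no training utterances for word '%s' level %d", w, lev),
                "stratification")
      seqs <- lapply(tr[idx], function(f) zscore(f$frames))
      m <- init_hmm(seqs, n_states, n_mix, seed = seed + 131 * lev)
      hmms[[w]][[lev]] <- train_em(m, seqs, max_iter = max_iter, tol = tol)
    }
  }
  WX <- do.call(rbind, lapply(tr, `[[`, "wordvec"))
  wy <- vapply(tr, `[[`, 0L, "level")
  mlp <- mlp_init(ncol(WX), n_hidden, length(vl_levels), seed = seed)
  mlp <- train_mlp(mlp, WX, wy, epochs = mlp_epochs, lr = mlp_lr)
  structure(list(hmms = hmms, mlp = mlp, norm = norm, words = words,
                 n_states = n_states, n_mix = n_mix, meta = NULL,
                 train_size = length(tr), call = match.call()),
            class = "voice_grader")
}

# per-utterance base-classifier outputs on a feature subset:
# data.frame of labels + HMM level/logliks + NN level/soft outputs
grader_utterance_outputs <- function(object, features, subset = NULL) {
  if (is.null(subset)) subset <- seq_along(features)
  zscore <- function(X) scale(X, object$norm$mu, object$norm$sd)
  out <- lapply(subset, function(i) {
    f <- features[[i]]
    cls <- classify_word(object$hmms[[f$word]], zscore(f$frames))
    nn <- predict_level(object$mlp, f$wordvec)
    list(idx = i, word = f$word, level = f$level, child_id = f$child_id,
         repetition = f$repetition, hmm_level = cls$level,
         logliks = cls$logliks, nn_level = nn$level, nn_soft = nn$soft)
  })
  out
}

# fuse one trial (the base outputs of one child-repetition) under one rule
fuse_trial <- function(uo, rule, words, meta = NULL) {
  ll <- do.call(rbind, lapply(uo, `[[`, "logliks"))
  nn_soft <- colMeans(do.call(rbind, lapply(uo, `[[`, "nn_soft")))
  nn_vote <- which.max(nn_soft)
  votes <- c(vapply(uo, `[[`, 0L, "hmm_level"), nn_vote)
  ll_all <- rbind(ll, log(pmax(nn_soft, 1e-12)))
  switch(rule,
    mvr = fuse_mvr(votes, ll_all),
    linear = fuse_linear(ll_all),
    stacked = {
      if (is.null(meta)) vl_stop("stacked rule requires a trained meta-classifier",
                                 "fusion")
      # fixed 6-slot layout: five words (absent word = its HMM bank silent,
      # encoded by the trial's majority to keep the input complete) + NN
      by_word <- stats::setNames(rep(NA_integer_, length(words)), words)
      for (u in uo) by_word[u$word] <- u$hmm_level
      filler <- fuse_mvr(votes)$level
      by_word[is.na(by_word)] <- filler
      fuse_stacked(c(by_word, nn_vote), meta)
    },
    vl_stop(paste0("unknown fusion rule '", rule, "'"), "parameter"))
}

# group utterance outputs into (child, repetition) trials
split_trials <- function(uo) {
  key <- vapply(uo, function(u) paste(u$child_id, u$repetition, sep = "\r"), "")
  split(uo, key)
}

#' Predict severity levels with a fitted grader
#'
#' @param object a fitted [voice_grader()].
#' @param features a [corpus_features()] object to score.
#' @param subset integer indices of the utterances to score (default all).
#' @param rule fusion rule: `"mvr"` (majority voting), `"linear"`
#'   (log-likelihood combination) or `"stacked"` (meta-perceptron; requires
#'   [train_stacked()]).
#' @param type `"trial"` fuses all words of each (child, repetition) pair
#'   into one decision; `"utterance"` returns per-utterance word-classifier
#'   and network decisions.
#' @param ... unused.
#' @return a data.frame: for trials, `child_id`, `repetition`, `level`
#'   (truth) and `predicted`; for utterances additionally `word`,
#'   `hmm_level`, `nn_level`.
#' @export
predict.voice_grader <- function(object, features, subset = NULL,
                                 rule = c("mvr", "linear", "stacked"),
                                 type = c("trial", "utterance"), ...) {
  rule <- match.arg(rule); type <- match.arg(type)
  uo <- grader_utterance_outputs(object, features, subset)
  if (type == "utterance") {
    return(data.frame(
      child_id = vapply(uo, `[[`, "", "child_id"),
      word = vapply(uo, `[[`, "", "word"),
      repetition = vapply(uo, `[[`, 0L, "repetition"),
      level = vapply(uo, `[[`, 0L, "level"),
      hmm_level = vapply(uo, `[[`, 0L, "hmm_level"),
      nn_level = vapply(uo, `[[`, 0L, "nn_level"),
      stringsAsFactors = FALSE))
  }
  trials <- split_trials(uo)
  out <- do.call(rbind, lapply(trials, function(tu) {
    dec <- fuse_trial(tu, rule, object$words, object$meta)
    data.frame(child_id = tu[[1]]$child_id, repetition = tu[[1]]$repetition,
               level = tu[[1]]$level, predicted = dec$level,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Train the stacked-fusion meta-classifier
#'
#' Computes the six base decisions (five word classifiers + word-feature
#' network) on held-out trials and trains the 6-10-4 meta-perceptron on
#' them. The subset must be disjoint from the grader's training data.
#'
#' @param object a fitted [voice_grader()].
#' @param features a [corpus_features()] object.
#' @param subset utterance indices of the meta-training split.
#' @param epochs,lr meta-network training parameters.
#' @param seed integer seed.
#' @return the grader with `$meta` set.
#' @export
train_stacked <- function(object, features, subset, epochs = 2000L, lr = 0.05,
                          seed = 1L) {
  uo <- grader_utterance_outputs(object, features, subset)
  trials <- split_trials(uo)
  X <- do.call(rbind, lapply(trials, function(tu) {
    by_word <- stats::setNames(rep(NA_integer_, length(object$words)),
                               object$words)
    for (u in tu) by_word[u$word] <- u$hmm_level
    nn_soft <- colMeans(do.call(rbind, lapply(tu, `[[`, "nn_soft")))
    votes <- c(vapply(tu, `[[`, 0L, "hmm_level"), which.max(nn_soft))
    by_word[is.na(by_word)] <- fuse_mvr(votes)$level
    (c(by_word, which.max(nn_soft)) - 1) / 3
  }))
  y <- vapply(trials, function(tu) tu[[1]]$level, 0L)
  meta <- mlp_init(ncol(X), 10L, length(vl_levels), seed = seed)
  object$meta <- train_mlp(meta, X, y, epochs = epochs, lr = lr)
  object
}

#' @export
print.voice_grader <- function(x, ...) {
  cat("Hierarchical voice-severity grader\n")
  cat(sprintf("  words: %s\n", paste(x$words, collapse = ", ")))
  cat(sprintf("  %d left-right HMMs (%d states, %d mixtures) + %d-%d-%d word-feature MLP\n",
              length(x$words) * length(vl_levels), x$n_states, x$n_mix,
              x$mlp$n_in, x$mlp$n_hidden, x$mlp$n_out))
  cat(sprintf("  trained on %d utterances; stacked meta-classifier: %s\n",
              x$train_size, if (is.null(x$meta)) "not trained" else "trained"))
  invisible(x)
}

#' @export
summary.voice_grader <- function(object, ...) {
  ll <- vapply(object$words, function(w)
    sum(vapply(object$hmms[[w]], function(m) tail(m$loglik_trace, 1), 0)), 0)
  it <- vapply(object$words, function(w)
    sum(vapply(object$hmms[[w]], function(m) length(m$loglik_trace), 0L), 0L),
    0L)
  out <- list(grader = object,
              hmm_summary = data.frame(word = object$words,
                                       total_loglik = ll, em_iterations = it),
              mlp_mse = tail(object$mlp$loss_trace, 1))
  class(out) <- "summary.voice_grader"
  out
}

#' @export
print.summary.voice_grader <- function(x, ...) {
  print(x$grader)
  cat("\nPer-word HMM bank training (summed over the 4 level models):\n")
  print(x$hmm_summary, row.names = FALSE)
  cat(sprintf("\nWord-feature MLP final training MSE: %.4g\n", x$mlp_mse))
  invisible(x)
}

#' Plot Baum-Welch convergence of a fitted grader
#'
#' One panel per word, one line per severity level: total log-likelihood
#' against EM iteration.
#'
#' @param x a fitted [voice_grader()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.voice_grader <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, ceiling(length(x$words) / 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (w in x$words) {
    tr <- lapply(x$hmms[[w]], `[[`, "loglik_trace")
    len <- max(lengths(tr))
    m <- vapply(tr, function(v) c(v, rep(NA, len - length(v))), numeric(len))
    graphics::matplot(m, type = "l", lty = 1, xlab = "EM iteration",
                      ylab = "total log-likelihood", main = w, ...)
  }
  invisible(x)
}

#' Save a fitted grader as JSON
#'
#' Serializes topology, transition matrices, mixture parameters,
#' normalization statistics and perceptron weights to a single JSON file.
#'
#' @param object a fitted [voice_grader()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_grader <- function(object, path) {
  stopifnot(inherits(object, "voice_grader"))
  obj <- unclass(object)
  obj$call <- NULL
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  jsonlite::write_json(strip(obj), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a grader saved by [save_grader()]
#'
#' @param path JSON file path.
#' @return a `"voice_grader"` object.
#' @export
load_grader <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  vec <- function(v) as.numeric(unlist(v))
  mat <- function(m) do.call(rbind, lapply(m, vec))  # rowmajor on disk
  hmms <- lapply(raw$hmms, function(bank) lapply(bank, function(h) {
    structure(list(
      n_states = h$n_states, n_mix = h$n_mix, d = h$d,
      pi = vec(h$pi), A = mat(h$A),
      states = lapply(h$states, function(s)
        list(w = vec(s$w), mu = mat(s$mu), var = mat(s$var))),
      var_floor = h$var_floor,
      loglik_trace = vec(h$loglik_trace)), class = "vl_hmm")
  }))
  mlp_of <- function(m) {
    if (is.null(m)) return(NULL)
    structure(list(
      W1 = mat(m$W1), b1 = vec(m$b1), W2 = mat(m$W2), b2 = vec(m$b2),
      n_in = m$n_in, n_hidden = m$n_hidden, n_out = m$n_out,
      norm = list(mu = vec(m$norm$mu), sd = vec(m$norm$sd)),
      loss_trace = vec(m$loss_trace)), class = "vl_mlp")
  }
  structure(list(hmms = hmms, mlp = mlp_of(raw$mlp),
                 norm = list(mu = vec(raw$norm$mu), sd = vec(raw$norm$sd)),
                 words = as.character(unlist(raw$words)),
                 n_states = raw$n_states, n_mix = raw$n_mix,
                 meta = mlp_of(raw$meta), train_size = raw$train_size),
            class = "voice_grader")
}
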