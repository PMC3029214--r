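#' Random-subsampling cross-validation splits
#'
#' Draws `n_reps` independent random 60/40 train/test partitions of the
#' utterances, stratified by (word, level) so every one of the 20 HMMs has
#' training data. Utterances are never shared between train and test;
#' children may be (the protocol the accuracy tables assume), unless
#' `mode = "child"` forces child-disjoint splits. In stacked mode the test
#' part is further halved into a meta-training and a final test part, split
#' along whole (child, repetition) trials.
#'
#' @param manifest data.frame with columns `child_id`, `word`, `level`,
#'   `repetition` ([corpus_manifest()] or the attribute of
#'   [corpus_features()]).
#' @param train_frac fraction of utterances in the training part (default 0.6).
#' @param n_reps number of repetitions (default 10).
#' @param stacked also produce the `train2`/`test2` partition of `test1`.
#' @param seed integer seed; splits are deterministic given it.
#' @param mode `"utterance"` (default) or `"child"` (child-disjoint).
#' @return list of split plans, each a list `train1`, `test1` (and `train2`,
#'   `test2` when stacked) of utterance indices, plus `seed`.
#' @export
make_splits <- function(manifest, train_frac = 0.6, n_reps = 10L,
                        stacked = FALSE, seed = 1L, mode = c("utterance", "child")) {
  mode <- match.arg(mode)
  n <- nrow(manifest)
  cell <- interaction(manifest$word, manifest$level, drop = TRUE)
  if (any(table(manifest$word, manifest$level) == 0))
    vl_stop("some (word, level) cell has no utterances", "stratification")
  with_seed(seed, lapply(seq_len(n_reps), function(rep) {
    if (mode == "child") {
      train1 <- integer(0)
      for (lev in unique(manifest$level)) {
        kids <- unique(manifest$child_id[manifest$level == lev])
        ktr <- sample(kids, max(1L, round(train_frac * length(kids))))
        train1 <- c(train1, which(manifest$child_id %in% ktr))
      }
      train1 <- sort(train1)
    } else {
      # per-cell floor + largest-remainder apportionment hits the exact
      # overall training count while keeping >= 1 utterance per cell
      target <- round(train_frac * n)
      idx_by_cell <- split(seq_len(n), cell)
      sizes <- lengths(idx_by_cell)
      base <- pmax(1L, floor(train_frac * sizes))
      rem <- train_frac * sizes - base
      extra <- target - sum(base)
      if (extra > 0) {
        ord <- order(rem, decreasing = TRUE)
        give <- ord[seq_len(min(extra, length(ord)))]
        base[give] <- pmin(base[give] + 1L, sizes[give])
      } else if (extra < 0) {
        ord <- order(rem)
        for (i in ord) {
          if (extra == 0) break
          if (base[i] > 1L) { base[i] <- base[i] - 1L; extra <- extra + 1L }
        }
      }
      train1 <- sort(unlist(lapply(seq_along(idx_by_cell), function(i)
        sample(idx_by_cell[[i]], base[i]))))
    }
    test1 <- setdiff(seq_len(n), train1)
    plan <- list(train1 = train1, test1 = test1, seed = seed)
    if (stacked) {
      trial <- paste(manifest$child_id, manifest$repetition, sep = "\r")[test1]
      lev <- manifest$level[test1]
      tkeys <- unique(trial)
      tlev <- lev[match(tkeys, trial)]
      meta_keys <- unlist(lapply(split(tkeys, tlev), function(k)
        sample(k, ceiling(length(k) / 2))))
      plan$train2 <- sort(test1[trial %in% meta_keys])
      plan$test2 <- setdiff(test1, plan$train2)
    }
    plan
  }))
}

per_level_accuracy <- function(truth, predicted) {
  vapply(vl_levels, function(lev) {
    idx <- truth == lev
    if (!any(idx)) return(NA_real_)
    100 * mean(predicted[idx] == lev)
  }, 0)
}

#' Evaluate the full grading pipeline by random subsampling
#'
#' For each split: fits the grader on `train1`, scores the isolated word
#' classifiers and the word-feature network per utterance on the test part,
#' and fuses per-trial decisions under each requested rule (the stacked rule
#' trains its meta-perceptron on `train2` and is scored on `test2`).
#' Accuracies are per-level percentages averaged over repetitions;
#' classifiers averaging below 50% at a level are flagged "not classified".
#'
#' @param features a [corpus_features()] object.
#' @param splits split plans from [make_splits()] (must carry `train2` if
#'   `"stacked"` is requested).
#' @param rules fusion rules to evaluate.
#' @param seed integer seed for model initialization.
#' @param ... passed to [voice_grader()] (e.g. `n_states`, `max_iter`).
#' @return an object of class `"accuracy_report"`: array `acc` (repetition x
#'   classifier x level), matrix `mean_acc` (classifier x level), logical
#'   `not_classified`, and `n_reps`.
#' @export
evaluate_grader <- function(features, splits, rules = c("mvr", "linear"),
                            seed = 1L, ...) {
  man <- attr(features, "manifest")
  words <- sort(unique(man$word))
  classifiers <- c(words, "word_nn", rules)
  acc <- array(NA_real_, c(length(splits), length(classifiers),
                           length(vl_levels)),
               dimnames = list(NULL, classifiers, paste0("L", vl_levels)))
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    fit <- tryCatch(
      voice_grader(features, subset = sp$train1, seed = seed + r, ...),
      voicelevel_error = function(e) {
        warning(sprintf("repetition %d failed (%s); dropped", r,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    uo <- grader_utterance_outputs(fit, features, sp$test1)
    word_of <- vapply(uo, `[[`, "", "word")
    truth_u <- vapply(uo, `[[`, 0L, "level")
    hmm_u <- vapply(uo, `[[`, 0L, "hmm_level")
    nn_u <- vapply(uo, `[[`, 0L, "nn_level")
    for (w in words)
      acc[r, w, ] <- per_level_accuracy(truth_u[word_of == w],
                                        hmm_u[word_of == w])
    acc[r, "word_nn", ] <- per_level_accuracy(truth_u, nn_u)
    for (rule in rules) {
      if (rule == "stacked") {
        if (is.null(sp$train2))
          vl_stop("stacked rule needs splits made with stacked = TRUE",
                  "parameter")
        fit2 <- train_stacked(fit, features, sp$train2, seed = seed + r)
        trials <- split_trials(grader_utterance_outputs(fit2, features,
                                                        sp$test2))
        meta <- fit2$meta
      } else {
        trials <- split_trials(uo)
        meta <- NULL
      }
      truth_t <- vapply(trials, function(tu) tu[[1]]$level, 0L)
      pred_t <- vapply(trials, function(tu)
        fuse_trial(tu, rule, words, meta)$level, 0L)
      acc[r, rule, ] <- per_level_accuracy(truth_t, pred_t)
    }
  }
  mean_acc <- apply(acc, c(2, 3), mean, na.rm = TRUE)
  structure(list(acc = acc, mean_acc = mean_acc,
                 not_classified = mean_acc < 50, n_reps = length(splits),
                 rules = rules, words = words),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 1, ...) {
  cat(sprintf("Per-level accuracy (%%), mean over %d random 60/40 subsamplings\n",
              x$n_reps))
  m <- x$mean_acc
  disp <- matrix(sprintf(paste0("%.", digits, "f"), m), nrow(m),
                 dimnames = dimnames(m))
  disp[x$not_classified] <- paste0(disp[x$not_classified], " (nc)")
  disp[is.na(m)] <- "-"
  mean_all <- rowMeans(m, na.rm = TRUE)
  print(data.frame(classifier = rownames(m), disp,
                   mean = sprintf(paste0("%.", digits, "f"), mean_all),
                   check.names = FALSE, row.names = NULL))
  cat("(nc) = not classified: mean accuracy below 50% at that level\n")
  invisible(x)
}

#' Mean accuracies of an evaluation report
#'
#' @param report an `"accuracy_report"`.
#' @return list with `fused` (named vector: mean-over-levels accuracy per
#'   fusion rule), `isolated_words` (per word), `mean_isolated` (their mean)
#'   and `word_nn`.
#' @export
report_means <- function(report) {
  m <- rowMeans(report$mean_acc, na.rm = TRUE)
  list(fused = m[report$rules],
       isolated_words = m[report$words],
       mean_isolated = mean(m[report$words]),
       word_nn = unname(m["word_nn"]))
}
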