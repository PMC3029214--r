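#' Linear-combination fusion of per-classifier log-likelihoods
#'
#' Sums (uniformly or with weights) each level's log-likelihoods across the
#' base classifiers and picks the level with the maximal combined
#' log-likelihood; ties break toward the lower (more severe) level. Simple
#' averaging is the optimal fuser for classifiers of equal accuracy, hence
#' the uniform default.
#'
#' @param ll N x 4 matrix of log-likelihoods (rows = base classifiers,
#'   columns = levels 1..4), or a list of 4-vectors.
#' @param weights per-classifier weights (default uniform 1).
#' @return list of class `"fusion_decision"`: `level`, `rule = "linear"`,
#'   `evidence` (the 4 combined log-likelihoods).
#' @export
fuse_linear <- function(ll, weights = NULL) {
  if (is.list(ll) && !is.matrix(ll)) ll <- do.call(rbind, ll)
  ll <- as.matrix(ll)
  if (nrow(ll) == 0L) vl_stop("no classifier log-likelihoods to fuse", "fusion")
  if (is.null(weights)) weights <- rep(1, nrow(ll))
  comb <- colSums(ll * weights)
  structure(list(level = which.max(comb), rule = "linear", evidence = comb),
            class = "fusion_decision")
}

#' Majority-voting fusion of crisp level decisions
#'
#' The most frequent level among the base classifiers' crisp outputs wins.
#' Vote ties are resolved by linear-combination evidence when log-likelihoods
#' are supplied, otherwise toward the lower level.
#'
#' @param votes integer vector of crisp levels (1..4), one per classifier.
#' @param ll optional log-likelihood matrix (as in [fuse_linear()]) for tie
#'   breaking.
#' @return list of class `"fusion_decision"`: `level`, `rule = "mvr"`,
#'   `evidence` (the vote counts over levels 1..4).
#' @export
fuse_mvr <- function(votes, ll = NULL) {
  votes <- as.integer(votes)
  if (length(votes) == 0L) vl_stop("no votes to fuse", "fusion")
  counts <- tabulate(votes, nbins = 4L)
  top <- which(counts == max(counts))
  level <- if (length(top) == 1L) top else if (!is.null(ll)) {
    cand <- fuse_linear(ll)$evidence
    top[which.max(cand[top])]
  } else top[1]
  structure(list(level = level, rule = "mvr", evidence = counts),
            class = "fusion_decision")
}

#' Stacked fusion through a meta-perceptron
#'
#' The six base decisions (five word classifiers plus the word-feature
#' network) are scaled to `[0, 1]` by `(level - 1) / 3` and fed to a trained
#' 6-10-4 meta-network; the decision is the argmax output unit. The meta
#' network must be trained on data disjoint from the base classifiers'
#' training split.
#'
#' @param base_levels integer vector of 6 crisp base decisions (1..4).
#' @param meta a trained `"vl_mlp"` with `n_in = length(base_levels)`.
#' @return list of class `"fusion_decision"`: `level`, `rule = "stacked"`,
#'   `evidence` (the 4 soft outputs).
#' @export
fuse_stacked <- function(base_levels, meta) {
  if (!inherits(meta, "vl_mlp") || is.null(meta$loss_trace))
    vl_stop("meta-classifier is not a trained MLP", "fusion")
  if (length(base_levels) != meta$n_in)
    vl_stop("number of base decisions does not match meta input layer", "dimension")
  p <- predict_level(meta, (as.numeric(base_levels) - 1) / 3)
  structure(list(level = p$level, rule = "stacked", evidence = p$soft),
            class = "fusion_decision")
}

#' @export
print.fusion_decision <- function(x, ...) {
  cat(sprintf("<fusion (%s): level %d>\n", x$rule, x$level))
  invisible(x)
}
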