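#' Initialize a continuous left-right HMM
#'
#' Pooled frames are partitioned into `n_states` contiguous time blocks
#' (uniform segmentation); within each block, k-means with `n_mix` centres
#' initializes the state's Gaussian mixture means, cluster scatter (floored)
#' the diagonal variances, and cluster sizes the mixture weights. Transitions
#' start uniform left-right (self 0.5 / forward 0.5, final state absorbing)
#' and all initial mass sits on state 1.
#'
#' @param seqs list of T x d observation matrices (already normalized).
#' @param n_states number of hidden states (default 8).
#' @param n_mix Gaussian mixture components per state (default 4).
#' @param seed integer seed making the k-means initialization reproducible.
#' @param var_floor lower bound on mixture variances (default 1e-3).
#' @return an object of class `"vl_hmm"` with fields `n_states`, `pi`, `A`,
#'   `states` (list of `list(w, mu, var)`), `var_floor`.
#' @export
init_hmm <- function(seqs, n_states = 8L, n_mix = 4L, seed = 1L,
                     var_floor = 1e-3) {
  if (length(seqs) == 0L) vl_stop("no training sequences", "init")
  d <- ncol(seqs[[1]])
  n_states <- as.integer(n_states); n_mix <- as.integer(n_mix)
  # per-sequence uniform segmentation keeps temporal position information
  pooled <- vector("list", n_states)
  for (s in seq_along(seqs)) {
    X <- seqs[[s]]
    bl <- cut(seq_len(nrow(X)), breaks = n_states, labels = FALSE)
    for (st in unique(bl))
      pooled[[st]] <- rbind(pooled[[st]], X[bl == st, , drop = FALSE])
  }
  total <- sum(vapply(pooled, function(p) if (is.null(p)) 0L else nrow(p), 0L))
  if (total < n_states * n_mix)
    vl_stop("insufficient data: need at least n_states*n_mix pooled frames", "init")
  states <- with_seed(seed, lapply(seq_len(n_states), function(st) {
    X <- pooled[[st]]
    if (is.null(X) || nrow(X) < n_mix)
      X <- do.call(rbind, pooled)  # degenerate block: borrow all frames
    km <- suppressWarnings(
      kmeans(X, centers = min(n_mix, nrow(unique(X))), iter.max = 30,
             nstart = 1))
    mu <- km$centers
    M <- nrow(mu)
    v <- t(vapply(seq_len(M), function(m) {
      Xi <- X[km$cluster == m, , drop = FALSE]
      if (nrow(Xi) < 2L) rep(1, d) else pmax(apply(Xi, 2, var), var_floor)
    }, numeric(d)))
    w <- km$size / sum(km$size)
    if (M < n_mix) {  # pad duplicated, slightly perturbed components
      for (m in (M + 1L):n_mix) {
        mu <- rbind(mu, mu[1L + (m - 1L) %% M, ] + rnorm(d, 0, 0.01))
        v <- rbind(v, v[1L + (m - 1L) %% M, ])
        w <- c(w, min(w) / 2)
      }
      w <- w / sum(w)
    }
    list(w = w, mu = unname(mu), var = unname(pmax(v, var_floor)))
  }))
  A <- diag(0.5, n_states)
  for (s in seq_len(n_states - 1L)) A[s, s + 1L] <- 0.5
  A[n_states, n_states] <- 1
  structure(list(n_states = n_states, n_mix = n_mix, d = d,
                 pi = c(1, rep(0, n_states - 1L)), A = A, states = states,
                 var_floor = var_floor),
            class = "vl_hmm")
}

# T x M per-component log densities (including log weights) for one state
state_comp_logdens <- function(X, st) {
  .gmm_comp_logdens_cpp(X, st$mu, st$var, log(st$w))
}

# T x S per-state log emission densities
hmm_logdens <- function(model, X) {
  out <- matrix(0, nrow(X), model$n_states)
  for (s in seq_len(model$n_states)) {
    lc <- state_comp_logdens(X, model$states[[s]])
    m <- apply(lc, 1, max)
    out[, s] <- m + log(rowSums(exp(lc - m)))
  }
  out
}

#' Forward-algorithm log-likelihood of a sequence under an HMM
#'
#' Exact `log P(seq | model)` via the scaled forward recursion.
#'
#' @param model a `"vl_hmm"`.
#' @param seq T x d observation matrix (same normalization as training).
#' @return log-likelihood in nats (`-Inf` if the sequence is impossible).
#' @export
forward_loglik <- function(model, seq) {
  seq <- as.matrix(seq)
  if (ncol(seq) != model$d)
    vl_stop("observation dimension does not match model", "dimension")
  .hmm_forward_cpp(hmm_logdens(model, seq), model$A, model$pi)
}

#' Baum-Welch training of a left-right GMM-HMM
#'
#' Expectation-maximization with per-sequence scaled forward-backward
#' recursions. The left-right zero pattern of the transition matrix and the
#' state-1 start are preserved exactly; mixture variances are floored.
#' Training stops after `max_iter` iterations or when the relative
#' improvement of the total log-likelihood drops below `tol`.
#'
#' @param model an initialized `"vl_hmm"` (see [init_hmm()]).
#' @param seqs list of T x d observation matrices.
#' @param max_iter maximum EM iterations (default 50).
#' @param tol relative log-likelihood improvement threshold (default 1e-5).
#' @return the trained model, with the per-iteration total log-likelihood in
#'   `$loglik_trace`.
#' @export
train_em <- function(model, seqs, max_iter = 50L, tol = 1e-5) {
  if (length(seqs) == 0L) vl_stop("no training sequences", "init")
  S <- model$n_states; M <- model$n_mix; d <- model$d
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ll_tot <- 0
    A_num <- matrix(0, S, S)
    gw <- matrix(0, S, M)                    # sum of mixture responsibilities
    gmu <- array(0, c(S, M, d))
    gx2 <- array(0, c(S, M, d))
    for (si in seq_along(seqs)) {
      X <- as.matrix(seqs[[si]])
      comp <- lapply(seq_len(S), function(s) state_comp_logdens(X, model$states[[s]]))
      logB <- vapply(comp, function(lc) {
        m <- apply(lc, 1, max)
        m + log(rowSums(exp(lc - m)))
      }, numeric(nrow(X)))
      if (nrow(X) == 1L) logB <- matrix(logB, 1L, S)
      fb <- .hmm_fb_cpp(logB, model$A, model$pi)
      if (isTRUE(fb$underflow))
        vl_stop(paste0("numerical underflow training on sequence ", si), "training")
      ll_tot <- ll_tot + fb$loglik
      A_num <- A_num + fb$xi
      for (s in seq_len(S)) {
        lc <- comp[[s]]
        post <- exp(lc - logB[, s])          # within-state component posteriors
        g <- fb$gamma[, s] * post            # T x M joint responsibilities
        gw[s, ] <- gw[s, ] + colSums(g)
        gmu[s, , ] <- gmu[s, , ] + t(g) %*% X
        gx2[s, , ] <- gx2[s, , ] + t(g) %*% X^2
      }
    }
    trace <- c(trace, ll_tot)
    # M-step: transitions (left-right zeros stay zero since xi is zero there)
    rs <- rowSums(A_num)
    for (s in seq_len(S))
      if (rs[s] > 0) model$A[s, ] <- A_num[s, ] / rs[s]
    for (s in seq_len(S)) {
      tot <- sum(gw[s, ])
      if (tot <= 0) next                     # starved state: keep parameters
      w <- pmax(gw[s, ] / tot, 1e-8); w <- w / sum(w)
      mu <- gmu[s, , , drop = FALSE][1, , , drop = TRUE]
      x2 <- gx2[s, , , drop = FALSE][1, , , drop = TRUE]
      if (d == 1L) { mu <- matrix(mu, M, 1); x2 <- matrix(x2, M, 1) }
      if (M == 1L) { mu <- matrix(mu, 1, d); x2 <- matrix(x2, 1, d) }
      denom <- pmax(gw[s, ], 1e-10)
      mu <- mu / denom
      v <- pmax(x2 / denom - mu^2, model$var_floor)
      model$states[[s]] <- list(w = w, mu = mu, var = v)
    }
    if (iter > 1L) {
      rel <- (ll_tot - trace[iter - 1L]) / abs(trace[iter - 1L])
      if (is.finite(rel) && rel < tol) break
    }
  }
  model$loglik_trace <- trace
  model
}

#' Classify one utterance with a word's four level models
#'
#' Scores the sequence under each level's HMM with the forward algorithm and
#' returns the maximizing level; exact ties break toward the lower level.
#'
#' @param models list of 4 `"vl_hmm"` objects, one per level (in level order).
#' @param seq T x d observation matrix.
#' @return list with `level` (1-4) and `logliks` (the 4 log-likelihoods).
#' @export
classify_word <- function(models, seq) {
  ll <- vapply(models, forward_loglik, 0, seq = seq)
  if (all(!is.finite(ll)))
    vl_stop("sequence unscorable under every level model", "scoring")
  list(level = which.max(ll), logliks = ll)
}

#' Sample an observation sequence from a GMM-HMM
#'
#' @param model a `"vl_hmm"`.
#' @param len sequence length.
#' @param seed integer seed.
#' @return T x d observation matrix.
#' @export
simulate_hmm <- function(model, len, seed = 1L) {
  with_seed(seed, {
    S <- model$n_states
    X <- matrix(0, len, model$d)
    s <- sample.int(S, 1, prob = model$pi)
    for (t in seq_len(len)) {
      st <- model$states[[s]]
      m <- sample.int(length(st$w), 1, prob = st$w)
      X[t, ] <- rnorm(model$d, st$mu[m, ], sqrt(st$var[m, ]))
      s <- sample.int(S, 1, prob = model$A[s, ])
    }
    X
  })
}

#' @export
print.vl_hmm <- function(x, ...) {
  cat(sprintf("<left-right GMM-HMM: %d states, %d mixtures, dim %d>\n",
              x$n_states, x$n_mix, x$d))
  if (!is.null(x$loglik_trace))
    cat(sprintf("  trained: %d EM iterations, final total log-lik %.2f\n",
                length(x$loglik_trace), tail(x$loglik_trace, 1)))
  invisible(x)
}
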