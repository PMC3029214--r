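test_that("forward log-likelihood equals exhaustive path enumeration", {
  for (seed in 1:12) {
    S <- sample(1:3, 1); M <- sample(1:2, 1); d <- sample(1:3, 1)
    Tn <- sample(1:6, 1)
    model <- random_hmm(S, M, d, seed, left_right = seed %% 2 == 0)
    X <- matrix(rnorm(Tn * d, 0, 2), Tn, d)
    expect_equal(forward_loglik(model, X), oracle_forward_loglik(model, X),
                 tolerance = 1e-10)
  }
})

test_that("forward recursion base case is the weighted emission density", {
  model <- random_hmm(3, 2, 2, 99)
  x <- matrix(rnorm(2), 1, 2)
  direct <- log(sum(vapply(1:3, function(s)
    model$pi[s] * oracle_mix_density(x[1, ], model$states[[s]]), 0)))
  expect_equal(forward_loglik(model, x), direct, tolerance = 1e-10)
  expect_error(forward_loglik(model, matrix(0, 2, 5)),
               class = "voicelevel_dimension_error")
})

test_that("splitting a state's probability leaves the likelihood unchanged", {
  m1 <- random_hmm(1, 1, 2, 7)
  # duplicate the single state, splitting initial and transition mass
  m2 <- make_hmm(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                 means = list(m1$states[[1]]$mu, m1$states[[1]]$mu),
                 vars = list(m1$states[[1]]$var, m1$states[[1]]$var))
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(forward_loglik(m2, X), forward_loglik(m1, X), tolerance = 1e-10)
})

test_that("uniform-segmentation k-means init is deterministic and sane", {
  set.seed(1)
  seqs <- list(rbind(matrix(rnorm(500, 0), 500, 1),
                     matrix(rnorm(500, 10), 500, 1)))
  m <- init_hmm(seqs, n_states = 2, n_mix = 1, seed = 5)
  mus <- sort(vapply(m$states, function(s) s$mu[1, 1], 0))
  expect_equal(mus, c(0, 10), tolerance = 0.5)
  m2 <- init_hmm(seqs, n_states = 2, n_mix = 1, seed = 5)
  expect_identical(m, m2)
  expect_error(init_hmm(list(matrix(rnorm(10), 5, 2)), 8, 4, 1),
               class = "voicelevel_init_error")
})

test_that("Baum-Welch increases likelihood and preserves the topology", {
  set.seed(3)
  true <- make_hmm(pi = c(1, 0), A = rbind(c(0.8, 0.2), c(0, 1)),
                   means = list(matrix(c(0, 0), 1), matrix(c(3, 3), 1)),
                   vars = list(matrix(1, 1, 2), matrix(1, 1, 2)))
  seqs <- lapply(1:10, function(i) simulate_hmm(true, 40, seed = i))
  m0 <- init_hmm(seqs, n_states = 2, n_mix = 2, seed = 2)
  m <- train_em(m0, seqs, max_iter = 25)
  expect_true(all(diff(m$loglik_trace) > -1e-8))
  expect_true(all(abs(rowSums(m$A) - 1) < 1e-9))
  expect_true(all(m$A[lower.tri(m$A)] == 0))
  expect_equal(m$pi, c(1, 0))
  for (s in m$states) {
    expect_true(all(s$var >= m$var_floor - 1e-12))
    expect_equal(sum(s$w), 1, tolerance = 1e-9)
  }
})

test_that("EM recovers a known 3-state left-right generator", {
  # dwell times ~ T/3 per state so the temporal segmentation is informative
  A_true <- rbind(c(0.97, 0.03, 0), c(0, 0.97, 0.03), c(0, 0, 1))
  true <- make_hmm(pi = c(1, 0, 0), A = A_true,
                   means = list(matrix(c(-3, 0), 1), matrix(c(0, 3), 1),
                                matrix(c(3, -3), 1)),
                   vars = list(matrix(1, 1, 2), matrix(1, 1, 2),
                               matrix(1, 1, 2)))
  train <- lapply(1:50, function(i) simulate_hmm(true, 100, seed = 100 + i))
  test <- lapply(1:20, function(i) simulate_hmm(true, 100, seed = 900 + i))
  m <- train_em(init_hmm(train, 3, 1, seed = 4), train, max_iter = 40)
  # left-right order makes the state alignment the identity; check means
  mu_hat <- t(vapply(m$states, function(s) s$mu[1, ], numeric(2)))
  mu_true <- rbind(c(-3, 0), c(0, 3), c(3, -3))
  expect_lt(max(abs(mu_hat - mu_true)), 0.5)
  expect_lt(max(abs(m$A - A_true)), 0.1)
  ll_hat <- mean(vapply(test, forward_loglik, 0, model = m))
  ll_true <- mean(vapply(test, forward_loglik, 0, model = true))
  expect_lt(abs(ll_hat - ll_true) / abs(ll_true), 0.02)
})

test_that("variance flooring survives constant features", {
  seqs <- list(cbind(rnorm(200), rep(1, 200)))
  m <- train_em(init_hmm(seqs, 2, 2, seed = 1), seqs, max_iter = 5)
  for (s in m$states) expect_true(all(s$var >= m$var_floor - 1e-12))
})

test_that("word classification takes the argmax level, ties to the lower", {
  models <- lapply(1:4, function(l) random_hmm(2, 1, 2, 50 + l))
  X <- matrix(rnorm(12), 6, 2)
  cls <- classify_word(models, X)
  expect_equal(cls$level, which.max(cls$logliks))
  # exact tie between level 1 and 3 (identical models)
  models_tie <- models
  models_tie[[3]] <- models_tie[[1]]
  ll <- vapply(models_tie, forward_loglik, 0, seq = X)
  if (which.max(ll) %in% c(1, 3)) {
    expect_equal(classify_word(models_tie, X)$level, min(which(ll == max(ll))))
  }
})

test_that("well-separated generators are classified correctly", {
  gen <- lapply(1:4, function(l)
    make_hmm(pi = c(1, 0), A = rbind(c(0.9, 0.1), c(0, 1)),
             means = list(matrix(c(3 * l, 0), 1), matrix(c(0, 3 * l), 1)),
             vars = list(matrix(1, 1, 2), matrix(1, 1, 2))))
  fitted <- lapply(1:4, function(l) {
    seqs <- lapply(1:15, function(i) simulate_hmm(gen[[l]], 30, 1000 * l + i))
    train_em(init_hmm(seqs, 2, 1, seed = l), seqs, max_iter = 15)
  })
  correct <- 0; total <- 0
  for (l in 1:4) for (i in 1:50) {
    X <- simulate_hmm(gen[[l]], 30, seed = 5000 + 100 * l + i)
    total <- total + 1
    if (classify_word(fitted, X)$level == l) correct <- correct + 1
  }
  expect_gte(correct / total, 0.9)
})
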