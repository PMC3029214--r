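fake_manifest <- function(n_children = c(2, 2, 2, 4), reps = 5,
                          words = vl_words) {
  rows <- expand.grid(word = words, repetition = seq_len(reps),
                      stringsAsFactors = FALSE)
  out <- NULL
  for (lev in 1:4) for (ci in seq_len(n_children[lev])) {
    r <- rows
    r$child_id <- sprintf("L%d_C%d", lev, ci)
    r$level <- lev
    out <- rbind(out, r)
  }
  out
}

test_that("60/40 splits are exact, disjoint and stratified", {
  man <- fake_manifest()
  sp <- make_splits(man, train_frac = 0.6, n_reps = 4, seed = 2)
  for (plan in sp) {
    expect_equal(length(plan$train1), round(0.6 * nrow(man)))
    expect_equal(length(plan$test1), nrow(man) - length(plan$train1))
    expect_length(intersect(plan$train1, plan$test1), 0)
    expect_setequal(c(plan$train1, plan$test1), seq_len(nrow(man)))
    tr <- man[plan$train1, ]
    expect_true(all(table(tr$word, tr$level) >= 1))
  }
})

test_that("splits are deterministic in the seed and vary across reps", {
  man <- fake_manifest()
  a <- make_splits(man, n_reps = 3, seed = 9)
  b <- make_splits(man, n_reps = 3, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$train1, a[[2]]$train1))
})

test_that("stacked mode partitions test1 into whole trials", {
  man <- fake_manifest()
  sp <- make_splits(man, n_reps = 2, stacked = TRUE, seed = 3)
  for (plan in sp) {
    expect_setequal(c(plan$train2, plan$test2), plan$test1)
    expect_length(intersect(plan$train2, plan$test2), 0)
    key <- paste(man$child_id, man$repetition)
    expect_length(intersect(key[plan$train2], key[plan$test2]), 0)
  }
})

test_that("child-disjoint mode keeps children on one side", {
  man <- fake_manifest(n_children = c(4, 4, 4, 6))
  sp <- make_splits(man, n_reps = 2, seed = 4, mode = "child")
  for (plan in sp)
    expect_length(intersect(man$child_id[plan$train1],
                            man$child_id[plan$test1]), 0)
})

test_that("an empty (word, level) cell raises a stratification error", {
  man <- fake_manifest()
  man <- man[!(man$word == "gav" & man$level == 2), ]
  expect_error(make_splits(man, n_reps = 1, seed = 1),
               class = "voicelevel_stratification_error")
})

test_that("per-level accuracy handles perfect and degenerate classifiers", {
  truth <- rep(1:4, each = 10)
  expect_equal(voicelevel:::per_level_accuracy(truth, truth),
               rep(100, 4))
  always1 <- rep(1L, 40)
  expect_equal(voicelevel:::per_level_accuracy(truth, always1),
               c(100, 0, 0, 0))
})

test_that("accuracy estimation is unbiased for a known error rate", {
  set.seed(80)
  p <- 0.65
  est <- replicate(400, {
    truth <- sample(1:4, 50, replace = TRUE)
    pred <- ifelse(runif(50) < p, truth, (truth %% 4) + 1L)
    mean(voicelevel:::per_level_accuracy(truth, pred), na.rm = TRUE)
  })
  expect_equal(mean(est), 100 * p, tolerance = 0.02)
})

test_that("reports flag sub-50% levels as not classified", {
  acc <- array(0, c(2, 2, 4), dimnames = list(NULL, c("mar", "mvr"),
                                              paste0("L", 1:4)))
  acc[, 1, ] <- c(90, 90, 45, 45, 100, 100, 30, 30)
  acc[, 2, ] <- 80
  rep_ <- structure(list(acc = acc, mean_acc = apply(acc, c(2, 3), mean),
                         not_classified = apply(acc, c(2, 3), mean) < 50,
                         n_reps = 2, rules = "mvr", words = "mar"),
                    class = "accuracy_report")
  expect_true(rep_$not_classified["mar", "L2"])
  expect_false(rep_$not_classified["mar", "L1"])
  txt <- capture.output(print(rep_))
  expect_true(any(grepl("nc", txt)))
  expect_output(print(rep_), "not classified")
})

test_that("the full evaluation loop runs on a small featurized corpus", {
  feats <- small_features()
  man <- attr(feats, "manifest")
  sp <- make_splits(man, n_reps = 2, stacked = TRUE, seed = 6)
  rep_ <- evaluate_grader(feats, sp, rules = c("mvr", "linear", "stacked"),
                          seed = 1, n_states = 4, n_mix = 2, max_iter = 10,
                          mlp_epochs = 300)
  expect_s3_class(rep_, "accuracy_report")
  expect_equal(dim(rep_$acc), c(2, 5 + 1 + 3, 4))
  expect_true(all(rep_$mean_acc >= 0 & rep_$mean_acc <= 100, na.rm = TRUE))
  means <- report_means(rep_)
  expect_named(means$fused, c("mvr", "linear", "stacked"))
  # same inputs, same report
  rep2 <- evaluate_grader(feats, sp, rules = c("mvr", "linear", "stacked"),
                          seed = 1, n_states = 4, n_mix = 2, max_iter = 10,
                          mlp_epochs = 300)
  expect_equal(rep_$mean_acc, rep2$mean_acc)
})
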