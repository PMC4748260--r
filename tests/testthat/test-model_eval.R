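make_separable <- function(n_per_class = 10, len = 20) {
  orn_dataset(stats::setNames(rep(strrep("A", len), n_per_class),
                              paste0("p", seq_len(n_per_class))),
              stats::setNames(rep(strrep("G", len), n_per_class),
                              paste0("n", seq_len(n_per_class))))
}

test_that("metrics match the closed-form confusion formulas", {
  lc <- labels_from_counts(tp = 40, fp = 10, tn = 30, fn = 20)
  m <- compute_metrics(lc$truth, lc$pred)
  expect_equal(m$sensitivity, 100 * 40 / 60)
  expect_equal(m$specificity, 75)
  expect_equal(m$accuracy, 70)
  expect_equal(m$mcc, 1000 / sqrt(50 * 60 * 40 * 50))

  perfect <- compute_metrics(rep(c(1, -1), each = 5), rep(c(1, -1), each = 5))
  expect_equal(metrics_vals <- c(perfect$sensitivity, perfect$specificity,
                                 perfect$accuracy, perfect$mcc),
               c(100, 100, 100, 1))
  # degenerate: everything called positive
  allpos <- compute_metrics(rep(c(1, -1), each = 5), rep(1, 10))
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$mcc, 0)
  expect_error(compute_metrics(c(1, -1), c(1)), "equal length")
})

test_that("MCC equals the closed form on random confusion tables", {
  set.seed(99)
  for (i in 1:200) {
    cnt <- as.list(stats::setNames(sample(0:25, 4, replace = TRUE),
                                   c("tp", "fp", "tn", "fn")))
    if (sum(unlist(cnt)) == 0) next
    lc <- do.call(labels_from_counts, cnt)
    m <- compute_metrics(lc$truth, lc$pred)
    expect_equal(m$mcc, do.call(mcc_closed_form, cnt))
  }
})

test_that("threshold classification is monotone with positive ties", {
  expect_identical(classify_at_threshold(c(0.5, -0.2)), c(1L, -1L))
  expect_identical(classify_at_threshold(0, 0), 1L)
  expect_identical(classify_at_threshold(c(1, 2, 3), 1e6), rep(-1L, 3))
  set.seed(5)
  scores <- rnorm(50)
  prev <- classify_at_threshold(scores, -Inf)
  for (t in sort(c(scores, 0))) {
    cur <- classify_at_threshold(scores, t)
    expect_true(all(cur <= prev))  # raising t never flips -1 to +1
    prev <- cur
  }
})

test_that("training requires two classes and scores separable data correctly", {
  ds <- make_separable(5)
  fit <- imorn_fit(ds, feature_spec("MNC"))
  expect_identical(unname(predict(fit, ds)), ds$label)
  s <- decision_scores(fit, ds)
  expect_true(all(s[ds$label == 1] > 0) && all(s[ds$label == -1] < 0))
  # duplicated row scores identically
  X <- encode_sequences(ds, feature_spec("MNC"))
  s2 <- decision_scores(fit, X[c(1, 1), , drop = FALSE])
  expect_equal(s2[[1]], s2[[2]])
  expect_error(decision_scores(fit, X[, 1:3]), "width mismatch")
  one_class <- orn_dataset(c(a = "AAAA", b = "AAAC"), character(0))
  expect_error(imorn_fit(one_class, feature_spec("MNC")), "both classes")
  expect_error(imorn_fit(matrix(numeric(0), 0, 4), feature_spec("MNC"),
                         labels = integer(0)), "empty")
})

test_that("linear coefficients reproduce decision scores", {
  ds <- generate_dataset(synthetic_spec(n_pos = 30, n_neg = 30, seed = 2))
  fit <- imorn_fit(ds, feature_spec("MNC"))
  w <- coef(fit)
  X <- encode_sequences(ds, feature_spec("MNC"))
  manual <- drop(X %*% w) + attr(w, "intercept")
  expect_equal(unname(manual), unname(decision_scores(fit, X)), tolerance = 1e-8)
  rbf <- imorn_fit(ds, feature_spec("MNC"), kernel = "radial")
  expect_error(coef(rbf), "linear")
})

test_that("five-fold CV pools held-out predictions and stratifies folds", {
  ds <- make_separable(10)
  m <- five_fold_cv(ds, feature_spec("MNC"), seed = 1)
  expect_equal(m$accuracy, 100)
  fold <- attr(m, "fold")
  for (cl in c(1L, -1L)) {
    sizes <- table(fold[ds$label == cl])
    expect_length(sizes, 5L)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_error(five_fold_cv(make_separable(4), feature_spec("MNC")), "at least 5")
})

test_that("CV under label permutation is near chance", {
  ds <- generate_dataset(synthetic_spec(n_pos = 50, n_neg = 50, seed = 8))
  set.seed(31)
  mccs <- replicate(8, {
    shuffled <- ds
    shuffled$label <- sample(ds$label)
    five_fold_cv(shuffled, feature_spec("MNC"), seed = sample.int(1e6, 1))$mcc
  })
  expect_lt(mean(abs(mccs)), 0.35)
})

test_that("Monte-Carlo split reproduces per-class sizes, disjoint and exhaustive", {
  ds <- generate_dataset(synthetic_spec(n_pos = 41, n_neg = 29, seed = 4))
  for (seed in 1:25) {
    sp <- monte_carlo_split(ds, 0.8, seed = seed)
    expect_equal(sum(sp$train$label == 1), round(0.8 * 41))
    expect_equal(sum(sp$train$label == -1), round(0.8 * 29))
    expect_length(intersect(sp$train$id, sp$independent$id), 0L)
    expect_setequal(c(sp$train$id, sp$independent$id), ds$id)
  }
  sp1 <- monte_carlo_split(ds, seed = 7)
  sp2 <- monte_carlo_split(ds, seed = 7)
  expect_identical(sp1$train$id, sp2$train$id)
  tiny <- orn_dataset(c(a = "AAAA"), c(b = "GGGG"))
  expect_error(monte_carlo_split(tiny, 0.8), "empty side")
})

test_that("grid search is exhaustive with documented tie-breaking", {
  ds <- make_separable(8)
  one <- grid_search(ds, feature_spec("MNC"),
                     grid = data.frame(kernel = "linear", cost = 2), seed = 1)
  expect_identical(one$cost, 2)
  # identical settings listed twice: first in grid wins
  dup <- grid_search(ds, feature_spec("MNC"),
                     grid = data.frame(kernel = "linear", cost = c(1, 1)), seed = 1)
  expect_identical(dup$table$mcc[1], dup$table$mcc[2])
  expect_identical(dup$cost, 1)
  expect_error(grid_search(ds, feature_spec("MNC"),
                           grid = data.frame()), "empty")
})

test_that("sampling protocol reports per-round and summary statistics", {
  ds <- generate_dataset(synthetic_spec(n_pos = 40, n_neg = 40, seed = 6))
  rep1 <- sampling_protocol(ds, feature_spec("MNC"), n_rounds = 1, base_seed = 3)
  expect_identical(nrow(rep1$internal), 1L)
  expect_identical(nrow(rep1$external), 1L)
  # one round: summary mean is the round value, sd is NA-free single obs
  expect_equal(rep1$summary$internal$mean[3], rep1$internal$accuracy[1])
  rep3 <- sampling_protocol(ds, feature_spec("MNC"), n_rounds = 3, base_seed = 3)
  expect_equal(rep3$summary$external$mean[3], mean(rep3$external$accuracy))
  expect_equal(rep3$summary$external$sd[3], sd(rep3$external$accuracy))
})

test_that("feature selection ranks by |t| with deterministic ties", {
  set.seed(12)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- rep(c(1L, -1L), each = 30)
  X[, 5] <- X[, 5] + 3 * y  # single strongly separating feature
  expect_identical(feature_selection(X, y, 1), 5L)
  expect_setequal(feature_selection(X, y, 8), 1:8)
  # duplicated column ties broken by lower index
  X2 <- cbind(X[, 5], X[, 5], X[, 1:2])
  expect_identical(feature_selection(X2, y, 2), c(1L, 2L))
  expect_error(feature_selection(X, y, 0), "m must be")
  expect_error(feature_selection(X, y, 9), "m must be")
})
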