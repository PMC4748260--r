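# Evaluation protocols: stratified five-fold cross-validation with pooled
# held-out metrics, Monte-Carlo 80/20 train-test vs independent splits, the
# repeated (10-round) sampling scheme with mean +/- sd reporting, grid search
# over SVM settings, and a t-statistic filter for feature selection.

#' Stratified five-fold cross-validation
#'
#' Partitions each class into five folds (sizes differing by at most one per
#' class), trains on four folds and scores the held-out fold, then pools all
#' held-out predictions and computes one set of metrics over the whole
#' dataset.
#'
#' @param ds An [orn_dataset()] with at least `folds` records per class.
#' @param spec A [feature_spec()].
#' @param kernel,cost,gamma,degree,threshold Passed to [imorn_fit()].
#' @param seed Integer seed governing the fold assignment.
#' @param folds Number of folds (default 5).
#' @return An `imorn_metrics` object over the pooled held-out predictions,
#'   with the per-fold assignment in `attr(, "fold")`.
#' @export
five_fold_cv <- function(ds, spec = feature_spec("PNC"),
                         kernel = "linear", cost = 1, gamma = NULL, degree = 3,
                         threshold = 0, seed = 1L, folds = 5L) {
  stopifnot(inherits(ds, "orn_dataset"))
  n_pos <- sum(ds$label == 1L); n_neg <- sum(ds$label == -1L)
  if (n_pos < folds || n_neg < folds)
    stop(sprintf("each class needs at least %d records for %d-fold CV", folds, folds),
         call. = FALSE)
  X <- encode_sequences(ds, spec)
  y <- ds$label
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in c(1L, -1L)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  pred <- integer(length(y))
  for (f in seq_len(folds)) {
    hold <- fold == f
    fit <- imorn_fit(X[!hold, , drop = FALSE], spec = spec, kernel = kernel,
                     cost = cost, gamma = gamma, degree = degree,
                     threshold = threshold, labels = y[!hold])
    pred[hold] <- classify_at_threshold(decision_scores(fit, X[hold, , drop = FALSE]),
                                        threshold)
  }
  m <- compute_metrics(y, pred, threshold)
  attr(m, "fold") <- fold
  m
}

#' Monte-Carlo 80/20 split into train-test and independent sets
#'
#' Draws, per class, `round(train_fraction * n)` records without replacement
#' into the train-test set; the remainder forms the independent set. With the
#' default fraction 0.8 a 602/520 dataset yields 482/416 train-test records
#' per class. The two sets are disjoint and together exhaust the dataset.
#'
#' @param ds An [orn_dataset()] with both classes non-empty.
#' @param train_fraction Fraction per class assigned to train-test (default 0.8).
#' @param seed Integer seed for the draw.
#' @return List with elements `train` and `independent`, both [orn_dataset()]s.
#' @export
monte_carlo_split <- function(ds, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "orn_dataset"),
            train_fraction > 0, train_fraction < 1)
  take <- logical(length(ds$label))
  with_seed(seed, {
    for (cl in c(1L, -1L)) {
      idx <- which(ds$label == cl)
      n_take <- round(train_fraction * length(idx))
      if (n_take < 1L || n_take >= length(idx))
        stop(sprintf("train fraction %g leaves an empty side for class %+d",
                     train_fraction, cl), call. = FALSE)
      take[sample(idx, n_take)] <- TRUE
    }
  })
  subset_ds <- function(keep, tag) {
    structure(list(id = ds$id[keep], seq = ds$seq[keep], label = ds$label[keep],
                   name = paste0(ds$name, "_", tag)),
              class = "orn_dataset")
  }
  list(train = subset_ds(take, "train"), independent = subset_ds(!take, "independent"))
}

#' Default SVM hyperparameter grid
#'
#' Linear kernel with C in {0.1, 1, 10} and RBF kernel with the same costs
#' crossed with gamma in {0.01, 0.1, 1}.
#'
#' @return Data frame with columns `kernel`, `cost`, `gamma`.
#' @export
default_grid <- function() {
  rbind(data.frame(kernel = "linear", cost = c(0.1, 1, 10), gamma = NA_real_),
        expand.grid(kernel = "radial", cost = c(0.1, 1, 10),
                    gamma = c(0.01, 0.1, 1), stringsAsFactors = FALSE))
}

#' Exhaustive grid search by internal cross-validation MCC
#'
#' Evaluates every grid row with [five_fold_cv()] and returns the setting with
#' the highest MCC; ties are broken by higher accuracy, then by first position
#' in the grid.
#'
#' @param ds An [orn_dataset()].
#' @param spec A [feature_spec()].
#' @param grid Data frame with columns `kernel`, `cost` and optionally `gamma`
#'   (ignored for the linear kernel); default [default_grid()].
#' @param seed Seed used for every CV fold assignment (shared across settings
#'   so they see identical folds).
#' @return List with `kernel`, `cost`, `gamma`, `metrics` (the winning CV
#'   metrics) and `table` (per-setting CV results).
#' @export
grid_search <- function(ds, spec = feature_spec("PNC"), grid = default_grid(),
                        seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  if (is.null(grid$gamma)) grid$gamma <- NA_real_
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- if (is.na(grid$gamma[i])) NULL else grid$gamma[i]
    five_fold_cv(ds, spec, kernel = grid$kernel[i], cost = grid$cost[i],
                 gamma = g, seed = seed)
  })
  tab <- cbind(grid, t(vapply(res, metrics_row, numeric(4))))
  best <- order(-tab$mcc, -tab$accuracy, seq_len(nrow(tab)))[1L]
  list(kernel = grid$kernel[best], cost = grid$cost[best],
       gamma = if (is.na(grid$gamma[best])) NULL else grid$gamma[best],
       metrics = res[[best]], table = tab)
}

#' Repeated Monte-Carlo sampling protocol
#'
#' Repeats the 80/20 split `n_rounds` times (default 10). In each round the
#' train-test set is evaluated by internal five-fold cross-validation, and a
#' model trained on the full train-test set is evaluated on the independent
#' set (external validation). Per-round metrics and their mean and standard
#' deviation are reported for both settings.
#'
#' @inheritParams five_fold_cv
#' @param train_fraction Per-class train-test fraction (default 0.8).
#' @param n_rounds Number of sampling rounds (default 10).
#' @param base_seed Round `r` uses seed `base_seed + r`.
#' @return An object of class `sampling_report`: list with data frames
#'   `internal` and `external` (one row per round) and `summary` (mean and sd
#'   of each metric in each setting).
#' @export
sampling_protocol <- function(ds, spec = feature_spec("PNC"),
                              kernel = "linear", cost = 1, gamma = NULL,
                              degree = 3, threshold = 0,
                              train_fraction = 0.8, n_rounds = 10L,
                              base_seed = 1L) {
  stopifnot(n_rounds >= 1L)
  internal <- external <- matrix(NA_real_, n_rounds, 4,
                                 dimnames = list(NULL, c("sensitivity", "specificity",
                                                         "accuracy", "mcc")))
  for (r in seq_len(n_rounds)) {
    sp <- monte_carlo_split(ds, train_fraction, seed = base_seed + r)
    internal[r, ] <- metrics_row(
      five_fold_cv(sp$train, spec, kernel = kernel, cost = cost, gamma = gamma,
                   degree = degree, threshold = threshold, seed = base_seed + r))
    fit <- imorn_fit(sp$train, spec, kernel = kernel, cost = cost, gamma = gamma,
                     degree = degree, threshold = threshold)
    pred <- predict(fit, sp$independent)
    external[r, ] <- metrics_row(compute_metrics(sp$independent$label, pred, threshold))
  }
  summarise <- function(m) {
    data.frame(metric = colnames(m), mean = colMeans(m),
               sd = apply(m, 2, stats::sd), row.names = NULL)
  }
  structure(list(internal = data.frame(round = seq_len(n_rounds), internal),
                 external = data.frame(round = seq_len(n_rounds), external),
                 summary = list(internal = summarise(internal),
                                external = summarise(external)),
                 n_rounds = n_rounds, encoding = spec$encoding, kernel = kernel),
            class = "sampling_report")
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf("sampling_report: %d rounds, %s features, %s kernel\n",
              x$n_rounds, x$encoding, x$kernel))
  fmt <- function(s) paste(sprintf("%s %.2f ± %.2f", substr(s$metric, 1, 4),
                                   s$mean, s$sd), collapse = "  ")
  cat("  internal:", fmt(x$summary$internal), "\n")
  cat("  external:", fmt(x$summary$external), "\n")
  invisible(x)
}

#' Filter feature selection by two-sample t statistic
#'
#' Ranks features by the absolute pooled-variance two-sample t statistic
#' between classes and returns the indices of the top `m`; ties are broken by
#' lower index. A feature with zero pooled variance scores infinity when the
#' class means differ and 0 when they are equal.
#'
#' @param X Numeric feature matrix.
#' @param y +1/-1 label vector of length `nrow(X)`.
#' @param m Number of features to keep, between 1 and `ncol(X)`.
#' @return Integer vector of the selected column indices, best first.
#' @export
feature_selection <- function(X, y, m) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (m < 1L || m > ncol(X))
    stop(sprintf("m must be in 1..%d", ncol(X)), call. = FALSE)
  t_abs <- abs(pooled_t_statistic(X[y == 1L, , drop = FALSE],
                                  X[y == -1L, , drop = FALSE])$t)
  order(-t_abs, seq_len(ncol(X)))[seq_len(m)]
}

# Vectorised pooled-variance two-sample t statistic per column, with the
# degenerate zero-variance convention used throughout the package:
# sp == 0 -> t = +/-Inf (p = 0) when means differ, t = 0 (p = 1) when equal.
pooled_t_statistic <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2L || n2 < 2L)
    stop("each class needs at least 2 observations for a t test", call. = FALSE)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  t <- ifelse(se > 0, (m1 - m2) / se,
              ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  p[se == 0 & m1 == m2] <- 1
  list(t = t, p = p, df = df, mean1 = m1, mean2 = m2)
}
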