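# SVM classifier for IMORN vs non-IMORN oligonucleotides.
#
# The fitted object pairs a libsvm model (via e1071) with the feature_spec it
# was trained under, so prediction always re-encodes raw sequences the same
# way. Decision scores are oriented so that larger means more IMORN-like, and
# classification applies a fixed score threshold (default 0, ties positive).

#' Fit an immunomodulatory-RNA classifier
#'
#' Trains a support vector machine on the encoded sequences of a labelled
#' dataset. The feature encoding is fixed at training time and enforced at
#' prediction time.
#'
#' @param ds An [orn_dataset()] with both classes present, or a numeric
#'   feature matrix (then `labels` must be given and `spec` describes how the
#'   matrix was produced).
#' @param spec A [feature_spec()]; default pentanucleotide composition.
#' @param kernel `"linear"`, `"radial"` or `"polynomial"`.
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF/polynomial kernel width; default `1/ncol(X)`.
#' @param degree Polynomial degree (default 3).
#' @param threshold Decision-score threshold for classification (default 0;
#'   a score exactly equal to the threshold is called positive).
#' @param labels Optional +1/-1 vector when `ds` is a matrix.
#' @return An object of class `imorn_fit` with `print`, `summary`, `coef` and
#'   `predict` methods.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_pos = 30, n_neg = 30, seed = 1))
#' fit <- imorn_fit(ds, feature_spec("TNC"))
#' predict(fit, dataset_class(ds, 1)[1:3])
#' @export
imorn_fit <- function(ds, spec = feature_spec("PNC"),
                      kernel = c("linear", "radial", "polynomial"),
                      cost = 1, gamma = NULL, degree = 3, threshold = 0,
                      labels = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(is.finite(threshold))
  if (inherits(ds, "orn_dataset")) {
    X <- encode_sequences(ds, spec)
    y <- ds$label
  } else if (is.matrix(ds)) {
    X <- ds
    y <- labels
    if (is.null(y)) stop("labels required when fitting on a matrix", call. = FALSE)
  } else stop("ds must be an orn_dataset or a feature matrix", call. = FALSE)
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  y <- as.integer(y)
  if (!all(y %in% c(1L, -1L))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training requires both classes to be present", call. = FALSE)
  gamma <- gamma %||% (1 / ncol(X))
  yf <- factor(y, levels = c(1L, -1L))
  svm <- e1071::svm(x = X, y = yf, kernel = kernel, cost = cost, gamma = gamma,
                    degree = degree, scale = FALSE)
  fit <- structure(list(svm = svm, spec = spec, kernel = kernel,
                        hyperparameters = list(cost = cost, gamma = gamma,
                                               degree = if (kernel == "polynomial") degree),
                        threshold = threshold, n_train = nrow(X),
                        class_sizes = c(pos = sum(y == 1L), neg = sum(y == -1L)),
                        orientation = 1),
                   class = "imorn_fit")
  # libsvm orders decision values by first-seen label; orient so that
  # positive score always means the IMORN class
  dv <- attr(stats::predict(svm, X[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  if (identical(colnames(dv), "-1/1")) fit$orientation <- -1
  fit
}

#' Decision scores of a fitted classifier
#'
#' @param fit An [imorn_fit()] object.
#' @param newdata Named character vector of sequences, an [orn_dataset()], or
#'   a numeric matrix already encoded under the fit's feature spec.
#' @return Named numeric vector of signed decision scores (positive =
#'   IMORN-like).
#' @export
decision_scores <- function(fit, newdata) {
  stopifnot(inherits(fit, "imorn_fit"))
  X <- if (is.matrix(newdata)) newdata else encode_sequences(newdata, fit$spec)
  p <- spec_length(fit$spec)
  if (ncol(X) != p)
    stop(sprintf("feature width mismatch: model expects %d columns, got %d",
                 p, ncol(X)), call. = FALSE)
  if (nrow(X) == 0L) return(stats::setNames(numeric(0), character(0)))
  dv <- attr(stats::predict(fit$svm, X, decision.values = TRUE), "decision.values")
  stats::setNames(fit$orientation * as.numeric(dv), rownames(X))
}

#' Classify decision scores at a threshold
#'
#' A score greater than or equal to the threshold is called positive (+1);
#' ties at the threshold are positive by convention.
#'
#' @param scores Numeric vector of finite decision scores.
#' @param threshold Score cut-off (default 0).
#' @return Integer vector of +1/-1 labels.
#' @export
classify_at_threshold <- function(scores, threshold = 0) {
  stopifnot(all(is.finite(scores)))
  ifelse(scores >= threshold, 1L, -1L)
}

#' @export
predict.imorn_fit <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- decision_scores(object, newdata)
  if (type == "score") s else
    stats::setNames(classify_at_threshold(s, object$threshold), names(s))
}

#' @export
print.imorn_fit <- function(x, ...) {
  cat(sprintf("imorn_fit: %s kernel SVM on %s features (%d)\n",
              x$kernel, x$spec$encoding, spec_length(x$spec)))
  cat(sprintf("  trained on %d sequences (%d positive / %d negative); threshold %g\n",
              x$n_train, x$class_sizes[["pos"]], x$class_sizes[["neg"]],
              x$threshold))
  invisible(x)
}

#' @export
summary.imorn_fit <- function(object, ...) {
  hp <- object$hyperparameters
  cat(sprintf("Immunomodulatory-RNA SVM classifier\n"))
  print(object)
  cat(sprintf("  cost C = %g%s; support vectors: %d\n", hp$cost,
              if (object$kernel != "linear") sprintf(", gamma = %g", hp$gamma) else "",
              nrow(object$svm$SV)))
  invisible(object)
}

#' Linear-kernel feature weights
#'
#' For a linear kernel the decision score is `w . x + b`; this returns the
#' weight vector `w` (named by feature) with the intercept `b` as attribute
#' `"intercept"`. Positive weights pull toward the IMORN class.
#'
#' @param object A linear-kernel [imorn_fit()].
#' @param ... Unused.
#' @return Named numeric weight vector.
#' @export
coef.imorn_fit <- function(object, ...) {
  if (object$kernel != "linear")
    stop("coefficients are only defined for the linear kernel", call. = FALSE)
  w <- drop(crossprod(object$svm$coefs, object$svm$SV)) * object$orientation
  attr(w, "intercept") <- -object$svm$rho * object$orientation
  w
}

#' Confusion counts and threshold performance metrics
#'
#' Computes sensitivity, specificity and accuracy (as percentages) and the
#' Matthews correlation coefficient from true and predicted +1/-1 labels.
#' When any factor of the MCC denominator is zero the MCC is defined as 0.
#'
#' @param y_true,y_pred Equal-length vectors of +1/-1 labels.
#' @param threshold Optional threshold recorded alongside the metrics.
#' @return An object of class `imorn_metrics`: list with `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`, `mcc`, `threshold`.
#' @examples
#' compute_metrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' @export
compute_metrics <- function(y_true, y_pred, threshold = 0) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% c(1L, -1L)), all(y_pred %in% c(1L, -1L)))
  tp <- sum(y_true == 1L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == -1L)
  tn <- sum(y_true == -1L & y_pred == -1L)
  fp <- sum(y_true == -1L & y_pred == 1L)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / length(y_true)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 mcc = mcc, threshold = threshold),
            class = "imorn_metrics")
}

#' @export
print.imorn_metrics <- function(x, ...) {
  cat(sprintf("n = %d (tp %d, fp %d, tn %d, fn %d)\n",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("Sen %.2f%%  Spec %.2f%%  Acc %.2f%%  MCC %.3f  (threshold %g)\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc, x$threshold))
  invisible(x)
}

metrics_row <- function(m) {
  c(sensitivity = m$sensitivity, specificity = m$specificity,
    accuracy = m$accuracy, mcc = m$mcc)
}
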