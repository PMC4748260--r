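# Versioned model bundles: the fitted classifier serialized as RDS plus a
# JSON sidecar describing the feature spec, kernel, hyperparameters and
# threshold, so a bundle is self-describing without loading the payload.

BUNDLE_FORMAT <- 1L

#' Save a fitted classifier as a model bundle
#'
#' Writes `path` (RDS payload) and `path.json` (sidecar with format version,
#' feature spec, kernel, hyperparameters, threshold and training metadata).
#'
#' @param fit An [imorn_fit()].
#' @param path Output path for the RDS payload.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "imorn_fit"))
  saveRDS(fit, path)
  sidecar <- list(format = BUNDLE_FORMAT,
                  package_version = as.character(utils::packageVersion("imorn")),
                  encoding = fit$spec$encoding, window = fit$spec$window,
                  n_features = spec_length(fit$spec),
                  kernel = fit$kernel, hyperparameters = fit$hyperparameters,
                  threshold = fit$threshold,
                  n_train = fit$n_train, class_sizes = as.list(fit$class_sizes))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model bundle
#'
#' Verifies the sidecar's format version and that it matches the payload's
#' feature spec before returning the fitted classifier.
#'
#' @param path Path given to [save_model()].
#' @return An [imorn_fit()].
#' @export
load_model <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop(sprintf("model bundle not found: %s", path), call. = FALSE)
  fit <- readRDS(path)
  if (!inherits(fit, "imorn_fit")) stop("bundle payload is not an imorn_fit", call. = FALSE)
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (is.null(sc$format) || sc$format != BUNDLE_FORMAT)
      stop(sprintf("unsupported bundle format version: %s", sc$format %||% "missing"),
           call. = FALSE)
    if (!identical(sc$encoding, fit$spec$encoding))
      stop("bundle sidecar does not match payload feature spec", call. = FALSE)
  }
  fit
}
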