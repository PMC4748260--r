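# Fixed-length numeric encodings of variable-length oligonucleotides.
#
# Composition encodings (MNC/DNC/TNC/TetNC/PNC, k = 1..5) are overlapping
# k-mer frequencies: 4^k values summing to 1. Binary encodings one-hot encode
# a fixed window of terminal residues (A=1000, C=0100, G=0010, U=0001):
# BIN5/BIN3 use the first/last `window` positions (4*window values), BIN53
# concatenates both (8*window), and HYBRID is TNC followed by BIN53
# (64 + 8*window = 200 at the default window of 17).

RNA_ALPHABET <- c("A", "C", "G", "U")

COMPOSITION_K <- c(MNC = 1L, DNC = 2L, TNC = 3L, TetNC = 4L, PNC = 5L)

#' Describe a feature encoding
#'
#' @param encoding One of `"MNC"`, `"DNC"`, `"TNC"`, `"TetNC"`, `"PNC"`
#'   (k-mer composition, k = 1..5), `"BIN5"`, `"BIN3"`, `"BIN53"` (terminal
#'   one-hot profiles) or `"HYBRID"` (TNC + BIN53).
#' @param window Terminal window length in nucleotides for the binary and
#'   hybrid encodings (default 17, the minimum modelling length).
#' @param percent If `TRUE`, composition values are scaled to percent instead
#'   of fractions summing to 1.
#' @return An object of class `feature_spec`.
#' @examples
#' spec_length(feature_spec("PNC"))    # 1024
#' spec_length(feature_spec("HYBRID")) # 200
#' @export
feature_spec <- function(encoding = c("PNC", "MNC", "DNC", "TNC", "TetNC",
                                      "BIN5", "BIN3", "BIN53", "HYBRID"),
                         window = 17L, percent = FALSE) {
  encoding <- match.arg(encoding)
  window <- as.integer(window)
  stopifnot(window >= 1L)
  structure(list(encoding = encoding,
                 k = unname(COMPOSITION_K[encoding]),
                 window = window, percent = isTRUE(percent)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("feature_spec: %s (%d features%s)\n", x$encoding, spec_length(x),
              if (x$encoding %in% names(COMPOSITION_K)) "" else
                sprintf(", terminal window %d nt", x$window)))
  invisible(x)
}

#' Number of features an encoding produces
#'
#' @param spec A [feature_spec()].
#' @return Integer vector length of the encoding.
#' @export
spec_length <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  switch(spec$encoding,
         MNC = 4L, DNC = 16L, TNC = 64L, TetNC = 256L, PNC = 1024L,
         BIN5 = 4L * spec$window, BIN3 = 4L * spec$window,
         BIN53 = 8L * spec$window, HYBRID = 64L + 8L * spec$window)
}

# minimum sequence length the encoding can accept
spec_min_length <- function(spec) {
  switch(spec$encoding,
         MNC = , DNC = , TNC = , TetNC = , PNC = spec$k,
         spec$window)
}

#' All k-mers over the RNA alphabet, in canonical order
#'
#' Lexicographic order under A < C < G < U; this fixes the column order of all
#' composition feature vectors.
#'
#' @param k Word length, 1 to 5.
#' @return Character vector of the 4^k k-mers.
#' @examples
#' kmer_index(1)
#' @export
kmer_index <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 5L) stop("k must be in 1..5", call. = FALSE)
  grids <- rev(rep(list(RNA_ALPHABET), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Overlapping k-mer composition of one sequence
#'
#' The value for k-mer `m` is the number of overlapping windows equal to `m`
#' divided by the number of windows, `length - k + 1`; the vector is ordered
#' by [kmer_index()] and sums to 1.
#'
#' @param seq RNA residue string.
#' @param k Word length, 1 to 5.
#' @return Named numeric vector of length 4^k.
#' @examples
#' kmer_composition("AUGC", 2)[c("AU", "UG", "GC")]  # each 1/3
#' @export
kmer_composition <- function(seq, k) {
  idx <- kmer_index(k)
  n <- nchar(seq)
  if (n < k) stop(sprintf("sequence of length %d is shorter than k = %d", n, k),
                  call. = FALSE)
  windows <- substring(seq, 1:(n - k + 1L), k:n)
  counts <- table(factor(windows, levels = idx))
  stats::setNames(as.numeric(counts) / (n - k + 1L), idx)
}

#' One-hot binary profile of terminal residues
#'
#' Encodes a fixed window of residues from the 5' end, the 3' end, or both
#' (5' block then 3' block) as concatenated 4-bit one-hot blocks in the order
#' A, C, G, U. The 3' window keeps its native 5'->3' orientation. For
#' sequences shorter than `2 * window` the two windows overlap; each block is
#' computed independently (a 17-nt sequence has identical 5' and 3' profiles).
#'
#' @param seq RNA residue string of length at least `window`.
#' @param end `"five_prime"`, `"three_prime"` or `"both"`.
#' @param window Number of terminal positions (default 17).
#' @return Named numeric 0/1 vector of length `4 * window` (single end) or
#'   `8 * window` (both).
#' @export
binary_profile <- function(seq, end = c("both", "five_prime", "three_prime"),
                           window = 17L) {
  end <- match.arg(end)
  window <- as.integer(window)
  n <- nchar(seq)
  if (n < window)
    stop(sprintf("sequence of length %d is too short for a terminal window of %d",
                 n, window), call. = FALSE)
  one_hot <- function(residues, tag) {
    m <- outer(residues, RNA_ALPHABET, `==`) + 0
    v <- as.numeric(t(m))
    names(v) <- paste0(tag, rep(seq_along(residues), each = 4L), ".", RNA_ALPHABET)
    v
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  switch(end,
         five_prime = one_hot(chars[1:window], "p5_"),
         three_prime = one_hot(chars[(n - window + 1L):n], "p3_"),
         both = c(one_hot(chars[1:window], "p5_"),
                  one_hot(chars[(n - window + 1L):n], "p3_")))
}

#' Hybrid encoding: trinucleotide composition plus both-termini binary profile
#'
#' @param seq RNA residue string of length at least `window`.
#' @param window Terminal window (default 17); the vector has
#'   `64 + 8 * window` entries (200 at the default).
#' @return Named numeric vector.
#' @export
hybrid_features <- function(seq, window = 17L) {
  c(kmer_composition(seq, 3L), binary_profile(seq, "both", window))
}

# encode one sequence under a spec
encode_one <- function(seq, spec) {
  v <- switch(spec$encoding,
              MNC = , DNC = , TNC = , TetNC = , PNC =
                kmer_composition(seq, spec$k),
              BIN5 = binary_profile(seq, "five_prime", spec$window),
              BIN3 = binary_profile(seq, "three_prime", spec$window),
              BIN53 = binary_profile(seq, "both", spec$window),
              HYBRID = hybrid_features(seq, spec$window))
  if (spec$percent && spec$encoding %in% names(COMPOSITION_K)) v <- 100 * v
  if (spec$percent && spec$encoding == "HYBRID") v[1:64] <- 100 * v[1:64]
  v
}

#' Encode a set of sequences as a feature matrix
#'
#' @param seqs Named character vector of RNA sequences, or an [orn_dataset()]
#'   (whose labels are returned as the `labels` attribute).
#' @param spec A [feature_spec()].
#' @return Numeric matrix, one row per sequence (rownames = ids, colnames =
#'   feature names). For an `orn_dataset` input the +1/-1 label vector is
#'   attached as `attr(, "labels")`.
#' @export
encode_sequences <- function(seqs, spec = feature_spec("PNC")) {
  labels <- NULL
  if (inherits(seqs, "orn_dataset")) {
    labels <- seqs$label
    seqs <- stats::setNames(seqs$seq, seqs$id)
  }
  stopifnot(inherits(spec, "feature_spec"))
  p <- spec_length(spec)
  if (length(seqs) == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = p)
    return(m)
  }
  rows <- lapply(seq_along(seqs), function(i) {
    tryCatch(encode_one(seqs[[i]], spec),
             error = function(e) stop(sprintf("record '%s': %s",
                                              names(seqs)[i] %||% i,
                                              conditionMessage(e)), call. = FALSE))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  if (!is.null(labels)) attr(m, "labels") <- labels
  m
}
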