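# Class-wise composition comparison and two-sample-logo style position
# enrichment tables. Per-sequence composition values are the samples; tests
# are classic pooled-variance two-sample two-sided t tests (zero pooled
# variance: p = 0 when the class means differ, p = 1 when equal). Raw
# p-values are reported by default; Bonferroni correction is optional.

#' Compare k-mer composition between two sequence classes
#'
#' For every k-mer, per-sequence composition fractions form the two samples;
#' the table reports class means, their difference `delta = mean_pos -
#' mean_neg`, and the two-sided pooled-variance t-test p-value.
#'
#' @param pos,neg Character vectors of sequences (each class needs at least 2,
#'   all of length >= k).
#' @param k Word length, 1 to 5.
#' @param correction `"none"` (default) or `"bonferroni"` for the p-values.
#' @return Data frame with one row per k-mer (in [kmer_index()] order):
#'   `kmer`, `mean_pos`, `mean_neg`, `delta`, `abs_delta`, `p_value`.
#' @examples
#' pos <- c("AAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAC")
#' neg <- c("GGGGGGGGGGGGGGGGG", "GGGGGGGGGGGGGGGGC")
#' compare_composition(pos, neg, k = 1)
#' @export
compare_composition <- function(pos, neg, k, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each class needs at least 2 sequences", call. = FALSE)
  A <- encode_sequences(stats::setNames(as.character(pos), NULL),
                        feature_spec(names(COMPOSITION_K)[k]))
  B <- encode_sequences(stats::setNames(as.character(neg), NULL),
                        feature_spec(names(COMPOSITION_K)[k]))
  tt <- pooled_t_statistic(A, B)
  p <- tt$p
  if (correction == "bonferroni") p <- pmin(1, p * length(p))
  data.frame(kmer = kmer_index(k),
             mean_pos = unname(tt$mean1), mean_neg = unname(tt$mean2),
             delta = unname(tt$mean1 - tt$mean2),
             abs_delta = abs(unname(tt$mean1 - tt$mean2)),
             p_value = unname(p))
}

#' Rank k-mers by absolute mean-composition difference
#'
#' @param cc A table from [compare_composition()].
#' @param top Number of k-mers to return (default all).
#' @return Character vector of k-mers, largest `abs_delta` first, ties broken
#'   lexicographically.
#' @export
rank_by_abs_delta <- function(cc, top = nrow(cc)) {
  stopifnot(top >= 1L, top <= nrow(cc))
  cc$kmer[order(-cc$abs_delta, cc$kmer)][seq_len(top)]
}

#' Two-sample-logo style position enrichment table
#'
#' Aligns a fixed window of terminal residues (17 by default, since dataset
#' lengths vary) from the 5' or 3' end of every sequence and, per position and
#' nucleotide, compares the per-sequence occupancy indicator between classes
#' with a two-sample t test. A cell is `enriched` when the positive-class
#' frequency is higher and p < alpha, `depleted` when lower and p < alpha,
#' `none` otherwise.
#'
#' @param pos,neg Character vectors of sequences, all of length >= `window`,
#'   at least 2 per class.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param window Number of aligned terminal positions (default 17).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per (position, nucleotide): `position`,
#'   `nucleotide`, `freq_pos`, `freq_neg`, `p_value`, `direction`,
#'   `significant`. Frequencies sum to 1 over the 4 nucleotides at each
#'   position within each class.
#' @export
two_sample_logo_table <- function(pos, neg, end = c("five_prime", "three_prime"),
                                  window = 17L, alpha = 0.05) {
  end <- match.arg(end)
  window <- as.integer(window)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each class needs at least 2 sequences", call. = FALSE)
  for (nm in c("pos", "neg")) {
    seqs <- get(nm)
    short <- which(nchar(seqs) < window)
    if (length(short))
      stop(sprintf("%s sequence(s) shorter than window %d: %s", nm, window,
                   paste(utils::head(names(seqs)[short] %||% short, 3), collapse = ", ")),
           call. = FALSE)
  }
  spec <- feature_spec(if (end == "five_prime") "BIN5" else "BIN3", window = window)
  A <- encode_sequences(stats::setNames(as.character(pos), NULL), spec)
  B <- encode_sequences(stats::setNames(as.character(neg), NULL), spec)
  tt <- pooled_t_statistic(A, B)
  freq_pos <- unname(tt$mean1); freq_neg <- unname(tt$mean2); p <- unname(tt$p)
  direction <- ifelse(p < alpha & freq_pos > freq_neg, "enriched",
                      ifelse(p < alpha & freq_pos < freq_neg, "depleted", "none"))
  data.frame(position = rep(seq_len(window), each = 4L),
             nucleotide = rep(RNA_ALPHABET, window),
             freq_pos = freq_pos, freq_neg = freq_neg, p_value = p,
             direction = direction, significant = p < alpha)
}
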