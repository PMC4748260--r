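# Discriminative gapped motif mining (MERCI-style).
#
# A gapped motif is an ordered list of literal blocks over {A,C,G,U} written
# "AAA-AA-A": blocks must occur in order with each inter-block gap of length
# gap_min..max_gap (default 1..G, so "-" is a realized separation). Coverage
# (number of sequences matched) is anti-monotone under motif extension, which
# the level-wise miner exploits for pruning.

#' Construct a gapped motif
#'
#' @param blocks Character vector of non-empty literal blocks over
#'   `{A,C,G,U}`, or a single string with blocks joined by `"-"`.
#' @param max_gap Maximum inter-block gap length G; must be 0 only for
#'   single-block motifs.
#' @return An object of class `gapped_motif` with elements `blocks`,
#'   `max_gap` and `text`.
#' @examples
#' gapped_motif("AAA-AA-AA-A", max_gap = 5)
#' @export
gapped_motif <- function(blocks, max_gap = 0L) {
  if (length(blocks) == 1L && grepl("-", blocks, fixed = TRUE))
    blocks <- strsplit(blocks, "-", fixed = TRUE)[[1L]]
  blocks <- as.character(blocks)
  if (!length(blocks) || any(!nzchar(blocks)) || any(grepl("[^ACGU]", blocks)))
    stop("motif blocks must be non-empty strings over A/C/G/U", call. = FALSE)
  max_gap <- as.integer(max_gap)
  if (max_gap < 0L) stop("max_gap must be >= 0", call. = FALSE)
  if (max_gap == 0L && length(blocks) > 1L)
    stop("a multi-block motif needs max_gap >= 1", call. = FALSE)
  structure(list(blocks = blocks, max_gap = max_gap,
                 text = paste(blocks, collapse = "-")),
            class = "gapped_motif")
}

#' @export
print.gapped_motif <- function(x, ...) {
  cat(sprintf("gapped_motif: %s (max gap %d)\n", x$text, x$max_gap))
  invisible(x)
}

motif_regex <- function(motif, gap_min = 1L) {
  if (length(motif$blocks) == 1L) return(motif$blocks)
  sep <- sprintf(".{%d,%d}", gap_min, motif$max_gap)
  paste(motif$blocks, collapse = sep)
}

#' Match a gapped motif against sequences
#'
#' A motif matches when its blocks occur in order with every inter-block gap
#' length in `[gap_min, max_gap]`. Single-block motifs reduce to substring
#' search.
#'
#' @param motif A [gapped_motif()].
#' @param seqs Character vector of RNA sequences.
#' @param gap_min Minimum realized gap length (default 1; set 0 to let blocks
#'   abut).
#' @return Logical vector, one entry per sequence.
#' @export
motif_matches <- function(motif, seqs, gap_min = 1L) {
  stopifnot(inherits(motif, "gapped_motif"))
  grepl(motif_regex(motif, gap_min), seqs, perl = TRUE)
}

#' Number of sequences a motif covers
#'
#' @inheritParams motif_matches
#' @return Integer count of sequences matched (each counted once).
#' @export
motif_coverage <- function(motif, seqs, gap_min = 1L) {
  sum(motif_matches(motif, seqs, gap_min))
}

#' Mine discriminative gapped motifs
#'
#' Level-wise search: candidates grow from single nucleotides by either
#' appending a literal to the last block or opening a new single-literal block
#' after a gap. A candidate is pruned as soon as its positive coverage falls
#' below `min_pos_coverage` (coverage only shrinks under extension). Surviving
#' candidates are reported when their negative coverage is at most
#' `max_neg_coverage`, sorted by positive coverage (descending), then shorter
#' motif text, then lexicographic text. Swap the `pos` and `neg` arguments to
#' mine negative-class motifs.
#'
#' @param pos Character vector of positive-class sequences (non-empty).
#' @param neg Character vector of negative-class sequences.
#' @param max_gap Maximum gap length G (0 disables gaps entirely).
#' @param min_pos_coverage Minimum positive sequences a motif must cover;
#'   default 10% of `length(pos)` (at least 1).
#' @param max_neg_coverage Maximum negative sequences a reported motif may
#'   cover (default 0: exclusive motifs).
#' @param max_blocks,max_literal,max_block_len Search caps: maximum number of
#'   blocks, total literal length, and per-block literal length.
#' @param gap_min Minimum realized gap length (see [motif_matches()]).
#' @return Data frame with columns `motif` (text), `max_gap`,
#'   `positive_coverage`, `negative_coverage`, sorted as described.
#' @examples
#' discover_motifs(rep("GAAAG", 5), rep("GGGG", 5), max_gap = 0,
#'                 min_pos_coverage = 5)
#' @export
discover_motifs <- function(pos, neg, max_gap = 5L,
                            min_pos_coverage = max(1L, ceiling(0.1 * length(pos))),
                            max_neg_coverage = 0L,
                            max_blocks = 6L, max_literal = 10L,
                            max_block_len = max_literal, gap_min = 1L) {
  if (!length(pos)) stop("positive set must be non-empty", call. = FALSE)
  if (min_pos_coverage < 1L) stop("min_pos_coverage must be >= 1", call. = FALSE)
  pos <- unname(as.character(pos)); neg <- unname(as.character(neg))

  # frontier entries carry the indices they still match, so extensions only
  # re-test the parent's matches (anti-monotonicity)
  new_node <- function(blocks, pos_idx, neg_idx) {
    list(blocks = blocks, pos_idx = pos_idx, neg_idx = neg_idx)
  }
  check <- function(blocks, idx, seqs) {
    if (!length(idx)) return(integer(0))
    m <- gapped_motif(blocks, if (length(blocks) > 1L) max_gap else 0L)
    idx[motif_matches(m, seqs[idx], gap_min)]
  }
  frontier <- list()
  for (nt in RNA_ALPHABET) {
    pi <- check(nt, seq_along(pos), pos)
    if (length(pi) >= min_pos_coverage)
      frontier[[length(frontier) + 1L]] <- new_node(nt, pi, check(nt, seq_along(neg), neg))
  }
  results <- frontier
  while (length(frontier)) {
    nxt <- list()
    for (node in frontier) {
      blocks <- node$blocks
      lit <- sum(nchar(blocks))
      ext <- list()
      if (lit < max_literal) {
        last <- blocks[length(blocks)]
        if (nchar(last) < max_block_len) {
          for (nt in RNA_ALPHABET) {
            b <- blocks; b[length(b)] <- paste0(last, nt)
            ext[[length(ext) + 1L]] <- b
          }
        }
        if (max_gap >= 1L && length(blocks) < max_blocks) {
          for (nt in RNA_ALPHABET) ext[[length(ext) + 1L]] <- c(blocks, nt)
        }
      }
      for (b in ext) {
        pi <- check(b, node$pos_idx, pos)
        if (length(pi) >= min_pos_coverage)
          nxt[[length(nxt) + 1L]] <- new_node(b, pi, check(b, node$neg_idx, neg))
      }
    }
    results <- c(results, nxt)
    frontier <- nxt
  }
  keep <- vapply(results, function(n) length(n$neg_idx) <= max_neg_coverage, logical(1))
  results <- results[keep]
  if (!length(results)) {
    return(data.frame(motif = character(0), max_gap = integer(0),
                      positive_coverage = integer(0), negative_coverage = integer(0)))
  }
  out <- data.frame(
    motif = vapply(results, function(n) paste(n$blocks, collapse = "-"), character(1)),
    max_gap = vapply(results, function(n) if (length(n$blocks) > 1L) as.integer(max_gap) else 0L,
                     integer(1)),
    positive_coverage = vapply(results, function(n) length(n$pos_idx), integer(1)),
    negative_coverage = vapply(results, function(n) length(n$neg_idx), integer(1)))
  out <- out[order(-out$positive_coverage, nchar(out$motif), out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
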