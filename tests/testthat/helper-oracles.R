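# Independent oracles used across the suite. These deliberately use naive
# brute-force strategies so they share no code path with the implementation.

# count occurrences of each k-mer by scanning every window explicitly
naive_kmer_fractions <- function(seq, k) {
  kmers <- kmer_index(k)
  counts <- stats::setNames(integer(length(kmers)), kmers)
  n <- nchar(seq)
  for (i in seq_len(n - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    counts[w] <- counts[w] + 1L
  }
  counts / (n - k + 1L)
}

# closed-form Matthews correlation coefficient from confusion counts
mcc_closed_form <- function(tp, fp, tn, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) 0 else (tp * tn - fp * fn) / denom
}

# rebuild +1/-1 label vectors realizing given confusion counts
labels_from_counts <- function(tp, fp, tn, fn) {
  list(truth = c(rep(1L, tp), rep(1L, fn), rep(-1L, tn), rep(-1L, fp)),
       pred = c(rep(1L, tp), rep(-1L, fn), rep(-1L, tn), rep(1L, fp)))
}

# enumerate every gapped motif with <= max_blocks blocks, each block of
# length <= max_block_len, total literal length <= max_literal
enumerate_all_motifs <- function(max_blocks, max_block_len, max_literal) {
  nts <- c("A", "C", "G", "U")
  words <- unlist(lapply(seq_len(max_block_len), function(l) {
    do.call(paste0, rev(expand.grid(rev(rep(list(nts), l)),
                                    stringsAsFactors = FALSE)))
  }))
  out <- list()
  grow <- function(blocks, lit) {
    if (length(blocks)) out[[length(out) + 1L]] <<- blocks
    if (length(blocks) >= max_blocks) return()
    for (w in words) {
      if (lit + nchar(w) <= max_literal) grow(c(blocks, w), lit + nchar(w))
    }
  }
  grow(character(0), 0L)
  out
}

# brute-force reference for discover_motifs on bounded instances
brute_force_discover <- function(pos, neg, max_gap, min_pos, max_neg,
                                 max_blocks, max_block_len, max_literal) {
  cands <- enumerate_all_motifs(max_blocks, max_block_len, max_literal)
  rows <- lapply(cands, function(blocks) {
    if (length(blocks) > 1L && max_gap < 1L) return(NULL)
    m <- gapped_motif(blocks, if (length(blocks) > 1L) max_gap else 0L)
    pc <- motif_coverage(m, pos)
    if (pc < min_pos) return(NULL)
    nc <- motif_coverage(m, neg)
    if (nc > max_neg) return(NULL)
    data.frame(motif = m$text,
               max_gap = if (length(blocks) > 1L) as.integer(max_gap) else 0L,
               positive_coverage = pc, negative_coverage = nc)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(motif = character(0), max_gap = integer(0),
                      positive_coverage = integer(0), negative_coverage = integer(0)))
  out <- out[order(-out$positive_coverage, nchar(out$motif), out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive enumeration of all nested structures; returns the maximum number
# of base pairs over {AU, UA, GC, CG, GU, UG} with hairpin loops >= min_loop
brute_force_max_pairs <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  best <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    v <- best(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (ok(chars[k], chars[j])) {
        left <- if (k > i) best(i, k - 1L) else 0L
        v <- max(v, 1L + left + best(k + 1L, j - 1L))
      }
    }
    v
  }
  if (length(chars) < 2L) 0L else best(1L, length(chars))
}

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

random_rna <- function(n, len, probs = rep(0.25, 4), prefix = "r") {
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = probs),
            collapse = ""),
      character(1)),
    paste0(prefix, seq_len(n)))
}
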