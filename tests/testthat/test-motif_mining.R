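test_that("gapped motifs validate blocks and gaps", {
  m <- gapped_motif("AAA-AA-AA-A", max_gap = 5)
  expect_identical(m$blocks, c("AAA", "AA", "AA", "A"))
  expect_identical(m$text, "AAA-AA-AA-A")
  expect_error(gapped_motif("AAN"), "A/C/G/U")
  expect_error(gapped_motif(c("AA", "A"), max_gap = 0), "max_gap")
})

test_that("motif matching honours block order and gap bounds", {
  expect_true(motif_matches(gapped_motif("AAA"), "GAAAG"))
  expect_false(motif_matches(gapped_motif("AAA"), "GGGG"))
  # blocks at 1-2 and 5, realized gap 2 <= G
  expect_true(motif_matches(gapped_motif("AA-A", max_gap = 2), "AACGA"))
  # gap of 3 exceeds G = 2
  expect_false(motif_matches(gapped_motif("AA-A", max_gap = 2), "AACCGA"))
  # default minimum gap is 1: abutting blocks do not match
  expect_false(motif_matches(gapped_motif("AA-A", max_gap = 2), "AAAGGG"))
  expect_true(motif_matches(gapped_motif("AA-A", max_gap = 2), "AAAGGG", gap_min = 0))
  expect_identical(motif_matches(gapped_motif("A"), c("AGG", "GGG", "GAG")),
                   c(TRUE, FALSE, TRUE))
})

test_that("coverage counts matched sequences once each", {
  expect_identical(motif_coverage(gapped_motif("AAA"), rep("GGG", 4)), 0L)
  expect_identical(motif_coverage(gapped_motif("A"), c("AA", "GA", "AG")), 3L)
})

test_that("discovery finds exclusive motifs in a tiny separable case", {
  res <- discover_motifs(rep("AAAA", 5), rep("GGGG", 5), max_gap = 0,
                         min_pos_coverage = 5, max_neg_coverage = 0)
  expect_true("AAAA" %in% res$motif)
  expect_identical(res$positive_coverage[res$motif == "AAAA"], 5L)
  expect_true(all(res$negative_coverage == 0L))
  # swapped classes recover the negative-class motif
  swapped <- discover_motifs(rep("GGGG", 5), rep("AAAA", 5), max_gap = 0,
                             min_pos_coverage = 5)
  expect_true("GGGG" %in% swapped$motif)
  expect_identical(nrow(discover_motifs(rep("AAAA", 3), character(0),
                                        max_gap = 0, min_pos_coverage = 4)), 0L)
  expect_error(discover_motifs(rep("AAAA", 3), character(0),
                               min_pos_coverage = 0), "min_pos_coverage")
})

test_that("discovery is symmetric under A<->G relabelling", {
  set.seed(21)
  pos <- random_rna(8, 10, probs = c(0.55, 0.15, 0.15, 0.15))
  neg <- chartr("AG", "GA", pos)
  res_fwd <- discover_motifs(pos, neg, max_gap = 2, min_pos_coverage = 4,
                             max_neg_coverage = 1, max_literal = 4)
  res_rev <- discover_motifs(neg, pos, max_gap = 2, min_pos_coverage = 4,
                             max_neg_coverage = 1, max_literal = 4)
  expect_setequal(chartr("AG", "GA", res_fwd$motif), res_rev$motif)
})

test_that("coverage is anti-monotone under extension", {
  set.seed(17)
  seqs <- random_rna(30, 15)
  for (i in 1:20) {
    nblocks <- sample(1:3, 1)
    blocks <- replicate(nblocks, paste(sample(c("A", "C", "G", "U"),
                                              sample(1:2, 1), replace = TRUE),
                                       collapse = ""))
    m <- gapped_motif(blocks, max_gap = if (nblocks > 1) 3 else 0)
    base_cov <- motif_coverage(m, seqs)
    ext1 <- gapped_motif(c(blocks[-nblocks], paste0(blocks[nblocks], "A")),
                         max_gap = if (nblocks > 1) 3 else 0)
    ext2 <- gapped_motif(c(blocks, "G"), max_gap = 3)
    expect_lte(motif_coverage(ext1, seqs), base_cov)
    expect_lte(motif_coverage(ext2, seqs), base_cov)
  }
})

test_that("reported motifs verify their thresholds when re-matched from scratch", {
  set.seed(3)
  pos <- random_rna(20, 12, probs = c(0.5, 0.2, 0.1, 0.2))
  neg <- random_rna(20, 12, probs = c(0.1, 0.2, 0.5, 0.2))
  res <- discover_motifs(pos, neg, max_gap = 2, min_pos_coverage = 8,
                         max_neg_coverage = 2, max_literal = 5)
  expect_gt(nrow(res), 0)
  for (i in seq_len(nrow(res))) {
    m <- gapped_motif(res$motif[i], max_gap = res$max_gap[i])
    expect_identical(motif_coverage(m, pos), res$positive_coverage[i])
    expect_identical(motif_coverage(m, neg), res$negative_coverage[i])
    expect_gte(res$positive_coverage[i], 8L)
    expect_lte(res$negative_coverage[i], 2L)
  }
})

test_that("level-wise discovery matches brute-force enumeration on bounded instances", {
  set.seed(9)
  for (trial in 1:4) {
    pos <- random_rna(6, sample(6:10, 1), probs = c(0.4, 0.2, 0.2, 0.2))
    neg <- random_rna(6, sample(6:10, 1), probs = c(0.2, 0.2, 0.4, 0.2))
    for (G in c(0, 2)) {
      mine <- discover_motifs(pos, neg, max_gap = G, min_pos_coverage = 3,
                              max_neg_coverage = 2, max_blocks = 2,
                              max_block_len = 2, max_literal = 4)
      brute <- brute_force_discover(pos, neg, max_gap = G, min_pos = 3,
                                    max_neg = 2, max_blocks = 2,
                                    max_block_len = 2, max_literal = 4)
      expect_equal(mine, brute)
    }
  }
})

test_that("a planted gapped motif is recovered from synthetic positives", {
  unif <- rep(0.25, 4)
  planted <- gapped_motif("AAA-AA-AA-A", max_gap = 5)
  ds <- generate_dataset(synthetic_spec(
    n_pos = 120, n_neg = 120, pos_probs = unif, neg_probs = unif,
    planted_motif = planted, planting_rate = 0.7, seed = 19))
  pos <- dataset_class(ds, 1); neg <- dataset_class(ds, -1)
  res <- discover_motifs(pos, neg, max_gap = 5,
                         min_pos_coverage = ceiling(0.4 * length(pos)),
                         max_neg_coverage = ceiling(0.02 * length(neg)))
  planted_cov <- motif_coverage(planted, pos)
  # the planted motif itself, or a pattern covering at least as many
  # positives, sits at the top of the ranking
  expect_true("AAA-AA-AA-A" %in% res$motif)
  expect_gte(res$positive_coverage[1], planted_cov)
})
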