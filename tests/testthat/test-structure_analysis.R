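test_that("dot-bracket parsing validates and builds the pairing map", {
  db <- parse_dot_bracket("AAAA", "....")
  expect_identical(db$n_pairs, 0L)
  db2 <- parse_dot_bracket("GGGAAAACCC", "(((....)))")
  expect_identical(db2$n_pairs, 3L)
  expect_identical(db2$partner[1], 10L)
  expect_identical(db2$partner[3], 8L)
  expect_true(is.na(db2$partner[5]))
  expect_error(parse_dot_bracket("AA", "(."), "unbalanced")
  expect_error(parse_dot_bracket("AA", ")."), "unbalanced")
  expect_error(parse_dot_bracket("AAA", ".."), "length")
  expect_error(parse_dot_bracket("AAA", ".x."), "invalid structure character")
})

test_that("parsing preserves the structure string round-trip", {
  set.seed(33)
  for (i in 1:10) {
    db <- fold_nussinov(random_rna(1, sample(10:20, 1))[[1]])
    expect_identical(parse_dot_bracket(db$seq, db$structure)$structure,
                     db$structure)
  }
})

test_that("Nussinov fold handles canonical examples deterministically", {
  expect_identical(fold_nussinov("AAAAAAA")$structure, ".......")
  db <- fold_nussinov("GGGAAAACCC")
  expect_identical(db$structure, "(((....)))")
  expect_identical(db$n_pairs, 3L)
  # determinism
  expect_identical(fold_nussinov("GCGCAAAUGCGC")$structure,
                   fold_nussinov("GCGCAAAUGCGC")$structure)
})

test_that("Nussinov pair count matches exhaustive enumeration up to length 12", {
  set.seed(44)
  for (i in 1:12) {
    s <- random_rna(1, sample(6:12, 1))[[1]]
    expect_identical(fold_nussinov(s)$n_pairs, brute_force_max_pairs(s),
                     info = s)
  }
})

test_that("structures classify as linear exactly when no pairs exist", {
  expect_identical(classify_structure(parse_dot_bracket("AAAA", "....")), "linear")
  expect_identical(classify_structure(parse_dot_bracket("GGGAAAACCC", "(((....)))")),
                   "stem_loop")
  expect_identical(classify_structure(parse_dot_bracket("GAAAC", "(...)")),
                   "stem_loop")
  set.seed(55)
  for (i in 1:10) {
    db <- fold_nussinov(random_rna(1, 15)[[1]])
    lin <- classify_structure(db) == "linear"
    expect_identical(lin, db$n_pairs == 0L && nrow(hairpin_loops(db)) == 0L)
  }
})

test_that("hairpin loops are maximal unpaired runs closed by a pair", {
  expect_identical(nrow(hairpin_loops(parse_dot_bracket("AAAA", "...."))), 0L)
  one <- hairpin_loops(parse_dot_bracket("GGGAAAACCC", "(((....)))"))
  expect_identical(one$start, 4L)
  expect_identical(one$end, 7L)
  expect_identical(one$close_i, 3L)
  expect_identical(one$close_j, 8L)
  two <- hairpin_loops(parse_dot_bracket("GGAAAUCCGGAAAUCC",
                                         "((....))((....))"))
  expect_identical(nrow(two), 2L)
  expect_identical(two$start, c(3L, 11L))
  # internal loops are not hairpins: only the innermost run qualifies
  internal <- parse_dot_bracket("GGAGGAAAUCCAUCC", "((.((....)).)).")
  expect_identical(nrow(hairpin_loops(internal)), 1L)
})

test_that("loop uridine detection inspects only the loop range", {
  db <- parse_dot_bracket("GGGAAAACCC", "(((....)))")
  loop <- hairpin_loops(db)[1, ]
  expect_false(loop_contains_uridine(loop, db))
  db_u <- parse_dot_bracket("GGGAAUACCC", "(((....)))")
  expect_true(loop_contains_uridine(hairpin_loops(db_u)[1, ], db_u))
})

test_that("RNAfold backend folds and records energies", {
  structs <- fold_rnafold(c(polyA = strrep("A", 17),
                            hairpin = "GGGGGAAAACCCCCAAA"))
  expect_identical(structs$polyA$structure, strrep(".", 17))
  expect_lte(structs$hairpin$mfe, 0)
  expect_s3_class(structs$hairpin, "dot_bracket")
  byname <- fold_sequences(c(a = strrep("A", 17)), backend = "nussinov")
  expect_identical(attr(byname, "backend"), "nussinov")
})

test_that("length-bin summary conserves counts and computes half-up percentages", {
  set.seed(66)
  pos <- random_rna(30, 17, prefix = "p")
  pos <- c(pos, random_rna(10, 22, prefix = "q"), random_rna(5, 25, prefix = "r"))
  neg <- random_rna(22, 24, prefix = "n")
  ps <- fold_sequences(pos, backend = "nussinov")
  ns <- fold_sequences(neg, backend = "nussinov")
  tab <- summarize_by_length_bins(ps, ns)
  expect_true(all(tab$n_linear + tab$n_stem_loop == tab$n_sequences))
  pos_rows <- tab[tab$class == "IMORN" & tab$bin != "total", ]
  expect_equal(sum(pos_rows$n_sequences), length(pos))
  expect_equal(tab$pct_linear,
               percentage(tab$n_linear, tab$n_sequences))
  # the printed-table percentage convention
  expect_equal(percentage(353, 602), 58.64)
  expect_equal(percentage(2, 22), 9.09)
  expect_equal(percentage(128, 520), 24.62)
  # empty class yields zero percentages, not NaN
  tab0 <- summarize_by_length_bins(ps, list())
  expect_true(all(tab0$pct_linear[tab0$class == "non-IMORN"] == 0))
  short <- fold_sequences(c(s = strrep("A", 10)), backend = "nussinov")
  expect_error(summarize_by_length_bins(short, list()), "outside all bins")
})
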