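test_that("scoring scheme validates its parameters", {
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2))
  sc <- scoring_scheme()
  expect_equal(sc$gap_open, 10)
  expect_equal(sc$gap_extend, 0.5)
  expect_true(all(sc$submat["X", ] == 0))
})

test_that("global_align reproduces identity and derived examples", {
  al <- global_align("ACDEF", "ACDEF")
  expect_equal(al$identity_pct, 100)
  expect_false(grepl("-", al$gapped_a))

  # optimum and identity confirmed by exhaustive enumeration (helper oracle)
  al2 <- global_align("FAYK", "FCYK")
  expect_equal(al2$identity_pct, 75)
  expect_equal(al2$score, 18)

  expect_error(global_align("", "ACD"), "empty")
})

test_that("alignment score matches Biostrings on random pairs", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(99)
  sc <- scoring_scheme()
  for (k in 1:25) {
    a <- random_aa_string(sample(3:40, 1))
    b <- random_aa_string(sample(3:40, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b, sc)$score, ref)
  }
})

test_that("identity is symmetric, bounded and ungappable", {
  set.seed(17)
  sc <- scoring_scheme()
  for (k in 1:20) {
    a <- random_aa_string(sample(5:30, 1))
    b <- random_aa_string(sample(5:30, 1))
    ab <- global_align(a, b, sc); ba <- global_align(b, a, sc)
    expect_equal(ab$identity_pct, ba$identity_pct)
    expect_gte(ab$identity_pct, 0); expect_lte(ab$identity_pct, 100)
    expect_identical(gsub("-", "", ab$gapped_a), a)
    expect_identical(gsub("-", "", ab$gapped_b), b)
    cols <- cbind(strsplit(ab$gapped_a, "")[[1]], strsplit(ab$gapped_b, "")[[1]])
    expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
    expect_equal(global_align(a, a, sc)$identity_pct, 100)
  }
})

test_that("the shorter-sequence identity denominator is selectable", {
  sc <- scoring_scheme(identity_denominator = "shorter")
  al <- global_align("ACDEFG", "CDEF", sc)
  expect_equal(al$identity_pct, 100)
  al2 <- global_align("ACDEFG", "CDEF", scoring_scheme())
  expect_lt(al2$identity_pct, 100)
})

test_that("identity_matrix reports exclusion-aware extrema", {
  set.seed(23)
  base <- random_aa_string(50)
  near <- make_sequence_pair(50, 0.9, seed = 5)
  far <- random_aa_string(50)
  seqs <- c(p1 = near$a, p2 = near$b, q = far,
            r = paste(rev(strsplit(base, "")[[1]]), collapse = ""))
  im <- identity_matrix(seqs)
  expect_equal(diag(im$matrix), setNames(rep(100, 4), names(seqs)))
  expect_true(isSymmetric(im$matrix))
  expect_equal(im$max$pair, c("p1", "p2"))
  # excluding the same-protein pair changes the reported maximum
  im2 <- identity_matrix(seqs, groups = c(p1 = "g", p2 = "g", q = NA, r = NA))
  expect_false(all(im2$max$pair == c("p1", "p2")))
  expect_equal(im2$matrix, im$matrix)  # only the extrema change
})
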