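test_that("bundled registry has the expected cross-kingdom composition", {
  reg <- default_registry()
  expect_s3_class(reg, "s1_registry")
  expect_equal(nrow(reg), 24)
  cnt <- attr(reg, "kingdom_counts")
  expect_equal(unname(cnt[c("bacteria", "eukaryota", "archaea")]),
               c(9L, 10L, 5L))
  expect_setequal(reg$group[!is.na(reg$group)],
                  c("pnpase", "nusa", "polg", "aif2a", "rrp4"))
})

test_that("registry parsing handles single records, headers and comments", {
  f <- tempfile()
  writeLines(c("# a comment", "", "2K4K A 1 84 bacteria GSP13"), f)
  reg <- read_registry(f)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$pdb_id, "2k4k")
  expect_equal(reg$start, 1)
  expect_equal(reg$end, 84)
})

test_that("malformed and degenerate registries are rejected with context", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_error(read_registry(f), "no records")

  writeLines(c("1abc A 1", "# done"), f)
  expect_error(read_registry(f), "line 1")

  writeLines(c("1abc A 10 5 bacteria x"), f)
  expect_error(read_registry(f), "start > end")

  writeLines(c("1abc A 1 50 bacteria x", "1abc A 1 50 bacteria x"), f)
  expect_error(read_registry(f), "duplicate")

  writeLines(c("1abc A 1 50 fungi x"), f)
  expect_error(read_registry(f), "kingdom")

  writeLines(c("xxxx A 1 50 bacteria x"), f)
  expect_error(read_registry(f), "invalid PDB id")
})

test_that("registries round-trip through write_registry", {
  reg <- default_registry()
  f <- tempfile()
  write_registry(reg, f)
  back <- read_registry(f)
  expect_equal(as.data.frame(back), as.data.frame(reg))
})

test_that("kingdom partition is exhaustive and disjoint on random registries", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    reg <- s1scape:::validate_registry(data.frame(
      pdb_id = sprintf("%d%s", sample(1:9, n, TRUE),
                       vapply(seq_len(n), function(i)
                         paste(sample(letters, 3, TRUE), collapse = ""),
                         character(1))),
      chain = "A", start = 1L, end = sample(50:90, n, TRUE),
      kingdom = sample(c("bacteria", "eukaryota", "archaea"), n, TRUE),
      protein_name = "p", group = NA_character_,
      stringsAsFactors = FALSE
    ))
    part <- kingdom_partition(reg)
    expect_equal(sum(vapply(part, nrow, 1L)), nrow(reg))
    recon <- do.call(rbind, part)
    expect_setequal(paste(recon$pdb_id, recon$start, recon$end),
                    paste(reg$pdb_id, reg$start, reg$end))
  }
})

test_that("same-protein pairs are symmetric and confined to shared groups", {
  reg <- default_registry()
  m <- same_protein_pairs(reg)
  expect_true(all(m == t(m)))
  expect_false(any(diag(m)))
  expect_true(m["1sro", "4aim"])
  expect_true(m["6gmh", "6ir9"])
  expect_false(m["1sro", "2k4k"])
  expect_equal(sum(m), 10)  # five excluded pairs, both directions
})
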