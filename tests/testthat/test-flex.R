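test_that("fluctuation classes follow the 3/6 Angstrom thresholds", {
  expect_equal(classify_fluctuations(c(7, 2, 3, 6, 0, 6.001, 2.999)),
               c("flexible", "rigid", "moderate", "moderate", "rigid",
                 "flexible", "rigid"))
  expect_error(classify_fluctuations(c(1, -0.1)), "nonnegative")
})

test_that("percent_flexible counts the strict class by default", {
  labs <- c(rep("flexible", 3), rep("moderate", 4), rep("rigid", 3))
  expect_equal(percent_flexible(labs), 30)
  expect_equal(percent_flexible(labs, include_moderate = TRUE), 70)
  expect_equal(percent_flexible(rep("rigid", 10)), 0)
  expect_equal(percent_flexible(rep("flexible", 5)), 100)
  # permutation invariance and the stricter-threshold monotonicity
  set.seed(6)
  vals <- runif(50, 0, 10)
  p <- percent_flexible(classify_fluctuations(vals))
  expect_equal(percent_flexible(classify_fluctuations(sample(vals))), p)
  expect_lte(p, percent_flexible(ifelse(vals > 3, "flexible", "rigid")))
})

test_that("fluctuation tables are parsed, normalized and validated", {
  f <- tempfile()
  writeLines(c("# FlexPred-style output", "residue fluct",
               sprintf("%d %.2f", 70:1, seq(0.5, 7.4, by = 0.1))), f)
  v <- read_fluctuation_table(f)
  expect_length(v, 70)
  expect_equal(names(v)[1], "1")
  expect_equal(unname(v["70"]), 0.5)   # shuffled order re-sorted
  expect_true(!is.unsorted(as.numeric(names(v))))

  v2 <- read_fluctuation_table(f, expected_length = 60)
  expect_match(attr(v2, "warning"), "expected 60")

  writeLines(c("1 0.5", "2 oops"), f)
  expect_error(read_fluctuation_table(f), "line 2")
})

test_that("B-factor z-scores are population-standardized", {
  fx <- make_toy_structure(10, 9, 0.2, seed = 33)
  s <- fx$structure
  s$atoms$b[s$atoms$name == "CA"] <- rep(c(10, 20, 30), length.out = 10)[
    s$atoms$resno[s$atoms$name == "CA"]]
  # direct hand-checked case
  s3 <- s; keep <- s3$atoms$resno <= 3
  s3 <- s1scape:::new_structure(s3$atoms[keep, , drop = FALSE], "A")
  s3$atoms$b[s3$atoms$name == "CA"] <- c(10, 20, 30)
  prof <- bfactor_zscores(s3)
  expect_equal(prof$values, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(prof$values), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(prof$values^2)), 1, tolerance = 1e-12)
  expect_equal(prof$labels, c("rigid", "moderate", "flexible"))

  s$atoms$b <- 5
  expect_error(bfactor_zscores(s), "uninformative B-factors")
})

test_that("synthetic flexible fractions are recovered exactly", {
  for (ff in c(0, 0.1, 0.3, 0.45)) {
    fx <- make_toy_structure(70, 12, ff, seed = 55)
    prof <- bfactor_zscores(fx$structure)
    expect_equal(prof$percent_flexible, 100 * round(ff * 70) / 70)
    flagged <- which(prof$labels == "flexible")
    expect_equal(flagged, fx$truth$flexible_residues)
  }
})

test_that("profiles export as residue/value/class TSV", {
  prof <- flex_profile(c(1, 4, 8), residue_numbers = c(5, 6, 7))
  f <- tempfile(fileext = ".tsv")
  write_flex_tsv(prof, f)
  tab <- read.delim(f)
  expect_equal(tab$residue, 5:7)
  expect_equal(tab$class, c("rigid", "moderate", "flexible"))
})
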