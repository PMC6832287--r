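test_that("kabsch_superpose recovers rigid transforms exactly", {
  set.seed(4)
  x <- matrix(rnorm(30, sd = 4), 10, 3)
  sup <- kabsch_superpose(x, x)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-8)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  y <- sweep(x %*% t(R), 2, -c(5, 5, 5))
  sup2 <- kabsch_superpose(x, y)
  expect_equal(sup2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sup2$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(sup2, x), y, tolerance = 1e-8)
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + rnorm(15, sd = .1)),
               "degenerate")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3, 3),
                                matrix(rnorm(12), 4, 3)), "equal length")
})

test_that("rmsd is rigid-invariant and never beaten by the raw pairing", {
  set.seed(40)
  for (rep in 1:15) {
    x <- matrix(rnorm(24, sd = 3), 8, 3)
    y <- x + matrix(rnorm(24, sd = 0.7), 8, 3)
    r0 <- kabsch_superpose(x, y)$rmsd
    expect_lte(r0, sqrt(mean(rowSums((x - y)^2))) + 1e-12)
    ang <- runif(3, 0, 2 * pi)
    R <- euler_rotation(ang)
    y2 <- sweep(y %*% t(R), 2, -runif(3, -10, 10))
    expect_equal(kabsch_superpose(x, y2)$rmsd, r0, tolerance = 1e-9)
    x2 <- sweep(x %*% t(R), 2, -runif(3, -10, 10))
    expect_equal(kabsch_superpose(x2, y)$rmsd, r0, tolerance = 1e-9)
  }
})

test_that("pairwise_rmsd is sequence-guided and zero on self", {
  fx <- make_toy_structure(60, 12, 0.2, seed = 9)
  s <- fx$structure
  expect_equal(pairwise_rmsd(s, s)$rmsd, 0, tolerance = 1e-10)

  # mutate 30% of residue names without touching coordinates: rmsd stays 0
  mut <- s
  set.seed(10)
  idx <- sample(60, 18)
  pool <- setdiff(names(s1scape:::AA3TO1), unique(mut$residues$resname[idx]))
  for (k in seq_along(idx)) {
    rows <- mut$atoms$resno == idx[k]
    mut$atoms$resname[rows] <- pool[1 + (k %% length(pool))]
  }
  mut <- s1scape:::new_structure(mut$atoms, mut$chain)
  sup <- pairwise_rmsd(s, mut)
  expect_equal(sup$rmsd, 0, tolerance = 1e-6)
  expect_gte(sup$n_pairs, 40)
})

test_that("short correspondences attach a warning but still return", {
  a <- make_toy_structure(6, 8, 0, seed = 11)$structure
  b <- make_toy_structure(6, 8, 0, seed = 12)$structure
  sup <- pairwise_rmsd(a, b)
  expect_true(length(sup$warning) == 1)
  expect_match(sup$warning, "matched residue pairs")
})

test_that("multiple_superpose is order-invariant with a medoid reference", {
  set.seed(14)
  structs <- lapply(1:4, function(i)
    make_toy_structure(50, 11 + i, 0.1, seed = 20 + i)$structure)
  names(structs) <- paste0("s", 1:4)
  rm1 <- multiple_superpose(structs)
  expect_true(isSymmetric(rm1$matrix))
  expect_equal(unname(diag(rm1$matrix)), rep(0, 4))
  perm <- c("s3", "s1", "s4", "s2")
  rm2 <- multiple_superpose(structs[perm])
  expect_equal(rm2$matrix[names(structs), names(structs)], rm1$matrix)
  expect_equal(rm2$mean, rm1$mean)

  copies <- setNames(rep(list(structs[[1]]), 3), paste0("c", 1:3))
  rm3 <- multiple_superpose(copies)
  expect_equal(max(abs(rm3$matrix)), 0, tolerance = 1e-10)
})

test_that("radius_of_gyration obeys its closed forms and symmetries", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  set.seed(15)
  x <- matrix(rnorm(60, sd = 5), 20, 3)
  rg <- radius_of_gyration(x)
  for (k in c(0.5, 2, 10)) {
    expect_equal(radius_of_gyration(k * x), k * rg, tolerance = 1e-12)
  }
  R <- euler_rotation(runif(3, 0, 2 * pi))
  expect_equal(radius_of_gyration(sweep(x %*% t(R), 2, -c(3, -4, 7))), rg,
               tolerance = 1e-10)
})
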