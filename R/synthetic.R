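# Fixture generators with exact, recoverable ground truth. Toy structures
# carry no protein-like stereochemistry on purpose: only the measured
# quantities (Rg, B-factor classes, sequence) matter to the analyses.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy single-chain structure with known ground truth
#'
#' Builds an N/CA/C/O backbone along a compact random walk, rescales the
#' coordinates about their centroid so the all-atom radius of gyration
#' equals `target_rg` to within 1e-9 Angstrom, and fills the B-factor
#' column so that exactly `round(flexible_fraction * n_residues)` residues
#' exceed the within-domain z > 1 flexibility threshold. Deterministic
#' under `seed`. A z > 1 threshold can flag at most half the residues
#' (one-sided Chebyshev bound), so `flexible_fraction` must keep
#' `round(f * n) < n / 2`.
#'
#' @param n_residues number of residues (>= 5).
#' @param target_rg target all-atom radius of gyration, Angstrom.
#' @param flexible_fraction target fraction of flexible residues.
#' @param seed integer seed.
#' @param path optional path; when given, the structure is also written as a
#'   PDB-format file.
#' @return list with `structure` (an `s1_structure`), `path` (or `NULL`) and
#'   `truth` (list: `sequence`, `rg`, `flexible_residues`,
#'   `flexible_fraction`).
#' @export
make_toy_structure <- function(n_residues = 70, target_rg = 12,
                               flexible_fraction = 0.3, seed = 1,
                               path = NULL) {
  stopifnot(n_residues >= 5, target_rg > 0,
            flexible_fraction >= 0, flexible_fraction <= 1)
  k <- round(flexible_fraction * n_residues)
  if (k >= n_residues / 2) {
    stop("flexible_fraction too large: a z > 1 threshold can flag at most ",
         "half the residues (round(f*n) must be < n/2)")
  }
  with_seed(seed, {
    n <- n_residues
    # compact random walk of CA positions, 3.8 A steps
    steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 3.8
    ca <- apply(rbind(c(0, 0, 0), steps), 2, cumsum)
    # mild pull toward the centroid keeps the walk globular
    ca <- ca * 0.8 + 0.2 * matrix(colMeans(ca), n, 3, byrow = TRUE)

    offs <- list(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0),
                 C = c(1.2, 0.8, 0), O = c(1.9, 1.6, 0.4))
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(names(offs), function(nm) {
        p <- ca[i, ] + offs[[nm]]
        data.frame(name = nm, resno = i, x = p[1], y = p[2], z = p[3],
                   stringsAsFactors = FALSE)
      }))
    }))
    coords <- as.matrix(atoms[, c("x", "y", "z")])
    ctr <- colMeans(coords)
    scale <- target_rg / radius_of_gyration(coords)
    coords <- sweep(sweep(coords, 2, ctr), 2, rep(1, 3) / scale, `/`)
    coords <- sweep(coords, 2, -ctr)

    aa <- sample(AA1, n, replace = TRUE)
    resname <- names(AA3TO1)[match(aa, AA3TO1)]

    flex_res <- sort(sample.int(n, k))
    base <- rep_len(c(0, 1), n)           # variance even with no flexibles
    base[flex_res] <- 10
    z <- (base - mean(base)) / sqrt(mean((base - mean(base))^2))
    if (sum(z > 1) != k) {
      stop("rounding collision: cannot realize flexible_fraction ",
           flexible_fraction, " with n = ", n)
    }
    b_res <- round(15 + 5 * z, 2)          # PDB B column has 2 decimals

    adf <- data.frame(
      serial = seq_len(nrow(atoms)), name = atoms$name, altloc = "",
      resname = resname[atoms$resno], chain = "A", resno = atoms$resno,
      icode = "", x = coords[, 1], y = coords[, 2], z = coords[, 3],
      b = b_res[atoms$resno], stringsAsFactors = FALSE
    )
    s <- new_structure(adf, "A")
    # PDB fixed columns quantize coordinates to 1e-3 A, so a re-parsed file
    # recovers Rg to ~1e-4; the returned in-memory structure is exact (1e-9)
    if (!is.null(path)) write_pdb(s, path)
    list(structure = s, path = path,
         truth = list(sequence = paste(aa, collapse = ""),
                      rg = target_rg, flexible_residues = flex_res,
                      flexible_fraction = k / n))
  })
}

#' Generate a sequence pair with prescribed ungapped identity
#'
#' The second sequence differs from the first at exactly
#' `round((1 - pair_identity) * length)` positions; substitutions never
#' re-create the original residue, so the ungapped identity matches the
#' target exactly.
#'
#' @param length sequence length.
#' @param pair_identity target identity in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `a`, `b` (sequences) and `n_mismatches`.
#' @export
make_sequence_pair <- function(length = 70, pair_identity = 0.5, seed = 1) {
  stopifnot(length >= 1, pair_identity >= 0, pair_identity <= 1)
  with_seed(seed, {
    a <- sample(AA1, length, replace = TRUE)
    m <- round((1 - pair_identity) * length)
    b <- a
    if (m > 0) {
      pos <- sample.int(length, m)
      for (p in pos) b[p] <- sample(setdiff(AA1, a[p]), 1)
    }
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
         n_mismatches = m)
  })
}

#' Generate location-shifted group samples
#'
#' Group `i` is drawn from a standard normal shifted by `(i - 1) * shift`;
#' `shift = 0` gives the Kruskal-Wallis null of identical distributions.
#'
#' @param sizes integer vector of group sizes (>= 2 groups).
#' @param shift location shift between consecutive groups.
#' @param seed integer seed.
#' @return list of numeric vectors.
#' @export
make_group_samples <- function(sizes = c(9, 10, 5), shift = 0, seed = 1) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  with_seed(seed, {
    lapply(seq_along(sizes), function(i)
      rnorm(sizes[i], mean = (i - 1) * shift))
  })
}
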