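#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping `x` onto `y` via SVD of
#' the cross-covariance matrix, with the determinant sign fixed so the
#' result is a proper rotation (no reflection).
#'
#' @param x,y n x 3 coordinate matrices of paired points (n >= 3,
#'   non-collinear).
#' @return an object of class `s1_superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length 3; the fit is
#'   `x %*% t(rotation) + translation`), `rmsd` (Angstrom) and `n_pairs`.
#' @export
kabsch_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3)
  if (nrow(x) != nrow(y)) stop("point sets must have equal length")
  n <- nrow(x)
  if (n < 3) stop("need at least 3 paired points for superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  if (min(svd(xc)$d) < 1e-8 * max(svd(xc)$d, 1e-8)) {
    stop("degenerate (collinear or coincident) point set")
  }
  H <- t(xc) %*% yc
  s <- svd(H)
  sgn <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, sgn))
  R <- s$v %*% D %*% t(s$u)
  fitted <- xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  translation <- as.numeric(cy - R %*% cx)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_pairs = n),
            class = "s1_superposition")
}

#' @export
print.s1_superposition <- function(x, ...) {
  cat(sprintf("<s1_superposition> rmsd %.3f A over %d pairs\n",
              x$rmsd, x$n_pairs))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup an `s1_superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  out <- as.matrix(coords) %*% t(sup$rotation)
  out + matrix(sup$translation, nrow(out), 3, byrow = TRUE)
}

#' Sequence-guided pairwise C-alpha RMSD
#'
#' Residue correspondence comes from the ungapped columns of a global
#' sequence alignment; matched C-alpha pairs are superposed with
#' [kabsch_superpose()].
#'
#' @param a,b `s1_structure` objects.
#' @param sc an [scoring_scheme()].
#' @return an `s1_superposition` with an added `warning` element (character,
#'   possibly empty; set when fewer than 10 residue pairs matched).
#' @export
pairwise_rmsd <- function(a, b, sc = scoring_scheme()) {
  ca_a <- ca_coordinates(a); ca_b <- ca_coordinates(b)
  al <- global_align(domain_sequence(a), domain_sequence(b), sc)
  ga <- strsplit(al$gapped_a, "")[[1L]]
  gb <- strsplit(al$gapped_b, "")[[1L]]
  ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
  both <- ga != "-" & gb != "-"
  # sequence positions -> CA rows; residues lacking CA are dropped
  ca_idx_a <- match(rownames(ca_a), paste0(a$residues$resno, a$residues$icode))
  ca_idx_b <- match(rownames(ca_b), paste0(b$residues$resno, b$residues$icode))
  pos_a <- ia[both]; pos_b <- ib[both]
  ra <- match(pos_a, ca_idx_a); rb <- match(pos_b, ca_idx_b)
  ok <- !is.na(ra) & !is.na(rb)
  sup <- kabsch_superpose(ca_a[ra[ok], , drop = FALSE],
                          ca_b[rb[ok], , drop = FALSE])
  sup$warning <- if (sup$n_pairs < 10)
    sprintf("only %d matched residue pairs", sup$n_pairs) else character(0)
  sup
}

#' Multiple superposition onto a medoid reference
#'
#' Computes all pairwise sequence-guided RMSDs, picks the medoid (minimum
#' mean RMSD to the others) as reference, and reports the symmetric RMSD
#' matrix with its mean over distinct pairs.
#'
#' @param structures named list of `s1_structure` objects (>= 2).
#' @param sc an [scoring_scheme()].
#' @return an object of class `s1_rmsd`: list with `matrix` (Angstrom),
#'   `mean` (over the upper triangle), `reference` (medoid name) and
#'   `superpositions` (list mapping each entry onto the reference).
#' @export
multiple_superpose <- function(structures, sc = scoring_scheme()) {
  n <- length(structures)
  stopifnot(n >= 2, !is.null(names(structures)))
  nm <- names(structures)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    m[i, j] <- m[j, i] <- pairwise_rmsd(structures[[i]], structures[[j]], sc)$rmsd
  }
  medoid <- which.min(rowMeans(m))
  sups <- lapply(seq_len(n), function(i) {
    if (i == medoid) {
      structure(list(rotation = diag(3), translation = c(0, 0, 0),
                     rmsd = 0, n_pairs = nrow(ca_coordinates(structures[[i]]))),
                class = "s1_superposition")
    } else {
      pairwise_rmsd(structures[[i]], structures[[medoid]], sc)
    }
  })
  names(sups) <- nm
  structure(list(matrix = m, mean = mean(m[upper.tri(m)]),
                 reference = nm[medoid], superpositions = sups),
            class = "s1_rmsd")
}

#' @export
print.s1_rmsd <- function(x, ...) {
  cat(sprintf("<s1_rmsd> %d structures, mean pairwise rmsd %.2f A (reference %s)\n",
              nrow(x$matrix), x$mean, x$reference))
  print(round(x$matrix, 2))
  invisible(x)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the atoms from their common centroid,
#' unweighted by mass, over all (non-hydrogen) atoms:
#' `Rg = sqrt(mean(|r_i - r_mean|^2))`.
#'
#' @param s an `s1_structure`, or an n x 3 coordinate matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(s) {
  coords <- if (inherits(s, "s1_structure"))
    as.matrix(s$atoms[, c("x", "y", "z")]) else as.matrix(s)
  stopifnot(nrow(coords) >= 1, ncol(coords) == 3)
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}
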