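# Independent oracles used by the property and acceptance tests. These stay
# deliberately separate from the package's own code paths: the aligner
# oracle enumerates alignments recursively, the superposition oracle scans
# a rotation grid, the MSA oracle is a full three-way dynamic program.

# Best global alignment score by exhaustive enumeration of all alignments
# (each maximal gap run costs open + ext * length). Feasible for length <= 6.
enum_align_score <- function(va, vb, submat, open, ext) {
  best <- -Inf
  n <- length(va); m <- length(vb)
  rec <- function(i, j, last, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= n && j <= m) rec(i + 1L, j + 1L, "M", acc + submat[va[i], vb[j]])
    if (i <= n) rec(i + 1L, j, "A", acc - if (last == "A") ext else open + ext)
    if (j <= m) rec(i, j + 1L, "B", acc - if (last == "B") ext else open + ext)
  }
  rec(1L, 1L, "0", 0)
  best
}

euler_rotation <- function(ang) {
  ca <- cos(ang[1]); sa <- sin(ang[1])
  cb <- cos(ang[2]); sb <- sin(ang[2])
  cg <- cos(ang[3]); sg <- sin(ang[3])
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry  <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

# Minimal rmsd over proper rotations: coarse Euler-angle grid followed by
# Nelder-Mead refinement (translation handled by centering).
grid_rmsd <- function(x, y) {
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  f <- function(ang) {
    R <- euler_rotation(ang)
    sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
  }
  g <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                   b = seq(0, pi, length.out = 7),
                   c = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(g, 1, f)
  st <- as.numeric(g[which.min(vals), ])
  stats::optim(st, f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 10000))$value
}

# Column-additive sum-of-pairs scoring with a linear gap cost, and its
# exhaustive three-sequence optimum.
SP_GAP <- 5

sp_pair_score <- function(x, y, submat) {
  if (x == "-" && y == "-") 0
  else if (x == "-" || y == "-") -SP_GAP
  else submat[x, y]
}

sp_score <- function(rows, submat) {
  m <- do.call(rbind, strsplit(rows, ""))
  tot <- 0
  for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    tot <- tot + sum(mapply(sp_pair_score, m[i, ], m[j, ],
                            MoreArgs = list(submat = submat)))
  }
  tot
}

msa3_optimum <- function(a, b, c, submat) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  vc <- strsplit(c, "")[[1]]
  n1 <- length(va); n2 <- length(vb); n3 <- length(vc)
  D <- array(-Inf, dim = c(n1 + 1, n2 + 1, n3 + 1))
  D[1, 1, 1] <- 0
  moves <- as.matrix(expand.grid(0:1, 0:1, 0:1)[-1, ])
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    v <- D[i + 1, j + 1, k + 1]
    if (!is.finite(v)) next
    for (r in 1:7) {
      di <- moves[r, 1]; dj <- moves[r, 2]; dk <- moves[r, 3]
      if (i + di > n1 || j + dj > n2 || k + dk > n3) next
      x <- if (di) va[i + 1] else "-"
      y <- if (dj) vb[j + 1] else "-"
      z <- if (dk) vc[k + 1] else "-"
      nv <- v + sp_pair_score(x, y, submat) + sp_pair_score(x, z, submat) +
        sp_pair_score(y, z, submat)
      if (nv > D[i + 1 + di, j + 1 + dj, k + 1 + dk]) {
        D[i + 1 + di, j + 1 + dj, k + 1 + dk] <- nv
      }
    }
  }
  D[n1 + 1, n2 + 1, n3 + 1]
}

# random ultrametric distance matrix built by explicit agglomeration with
# strictly increasing merge heights (ground truth for UPGMA reconstruction)
random_ultrametric <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  clusters <- as.list(seq_len(n))
  h <- 0
  while (length(clusters) > 1) {
    h <- h + runif(1, 0.1, 1)
    pick <- sample(length(clusters), 2)
    for (i in clusters[[pick[1]]]) for (j in clusters[[pick[2]]]) {
      d[i, j] <- d[j, i] <- 2 * h
    }
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters[[pick[2]]] <- NULL
  }
  d
}
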