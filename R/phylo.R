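#' Distance matrix from a percent-identity matrix
#'
#' `d = 1 - identity/100`, symmetric with zero diagonal.
#'
#' @param m symmetric percent-identity matrix (as from
#'   [identity_matrix()]`$matrix`) or an `s1_identity` object.
#' @return symmetric numeric distance matrix in `[0, 1]`.
#' @export
distance_from_identity <- function(m) {
  if (inherits(m, "s1_identity")) m <- m$matrix
  stopifnot(is.matrix(m), isTRUE(all.equal(m, t(m))))
  d <- 1 - m / 100
  diag(d) <- 0
  d
}

# Average-linkage agglomeration over slot indices. Ties on the minimal
# distance are broken lexicographically on the pair of cluster labels (each
# cluster labeled by its lexicographically smallest leaf). Returns a list of
# merges: list(i, j, height) with the merged cluster kept in slot i.
upgma_merges <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 2, !is.null(rownames(d)))
  act <- rep(TRUE, n)
  size <- rep(1L, n)
  lab <- rownames(d)
  dm <- d
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(act)
    best <- NULL
    for (a in idx) for (b in idx) {
      if (a >= b) next
      key <- sort(c(lab[a], lab[b]))
      cand <- list(i = a, j = b, d = dm[a, b], key = key)
      if (is.null(best) || cand$d < best$d - 1e-12 ||
          (abs(cand$d - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    for (k in idx) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (size[i] * dm[i, k] + size[j] * dm[j, k]) / (size[i] + size[j])
    }
    merges[[step]] <- list(i = i, j = j, height = best$d / 2)
    size[i] <- size[i] + size[j]
    act[j] <- FALSE
    lab[i] <- min(lab[i], lab[j])
  }
  merges
}

#' UPGMA dendrogram from a distance matrix
#'
#' Standard unweighted average-linkage clustering producing an ultrametric
#' rooted tree; equal-distance ties are broken lexicographically so the
#' result is deterministic. Neighbor-joining (via ape, unrooted,
#' non-ultrametric) is available behind `method = "nj"`.
#'
#' @param d symmetric distance matrix with labelled rows/columns.
#' @param method `"upgma"` (default) or `"nj"`.
#' @return an object of class `s1_dendrogram`: list with `newick` (branch
#'   lengths to 6 decimals), `phylo` (an [ape::read.tree()] object) and
#'   `height` (root height; `NA` for NJ).
#' @export
upgma_tree <- function(d, method = c("upgma", "nj")) {
  method <- match.arg(method)
  if (method == "nj") {
    ph <- ape::nj(stats::as.dist(d))
    nwk <- ape::write.tree(ph)
    return(structure(list(newick = nwk, phylo = ph, height = NA_real_),
                     class = "s1_dendrogram"))
  }
  n <- nrow(d)
  labs <- rownames(d)
  sub <- as.list(labs)
  hgt <- rep(0, n)
  merges <- upgma_merges(d)
  for (mg in merges) {
    bl_i <- mg$height - hgt[mg$i]
    bl_j <- mg$height - hgt[mg$j]
    sub[[mg$i]] <- sprintf("(%s:%.6f,%s:%.6f)", sub[[mg$i]], bl_i,
                           sub[[mg$j]], bl_j)
    hgt[mg$i] <- mg$height
  }
  root <- merges[[length(merges)]]$i
  nwk <- paste0(sub[[root]], ";")
  structure(list(newick = nwk, phylo = ape::read.tree(text = nwk),
                 height = hgt[root]),
            class = "s1_dendrogram")
}

#' @export
print.s1_dendrogram <- function(x, ...) {
  cat("<s1_dendrogram>", length(x$phylo$tip.label), "leaves\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' @param tree an `s1_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "s1_dendrogram"))
  writeLines(tree$newick, path)
  invisible(path)
}

#' Cophenetic distances of a dendrogram
#'
#' @param tree an `s1_dendrogram`.
#' @return symmetric matrix of leaf-to-leaf path distances.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "s1_dendrogram"))
  ape::cophenetic.phylo(tree$phylo)
}
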