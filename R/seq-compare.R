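#' Alignment scoring scheme
#'
#' Defaults are the classic global-aligner settings: BLOSUM62 with gap open
#' 10 and gap extend 0.5 (a gap of length L costs `open + L * extend`). `X`
#' scores 0 against everything. End gaps are penalized (true global mode),
#' appropriate because domains are pre-sliced to comparable spans.
#'
#' @param matrix substitution matrix name available in Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open nonnegative gap opening penalty.
#' @param gap_extend nonnegative gap extension penalty, `<= gap_open`.
#' @param identity_denominator `"alignment"` (identical columns over full
#'   alignment length, the default) or `"shorter"` (over the shorter
#'   sequence length).
#' @return an object of class `s1_scoring`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5,
                           identity_denominator = c("alignment", "shorter")) {
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  identity_denominator <- match.arg(identity_denominator)
  sub <- load_submat(matrix)
  structure(list(matrix_name = matrix, submat = sub, gap_open = gap_open,
                 gap_extend = gap_extend,
                 identity_denominator = identity_denominator),
            class = "s1_scoring")
}

load_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  ab <- c(AA1, "X")
  m <- m[ab, ab]
  m["X", ] <- 0  # unknown residues are neutral
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  m
}

seq_to_idx <- function(s, alphabet) {
  v <- strsplit(toupper(s), "")[[1L]]
  idx <- match(v, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx
}

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Optimal global alignment under affine gap penalties via the Gotoh
#' three-state recursion, with deterministic traceback tie-breaking
#' (diagonal, then up, then left).
#'
#' @param a,b sequences (one-letter strings); `X` allowed, scored 0.
#' @param sc an [scoring_scheme()].
#' @return an object of class `s1_alignment`: list with `gapped_a`,
#'   `gapped_b`, `score`, `identity_pct`, `n_columns`.
#' @examples
#' aln <- global_align("FAYK", "FCYK")
#' aln$identity_pct  # 75
#' @export
global_align <- function(a, b, sc = scoring_scheme()) {
  stopifnot(inherits(sc, "s1_scoring"))
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  ab <- rownames(sc$submat)
  ia <- seq_to_idx(a, ab); ib <- seq_to_idx(b, ab)
  S <- sc$submat[ia, ib, drop = FALSE]
  res <- .gotoh_core(S, sc$gap_open, sc$gap_extend)
  va <- strsplit(toupper(a), "")[[1L]]; vb <- strsplit(toupper(b), "")[[1L]]
  ga <- ifelse(res$pa == 0L, "-", va[pmax(res$pa, 1L)])
  gb <- ifelse(res$pb == 0L, "-", vb[pmax(res$pb, 1L)])
  ident <- sum(ga == gb & ga != "-")
  denom <- if (sc$identity_denominator == "alignment") length(ga)
           else min(nchar(a), nchar(b))
  structure(list(
    gapped_a = paste(ga, collapse = ""), gapped_b = paste(gb, collapse = ""),
    score = res$score, identity_pct = 100 * ident / denom,
    n_columns = length(ga)
  ), class = "s1_alignment")
}

#' @export
print.s1_alignment <- function(x, ...) {
  cat(sprintf("<s1_alignment> score %.1f, identity %.1f%% over %d columns\n",
              x$score, x$identity_pct, x$n_columns))
  cat(" ", x$gapped_a, "\n ", x$gapped_b, "\n", sep = "")
  invisible(x)
}

#' Pairwise percent-identity matrix with extrema
#'
#' Aligns every pair globally and reports the symmetric identity matrix
#' (100 on the diagonal) together with the most- and least-identical pair,
#' excluding pairs marked as the same protein (solved in different
#' organisms) from the extrema.
#'
#' @param seqs named character vector of >= 2 sequences.
#' @param sc an [scoring_scheme()].
#' @param groups optional named character vector (names matching `names(seqs)`)
#'   whose non-`NA` equal values mark same-protein pairs to exclude from the
#'   extrema, or a logical exclusion matrix such as [same_protein_pairs()].
#' @return an object of class `s1_identity`: list with `matrix` (percent),
#'   `max`, `min` (each `list(pair, value)`).
#' @export
identity_matrix <- function(seqs, sc = scoring_scheme(), groups = NULL) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    m[i, j] <- m[j, i] <- global_align(seqs[[i]], seqs[[j]], sc)$identity_pct
  }
  excl <- matrix(FALSE, n, n)
  if (is.matrix(groups)) {
    excl <- groups[names(seqs), names(seqs)]
  } else if (!is.null(groups)) {
    g <- groups[names(seqs)]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && !is.na(g[i]) && !is.na(g[j]) && g[i] == g[j])
        excl[i, j] <- TRUE
    }
  }
  cand <- upper.tri(m) & !excl
  if (!any(cand)) stop("all pairs excluded; cannot report extrema")
  vals <- m[cand]
  idx <- which(cand, arr.ind = TRUE)
  hi <- which.max(vals); lo <- which.min(vals)
  pr <- function(k) sort(c(names(seqs)[idx[k, 1]], names(seqs)[idx[k, 2]]))
  structure(list(matrix = m,
                 max = list(pair = pr(hi), value = vals[hi]),
                 min = list(pair = pr(lo), value = vals[lo])),
            class = "s1_identity")
}

#' @export
print.s1_identity <- function(x, ...) {
  cat(sprintf("<s1_identity> %d sequences; max %.0f%% (%s), min %.0f%% (%s)\n",
              nrow(x$matrix), x$max$value, paste(x$max$pair, collapse = "-"),
              x$min$value, paste(x$min$pair, collapse = "-")))
  print(round(x$matrix, 1))
  invisible(x)
}

# msa rows as a character matrix (rows = sequences, cols = alignment columns)
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa), ""))
}

# column frequency profile over AA1 + X, gaps contribute zero weight
profile_freqs <- function(rows, alphabet) {
  mat <- msa_matrix(rows)
  nr <- nrow(mat)
  f <- matrix(0, length(alphabet), ncol(mat), dimnames = list(alphabet, NULL))
  for (j in seq_len(ncol(mat))) {
    tb <- table(factor(mat[, j], levels = alphabet))
    f[, j] <- as.numeric(tb) / nr
  }
  f
}

#' Progressive multiple sequence alignment
#'
#' Pairwise identities define distances (`1 - identity/100`); a UPGMA guide
#' tree orders profile-profile merges scored by average-of-pairs
#' substitution scores under the same affine gap penalties as
#' [global_align()].
#'
#' @param seqs named character vector of >= 2 sequences.
#' @param sc an [scoring_scheme()].
#' @return named character vector of equal-length gapped rows, class
#'   `s1_msa`; ungapping row i recovers `seqs[i]`.
#' @export
progressive_msa <- function(seqs, sc = scoring_scheme()) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  if (n == 2L) {
    al <- global_align(seqs[[1L]], seqs[[2L]], sc)
    out <- setNames(c(al$gapped_a, al$gapped_b), names(seqs))
    class(out) <- "s1_msa"
    return(out)
  }
  idm <- matrix(100, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    idm[i, j] <- idm[j, i] <- global_align(seqs[[i]], seqs[[j]], sc)$identity_pct
  }
  d <- 1 - idm / 100
  dimnames(d) <- list(names(seqs), names(seqs))
  merges <- upgma_merges(d)

  ab <- rownames(sc$submat)
  clusters <- lapply(seq_len(n), function(i) setNames(seqs[i], names(seqs)[i]))
  for (mg in merges) {
    left <- clusters[[mg$i]]; right <- clusters[[mg$j]]
    clusters[[mg$i]] <- align_profiles(left, right, sc, ab)
    clusters[[mg$j]] <- NULL_cluster
  }
  final <- clusters[[merges[[length(merges)]]$i]]
  out <- final[names(seqs)]
  class(out) <- "s1_msa"
  out
}

NULL_cluster <- structure(character(0), empty = TRUE)

align_profiles <- function(rows1, rows2, sc, alphabet) {
  f1 <- profile_freqs(rows1, alphabet)
  f2 <- profile_freqs(rows2, alphabet)
  S <- t(f1) %*% sc$submat %*% f2
  res <- .gotoh_core(S, sc$gap_open, sc$gap_extend)
  expand <- function(rows, pos) {
    mat <- msa_matrix(rows)
    out <- matrix("-", nrow(mat), length(pos))
    nz <- pos != 0L
    out[, nz] <- mat[, pos[nz], drop = FALSE]
    setNames(apply(out, 1L, paste, collapse = ""), names(rows))
  }
  c(expand(rows1, res$pa), expand(rows2, res$pb))
}

#' Per-column information content of an alignment
#'
#' For each column, the Shannon entropy `H = -sum f log2 f` over non-gap
#' residue frequencies gives information `log2(20) - H` bits; all-gap
#' columns carry 0 bits. No small-sample correction is applied.
#'
#' @param msa an `s1_msa` or named character vector of equal-length gapped
#'   rows.
#' @return an object of class `s1_logo`: list with `freq` (residues x
#'   columns, per-column frequencies over non-gap symbols summing to 1) and
#'   `information` (bits per column).
#' @export
logo_information <- function(msa) {
  mat <- msa_matrix(msa)
  stopifnot(ncol(mat) >= 1L)
  ab <- c(AA1, "X")
  L <- ncol(mat)
  freq <- matrix(0, length(ab), L, dimnames = list(ab, NULL))
  info <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (!length(col)) next  # all-gap column: 0 bits
    tb <- table(factor(col, levels = ab))
    f <- as.numeric(tb) / length(col)
    freq[, j] <- f
    nz <- f > 0
    info[j] <- log2(20) - (-sum(f[nz] * log2(f[nz])))
  }
  info[info < 0] <- 0  # guard: X-rich columns cannot go below zero
  structure(list(freq = freq, information = info), class = "s1_logo")
}

#' Conserved alignment positions
#'
#' @param msa an `s1_msa` or named character vector of gapped rows.
#' @param threshold minimal modal non-gap residue frequency, in (0, 1].
#' @return data frame with `column` (1-based alignment column), `residue`
#'   (modal residue) and `frequency`, one row per conserved column.
#' @export
conserved_positions <- function(msa, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  lg <- logo_information(msa)
  out <- data.frame(column = integer(0), residue = character(0),
                    frequency = numeric(0), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(lg$freq))) {
    f <- lg$freq[, j]
    if (all(f == 0)) next
    k <- which.max(f)
    if (f[k] >= threshold) {
      out <- rbind(out, data.frame(column = j, residue = names(f)[k],
                                   frequency = unname(f[k]),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Write a logo matrix as TSV
#'
#' Long format: `column`, `residue`, `frequency`, `bits`.
#' @param logo an `s1_logo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  L <- ncol(logo$freq)
  rows <- do.call(rbind, lapply(seq_len(L), function(j) {
    f <- logo$freq[, j]
    nz <- which(f > 0)
    if (!length(nz)) return(NULL)
    data.frame(column = j, residue = names(f)[nz], frequency = unname(f[nz]),
               bits = logo$information[j], stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
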