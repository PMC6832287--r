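#' Disorder-promoting residue content
#'
#' Residues are classified as order-promoting (C, W, F, I, Y, V, L, H, T, N)
#' or disorder-promoting (D, M, A, R, G, Q, S, P, E, K) following their
#' relative abundance in ordered versus intrinsically disordered proteins.
#' `X` residues are excluded from both numerator and denominator.
#'
#' @param seq one-letter sequence.
#' @return percentage of classified residues that are disorder-promoting.
#' @export
disorder_content <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1L]]
  stopifnot(length(v) > 0)
  v <- v[v != "X" & v != "-"]
  if (!length(v)) stop("sequence contains no classifiable residues")
  100 * sum(v %in% DISORDER_SET) / length(v)
}

#' Order-promoting residue content
#'
#' Complement of [disorder_content()] for X-free sequences.
#' @param seq one-letter sequence.
#' @return percentage of classified residues that are order-promoting.
#' @export
order_content <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1L]]
  stopifnot(length(v) > 0)
  v <- v[v != "X" & v != "-"]
  if (!length(v)) stop("sequence contains no classifiable residues")
  100 * sum(v %in% ORDER_SET) / length(v)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom: mid-ranks for ties,
#' `H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2` divided by
#' `1 - sum(t^3 - t)/(N^3 - N)`. A permutation p-value (of H) is available
#' for small groups via `n_perm`.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @param n_perm if > 0, additionally estimate a permutation p-value from
#'   `n_perm` random relabellings (seeded by the caller).
#' @return an object of class `s1_kw`: list with `H`, `df`, `p`,
#'   `group_sizes` and optionally `p_perm`.
#' @export
kruskal_wallis <- function(groups, n_perm = 0) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) > 0))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3) stop("need at least 3 observations in total")
  if (length(unique(x)) == 1L) stop("no rank variation: all values identical")
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  H_of <- function(g) {
    r <- rank(x)  # mid-ranks
    rbar <- tapply(r, g, mean)
    n_i <- tabulate(g)
    H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
    t_cnt <- table(x)
    H / (1 - sum(t_cnt^3 - t_cnt) / (N^3 - N))
  }
  H <- H_of(g)
  df <- length(groups) - 1L
  out <- list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE),
              group_sizes = vapply(groups, length, 1L))
  if (n_perm > 0) {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (H_of(sample(g)) >= H - 1e-12) hits <- hits + 1L
    }
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  structure(out, class = "s1_kw")
}

#' @export
print.s1_kw <- function(x, ...) {
  cat(sprintf("<s1_kw> H = %.4f, df = %d, p = %.5f (groups: %s)\n",
              x$H, x$df, x$p, paste(x$group_sizes, collapse = "/")))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.5f\n", x$p_perm))
  invisible(x)
}
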