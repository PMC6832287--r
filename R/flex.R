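#' Classify per-residue fluctuation values
#'
#' Predicted absolute C-alpha fluctuations are binned into three classes:
#' rigid (< 3 Angstrom), moderately flexible (3-6, boundaries inclusive)
#' and flexible (> 6).
#'
#' @param values nonnegative numeric vector of per-residue fluctuations
#'   (Angstrom).
#' @return character vector of labels in `{"rigid", "moderate", "flexible"}`.
#' @export
classify_fluctuations <- function(values) {
  stopifnot(is.numeric(values))
  if (any(values < 0)) stop("fluctuation values must be nonnegative")
  ifelse(values > 6, "flexible", ifelse(values >= 3, "moderate", "rigid"))
}

#' Percent of flexible residues
#'
#' By the most literal reading of "most flexible", only the strictly
#' flexible class counts; set `include_moderate = TRUE` to count the
#' moderate class too.
#'
#' @param labels character vector of class labels.
#' @param include_moderate count `"moderate"` as flexible as well.
#' @return percentage in `[0, 100]` (unrounded).
#' @export
percent_flexible <- function(labels, include_moderate = FALSE) {
  stopifnot(length(labels) > 0)
  hit <- labels == "flexible"
  if (include_moderate) hit <- hit | labels == "moderate"
  100 * sum(hit) / length(labels)
}

#' Build a flexibility profile from fluctuation values
#'
#' @param values per-residue fluctuations (Angstrom).
#' @param residue_numbers author residue numbers (defaults to 1..n).
#' @param source `"predicted"` or `"bfactor"`.
#' @return an object of class `s1_flexprofile`: list with `residue_numbers`,
#'   `values`, `source`, `labels`, `percent_flexible`.
#' @export
flex_profile <- function(values, residue_numbers = seq_along(values),
                         source = "predicted") {
  labels <- if (source == "bfactor") {
    ifelse(values > 1, "flexible", ifelse(values >= 0, "moderate", "rigid"))
  } else {
    classify_fluctuations(values)
  }
  structure(list(residue_numbers = residue_numbers, values = values,
                 source = source, labels = labels,
                 percent_flexible = percent_flexible(labels)),
            class = "s1_flexprofile")
}

#' @export
print.s1_flexprofile <- function(x, ...) {
  cat(sprintf("<s1_flexprofile> %d residues (%s): %.1f%% flexible\n",
              length(x$values), x$source, x$percent_flexible))
  invisible(x)
}

#' Read an externally produced per-residue fluctuation table
#'
#' Two-column whitespace-separated text (residue number, fluctuation in
#' Angstrom); `#` comments and a non-numeric header line are skipped; rows
#' are re-sorted by residue number.
#'
#' @param path file path.
#' @param expected_length optional domain length; a mismatch attaches a
#'   warning attribute instead of failing.
#' @return named numeric vector of fluctuations (names = residue numbers),
#'   possibly carrying a `warning` attribute.
#' @export
read_fluctuation_table <- function(path, expected_length = NULL) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) && !grepl("^\\s*-?[0-9]", lines[[1L]])) {
    lines <- lines[-1L]; lineno <- lineno[-1L]  # header
  }
  if (!length(lines)) stop("no data rows in ", path)
  res <- val <- numeric(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[[k]]), "\\s+")[[1L]]
    if (length(f) < 2L) stop("line ", lineno[[k]], ": expected 2 columns")
    r <- suppressWarnings(as.numeric(f[[1L]]))
    v <- suppressWarnings(as.numeric(f[[2L]]))
    if (is.na(r) || is.na(v)) {
      stop("line ", lineno[[k]], ": non-numeric value in ", path)
    }
    res[k] <- r; val[k] <- v
  }
  o <- order(res)
  out <- setNames(val[o], res[o])
  if (!is.null(expected_length) && length(out) != expected_length) {
    attr(out, "warning") <- sprintf("expected %d values, got %d",
                                    expected_length, length(out))
  }
  out
}

#' B-factor z-score flexibility profile
#'
#' Crystallographic B-factors carry no absolute fluctuation scale, so they
#' are standardized within the domain: `z = (B - mean) / sd` over the
#' C-alpha B-factors (population sd). Labels: flexible if `z > 1`, moderate
#' if `0 <= z <= 1`, rigid if `z < 0`.
#'
#' @param s an `s1_structure` with per-residue C-alpha B-factors.
#' @return an `s1_flexprofile` with `source = "bfactor"`.
#' @export
bfactor_zscores <- function(s) {
  b <- ca_bfactors(s)
  if (length(b) < 2) stop("need at least two residues with CA B-factors")
  mu <- mean(b)
  sdp <- sqrt(mean((b - mu)^2))
  if (sdp == 0) stop("uninformative B-factors: zero variance")
  z <- (b - mu) / sdp
  flex_profile(unname(z), residue_numbers = names(b), source = "bfactor")
}

#' Export a flexibility profile as TSV
#'
#' Columns: `residue`, `value`, `class`.
#' @param profile an `s1_flexprofile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flex_tsv <- function(profile, path) {
  write.table(
    data.frame(residue = profile$residue_numbers, value = profile$values,
               class = profile$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
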