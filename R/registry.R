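#' Read a domain registry file
#'
#' A registry is a plain-text, tab-separated table with one domain per row and
#' columns `pdb_id`, `chain`, `start`, `end`, `kingdom`, `protein_name` and an
#' optional `group` column marking entries of the same protein solved in
#' different organisms (used to exclude same-protein pairs from identity
#' extrema). Lines starting with `#` are comments. A header line naming the
#' columns is optional and detected automatically.
#'
#' @param path path to the registry file.
#' @return an object of class `s1_registry`: a data frame with columns
#'   `pdb_id`, `chain`, `start`, `end`, `kingdom`, `protein_name`, `group`
#'   plus a `kingdom_counts` attribute.
#' @seealso [default_registry()] for the bundled 24-entry S1-domain set.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) && grepl("^pdb_id\\b", lines[[1L]])) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(lines)) stop("no records in registry file: ", path)
  fields <- strsplit(lines, "\t|\\s{2,}| +")
  rows <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]][nzchar(fields[[k]])]
    if (length(f) < 6L) {
      stop("malformed registry line ", lineno[[k]], ": expected at least 6 ",
           "fields (pdb_id chain start end kingdom protein_name), got ",
           length(f))
    }
    start <- suppressWarnings(as.integer(f[[3L]]))
    end <- suppressWarnings(as.integer(f[[4L]]))
    if (is.na(start) || is.na(end)) {
      stop("malformed registry line ", lineno[[k]],
           ": start/end must be integers")
    }
    grp <- if (length(f) >= 7L && nzchar(f[[7L]]) && f[[7L]] != ".")
      f[[7L]] else NA_character_
    rows[[k]] <- data.frame(
      pdb_id = tolower(f[[1L]]), chain = f[[2L]], start = start, end = end,
      kingdom = tolower(f[[5L]]), protein_name = gsub("_", " ", f[[6L]]),
      group = grp, stringsAsFactors = FALSE
    )
  }
  reg <- do.call(rbind, rows)
  validate_registry(reg)
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  bad <- !grepl("^[0-9][A-Za-z0-9]{3}$", reg$pdb_id)
  if (any(bad)) stop("invalid PDB id(s): ", paste(reg$pdb_id[bad], collapse = ", "))
  if (any(reg$start > reg$end)) {
    stop("start > end for: ",
         paste(reg$pdb_id[reg$start > reg$end], collapse = ", "))
  }
  if (!all(reg$kingdom %in% KINGDOMS)) {
    stop("kingdom must be one of ", paste(KINGDOMS, collapse = "/"),
         "; offending: ",
         paste(unique(reg$kingdom[!reg$kingdom %in% KINGDOMS]), collapse = ", "))
  }
  key <- paste(reg$pdb_id, reg$chain, reg$start, reg$end)
  if (anyDuplicated(key)) {
    stop("duplicate registry record(s): ", paste(key[duplicated(key)], collapse = "; "))
  }
  attr(reg, "kingdom_counts") <- vapply(KINGDOMS, function(k)
    sum(reg$kingdom == k), integer(1))
  class(reg) <- c("s1_registry", "data.frame")
  reg
}

#' Write a registry to a tab-separated file
#'
#' @param reg an `s1_registry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  out <- as.data.frame(reg)
  out$group[is.na(out$group)] <- "."
  out$protein_name <- gsub(" ", "_", out$protein_name)
  writeLines(c(paste(c("pdb_id", "chain", "start", "end", "kingdom",
                       "protein_name", "group"), collapse = "\t"),
               apply(out, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' The bundled 24-entry S1-domain registry
#'
#' Nine bacterial, ten eukaryotic and five archaeal S1 domains spanning the
#' major S1-containing protein families (PNPase, RNases, NusA, Tex, GSP13,
#' ribosomal protein S1, exosome components, RNA-polymerase-II subunits and
#' translation initiation factor 2 alpha). Domain residue ranges are curated
#' defaults resolved against the Pfam S1 profile envelope and are editable
#' configuration, not code: copy the file, adjust, and pass your copy to
#' [read_registry()].
#'
#' @param repeats if `TRUE`, return the optional multi-repeat registry
#'   (ribosomal protein S1 repeats) instead of the main 24-entry set.
#' @return an `s1_registry`.
#' @export
default_registry <- function(repeats = FALSE) {
  f <- if (repeats) "s1_registry_repeats.tsv" else "s1_registry.tsv"
  read_registry(system.file("extdata", f, package = "s1scape", mustWork = TRUE))
}

#' Partition a registry by kingdom
#'
#' @param reg an `s1_registry`.
#' @return a named list `bacteria`/`eukaryota`/`archaea` of row subsets
#'   (empty kingdoms give zero-row data frames); the partition is exhaustive
#'   and disjoint.
#' @export
kingdom_partition <- function(reg) {
  stopifnot(inherits(reg, "s1_registry"))
  out <- lapply(KINGDOMS, function(k) reg[reg$kingdom == k, , drop = FALSE])
  names(out) <- KINGDOMS
  out
}

#' @export
print.s1_registry <- function(x, ...) {
  cnt <- attr(x, "kingdom_counts")
  cat(sprintf("<s1_registry> %d domains (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", ")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Same-protein exclusion pairs
#'
#' Returns a logical matrix over registry entries that is `TRUE` for pairs
#' belonging to the same `group` label (the same protein solved from
#' different organisms), which are excluded when reporting identity extrema.
#' @param reg an `s1_registry`.
#' @return an n x n logical matrix with `FALSE` diagonal.
#' @export
same_protein_pairs <- function(reg) {
  n <- nrow(reg)
  m <- matrix(FALSE, n, n, dimnames = list(reg$pdb_id, reg$pdb_id))
  g <- reg$group
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && !is.na(g[i]) && !is.na(g[j]) && g[i] == g[j]) m[i, j] <- TRUE
  }
  m
}
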