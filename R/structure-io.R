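#' Parse a PDB-format coordinate file
#'
#' Reads `ATOM` records of one chain from the first model of a PDB file.
#' `HETATM` records (ligands, waters), hydrogens and all models after the
#' first are excluded; where alternate locations exist, the first-listed
#' altloc of each atom is kept. Residues are keyed by author numbering with
#' insertion codes appended, and a one-letter sequence is derived from the
#' residue list (nonstandard residues become `X`).
#'
#' @param path path to a PDB-format file.
#' @param chain single-character chain identifier; `NULL` picks the first
#'   chain in the file.
#' @return an object of class `s1_structure`: a list with elements
#'   `atoms` (data frame: `serial`, `name`, `altloc`, `resname`, `chain`,
#'   `resno`, `icode`, `x`, `y`, `z`, `b`), `chain`, `residues` (data frame:
#'   `resno`, `icode`, `resname`, `aa`) and `sequence`.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[[1L]] - 1L)]  # model 1 only
  at <- lines[startsWith(lines, "ATOM  ")]
  if (!length(at)) stop("no ATOM records in ", path)

  fld <- function(l, a, b) substr(l, a, b)
  atoms <- data.frame(
    serial  = as.integer(fld(at, 7, 11)),
    name    = trimws(fld(at, 13, 16)),
    altloc  = fld(at, 17, 17),
    resname = trimws(fld(at, 18, 20)),
    chain   = fld(at, 22, 22),
    resno   = as.integer(fld(at, 23, 26)),
    icode   = trimws(fld(at, 27, 27)),
    x       = as.numeric(fld(at, 31, 38)),
    y       = as.numeric(fld(at, 39, 46)),
    z       = as.numeric(fld(at, 47, 54)),
    b       = suppressWarnings(as.numeric(fld(at, 61, 66))),
    element = trimws(fld(at, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$b[is.na(atoms$b)] <- 0

  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[[1L]]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found in ", path,
         "; available chains: ", paste(chains, collapse = ", "))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]

  is_h <- ifelse(nzchar(atoms$element), atoms$element %in% c("H", "D"),
                 grepl("^[0-9]*H", atoms$name))
  atoms <- atoms[!is_h, , drop = FALSE]

  # first-listed altloc per (residue, atom name)
  key <- paste(atoms$resno, atoms$icode, atoms$name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms$element <- NULL

  new_structure(atoms, chain)
}

new_structure <- function(atoms, chain) {
  if (!nrow(atoms)) stop("structure has no atoms")
  rownames(atoms) <- NULL
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  rk <- paste0(atoms$resno, atoms$icode)
  first <- !duplicated(rk)
  residues <- data.frame(
    resno = atoms$resno[first], icode = atoms$icode[first],
    resname = atoms$resname[first], stringsAsFactors = FALSE
  )
  aa <- AA3TO1[residues$resname]
  aa[is.na(aa)] <- "X"
  residues$aa <- unname(aa)
  structure(
    list(atoms = atoms, chain = chain, residues = residues,
         sequence = paste(residues$aa, collapse = "")),
    class = "s1_structure"
  )
}

#' @export
print.s1_structure <- function(x, ...) {
  cat(sprintf("<s1_structure> chain %s: %d residues, %d atoms\n",
              x$chain, nrow(x$residues), nrow(x$atoms)))
  cat("  sequence: ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Slice a residue range out of a structure
#'
#' Keeps residues with `start <= author number <= end` (1-based inclusive).
#' Residues missing inside the range (unmodelled loops) are tolerated.
#'
#' @param s an `s1_structure`.
#' @param start,end author residue numbers.
#' @return an `s1_structure` restricted to the range.
#' @export
slice_domain <- function(s, start, end) {
  stopifnot(inherits(s, "s1_structure"), start <= end)
  keep <- s$atoms$resno >= start & s$atoms$resno <= end
  if (!any(keep)) {
    stop("range outside chain: no residues in [", start, ", ", end,
         "] for chain ", s$chain)
  }
  new_structure(s$atoms[keep, , drop = FALSE], s$chain)
}

#' One-letter sequence of a structure
#'
#' @param s an `s1_structure`.
#' @return character scalar; nonstandard residues are `X`.
#' @export
domain_sequence <- function(s) {
  stopifnot(inherits(s, "s1_structure"))
  s$sequence
}

#' C-alpha coordinates in residue order
#'
#' @param s an `s1_structure`.
#' @return a matrix with one row per residue possessing a CA atom, columns
#'   `x`, `y`, `z`, rownames the author residue numbers (with insertion
#'   codes), plus a `resno` attribute.
#' @export
ca_coordinates <- function(s) {
  stopifnot(inherits(s, "s1_structure"))
  ca <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- paste0(ca$resno, ca$icode)
  attr(m, "resno") <- ca$resno
  m
}

#' Per-residue C-alpha B-factors
#'
#' @param s an `s1_structure`.
#' @return named numeric vector (names = author residue numbers).
#' @export
ca_bfactors <- function(s) {
  stopifnot(inherits(s, "s1_structure"))
  ca <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  setNames(ca$b, paste0(ca$resno, ca$icode))
}

#' Write a structure as a PDB-format file
#'
#' @param s an `s1_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "s1_structure"))
  a <- s$atoms
  name4 <- ifelse(nchar(a$name) < 4L, paste0(" ", formatC(a$name, width = -3)),
                  a$name)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
    a$serial, name4, ifelse(nzchar(a$altloc), a$altloc, " "),
    a$resname, a$chain, a$resno,
    ifelse(nzchar(a$icode), a$icode, " "), a$x, a$y, a$z, 1, a$b
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' Headers follow the `>pdbid_chain/start-end` convention used throughout
#' the pipeline.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
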