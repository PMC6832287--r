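# Fixture builders shared across test files. Everything is generated in
# code; nothing is downloaded.

toy_registry <- function() {
  lines <- c(
    "pdb_id\tchain\tstart\tend\tkingdom\tprotein_name\tgroup",
    "1aa1\tA\t1\t70\tbacteria\ttoy_one\t.",
    "1aa2\tA\t1\t70\tbacteria\ttoy_two\tgrp1",
    "1aa3\tA\t1\t70\teukaryota\ttoy_three\tgrp1",
    "1aa4\tA\t1\t70\teukaryota\ttoy_four\t.",
    "1aa5\tA\t1\t70\tarchaea\ttoy_five\t.",
    "1aa6\tA\t1\t70\tarchaea\ttoy_six\t."
  )
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  read_registry(f)
}

toy_structure_dir <- function(reg, seed0 = 100) {
  dir <- tempfile("pdbs")
  dir.create(dir)
  for (i in seq_len(nrow(reg))) {
    make_toy_structure(n_residues = reg$end[i] - reg$start[i] + 1,
                       target_rg = 11 + i * 0.3, flexible_fraction = 0.2,
                       seed = seed0 + i,
                       path = file.path(dir, paste0(reg$pdb_id[i], ".pdb")))
  }
  dir
}

# hand-written mini PDB exercising altlocs, HETATM, hydrogens, two models
# and an MSE residue
mini_pdb <- function() {
  lines <- c(
    "HEADER    TEST",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 11.00           C",
    "ATOM      3  C   ALA A   1      12.685   7.161  -4.922  1.00 12.00           C",
    "ATOM      4  HA  ALA A   1      12.000   5.100  -4.900  1.00  0.00           H",
    "ATOM      5  N  AGLY A   2      13.894   6.882  -5.422  0.50 13.00           N",
    "ATOM      6  N  BGLY A   2      13.900   6.900  -5.400  0.50 14.00           N",
    "ATOM      7  CA AGLY A   2      15.020   7.800  -5.300  0.50 15.00           C",
    "ATOM      8  CA BGLY A   2      15.100   7.900  -5.200  0.50 16.00           C",
    "ATOM      9  N   MSE A   3      16.000   8.000  -6.000  1.00 17.00           N",
    "ATOM     10  CA  MSE A   3      17.200   8.500  -6.400  1.00 18.00           C",
    "ATOM     11  N   ASP B   1       1.000   2.000   3.000  1.00 19.00           N",
    "ATOM     12  CA  ASP B   1       2.400   2.100   3.100  1.00 20.00           C",
    "TER",
    "HETATM   13  O   HOH A 101      20.000  20.000  20.000  1.00 30.00           O",
    "HETATM   14 ZN    ZN A 102      21.000  21.000  21.000  1.00 31.00          ZN",
    "ENDMDL",
    "ATOM     15  CA  TRP A  50      99.000  99.000  99.000  1.00 99.00           C",
    "END"
  )
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

random_aa_string <- function(n, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
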