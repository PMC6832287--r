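# s1scape

Cross-kingdom comparative analysis of S1 domains in R.

The S1 domain is an RNA-binding variant of the OB-fold: a five-stranded
antiparallel β-barrel with a single α-helix between strands 3 and 4,
found in bacterial ribonucleases, NusA, Tex and ribosomal protein S1, in
eukaryotic exosome and RNA-polymerase-II subunits, and in archaeal exosome
components and aIF2α. Despite very low sequence identity across the three
domains of life, the fold and its RNA-binding surface are strongly
conserved. `s1scape` packages the analyses used to characterize such a
domain family — for structural bioinformaticians who want the whole
comparison pipeline reproducible, offline-testable and scriptable:

* **Sequence**: Needleman–Wunsch global alignment with affine gaps
  (Gotoh recursion, BLOSUM62, gap open 10 / extend 0.5), percent-identity
  matrices with same-protein pair exclusion, progressive multiple alignment
  on a UPGMA guide tree, per-column information content
  *I = log₂20 − H* (bits) and conserved-position calling.
* **Structure**: PDB parsing (first model, first altloc, no
  HETATM/hydrogens), domain slicing by author residue numbers, Kabsch
  superposition *(argmin_{R,t} Σ‖Rxᵢ+t−yᵢ‖²* via SVD with reflection fix),
  sequence-guided Cα RMSD matrices with a medoid reference, and radius of
  gyration *Rg = √(mean‖rᵢ−r̄‖²)* over heavy atoms.
* **Flexibility & composition**: three-class flexibility calling on
  predicted per-residue fluctuations (rigid < 3 Å ≤ moderate ≤ 6 Å <
  flexible), within-domain B-factor z-scores (flexible at z > 1),
  percent-flexibility summaries, order/disorder-promoting residue content,
  and a tie-corrected Kruskal–Wallis H test
  *H = 12/(N(N+1)) Σ nᵢ(R̄ᵢ−(N+1)/2)²* (χ², k−1 df) for cross-kingdom
  comparisons.
* **Trees**: UPGMA dendrograms from identity distances (d = 1 − id/100),
  deterministic tie-breaking, Newick output.
* **Synthetic fixtures**: generators for toy structures with exact target
  Rg and flexible fraction, sequence pairs with exact identity, and null /
  shifted group samples — so every stage is testable without downloads.

A bundled registry (`default_registry()`) lists 24 S1 domains — 9
bacterial, 10 eukaryotic, 5 archaeal — by PDB id, chain, residue range,
kingdom and same-protein group. Structure files themselves are fetched
once with `fetch_structures()` (the only networked step).

## Worked example

A six-entry synthetic registry run through the full pipeline:

```r
library(s1scape)

reg_lines <- c("pdb_id\tchain\tstart\tend\tkingdom\tprotein_name\tgroup",
  "1tb1\tA\t1\t70\tbacteria\ttoy_S1_b1\t.",
  "1tb2\tA\t1\t70\tbacteria\ttoy_S1_b2\t.",
  "1te1\tA\t1\t70\teukaryota\ttoy_S1_e1\t.",
  "1te2\tA\t1\t70\teukaryota\ttoy_S1_e2\t.",
  "1ta1\tA\t1\t70\tarchaea\ttoy_S1_a1\t.",
  "1ta2\tA\t1\t70\tarchaea\ttoy_S1_a2\t.")
regfile <- tempfile(fileext = ".tsv"); writeLines(reg_lines, regfile)
reg <- read_registry(regfile)

pdb_dir <- tempfile("pdb"); dir.create(pdb_dir)
for (i in 1:6)
  make_toy_structure(n_residues = 70, target_rg = 10 + i,
                     flexible_fraction = 0.2, seed = i,
                     path = file.path(pdb_dir, paste0(reg$pdb_id[i], ".pdb")))

report <- run_pipeline(reg, pdb_dir)
print(report)
#> <s1_report> 6 domains
#>   identity: max 20% (1ta2-1tb2), min 11% (1ta1-1te1)
#>   mean pairwise RMSD: 12.89 A
#>   mean Rg: 13.50 A
#>   disorder-promoting content: 34-61%
#>   KW (Rg by kingdom): H = 4.571, p = 0.1017
#>   warnings:
#>    - KW on bfactor flexibility: no rank variation: all values identical
```

Reading the numbers: the toy domains carry unrelated random sequences, so
pairwise identities sit at the ~10–20% noise floor and the rigid-body RMSD
between unrelated random walks is large (12.89 Å) — real S1 domains align
to ~2 Å. Mean Rg is 13.50 Å because the six fixtures were built with
target Rg 11…16 Å ((11+…+16)/6 = 13.5), recovered exactly by
`radius_of_gyration()`. The Kruskal–Wallis p = 0.10 does not reject
identical Rg distributions across the three toy kingdoms; percent
flexibility is identical by construction (20% each), which the KW guard
reports as "no rank variation" instead of testing.

Single operations work standalone:

```r
global_align("FAYK", "FCYK")
#> <s1_alignment> score 18.0, identity 75.0% over 4 columns
#>  FAYK
#>  FCYK
kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#> <s1_kw> H = 7.2000, df = 2, p = 0.02732 (groups: 3/3/3)
```

For the real 24-domain set (network required once):

```r
reg <- default_registry()
fetch_structures(reg, "pdb_cache")
report <- run_pipeline(reg, "pdb_cache")
write_report(report, "s1_report")
```

A command-line wrapper with `fetch` / `identity` / `superpose` / `rg` /
`flex` / `composition` / `kw` / `tree` / `report` / `simulate` subcommands
is installed at `inst/cli/s1scape.R`.

## Vignette

`vignettes/s1scape-methods.Rmd` documents the models, parameter choices,
what the synthetic generator does and does not emulate, numerical
policies and known limitations.
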