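---
title: "s1scape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{s1scape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s1scape)
```

`s1scape` characterizes a family of small RNA-binding β-barrel domains
(S1/OB-fold) across Bacteria, Eukaryota and Archaea: how similar the
sequences are, how similar the folds are, where the flexible regions sit,
and how compact and disorder-prone the domains are. This vignette is the
package's own account of the models behind each stage, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the choices made where the design was genuinely open.

## The dataset model

The unit of analysis is a *domain record*: a PDB accession, one chain,
an inclusive author-numbered residue range, a kingdom label, and an
optional *same-protein group*. Groups mark the same protein solved from
different organisms (the two PNPase entries, the two NusA entries, the
two aIF2α entries, the two Rrp4 entries, the two polymerase-II subunit-G
entries); such pairs are trivially similar and are excluded when the
most- and least-identical pairs are reported, though they stay in the
matrices themselves.

The bundled registry lists 24 domains (9/10/5 per kingdom). Since domain
boundaries are annotation, not structure, the residue ranges are shipped
as *editable configuration* — curated defaults in the style of Pfam S1
profile envelopes — and users are expected to adjust them: a shift of a
few residues changes identity percentages by a point or two and Rg by a
few tenths of an Å. The chain letters for the four large cryo-EM
complexes in the set are likewise best-effort defaults; verify them
against the deposited entry before interpreting per-entry numbers.

## Sequence comparison

Pairwise alignment is global Needleman–Wunsch with affine gaps solved by
the three-state Gotoh recursion (implemented in C++). A gap run of
length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$; end gaps are
penalized, which is appropriate because domains are pre-sliced to
comparable spans. Defaults are the classic global-aligner settings —
BLOSUM62, open 10, extend 0.5 — exposed through `scoring_scheme()`.
Unknown residues (`X`) score 0 against everything. Traceback ties break
deterministically: diagonal, then up, then left.

Percent identity is `100 × identical columns / alignment length`,
including gap columns in the denominator. This is a genuine choice — the
literature also divides by the shorter sequence — and the alternative is
selectable (`identity_denominator = "shorter"`). With unrelated ~70-mers
the default definition sits near a 10–15% noise floor; this matters when
reading the low end of the identity matrix.

The multiple alignment is progressive: pairwise identities define
distances $d = 1 - \mathrm{id}/100$, a UPGMA guide tree orders the
merges, and profiles are aligned profile-to-profile with
average-of-pairs substitution scores (gap symbols contribute zero) under
the same gap penalties. This replaces an external MSA service with
something deterministic and testable; on small related families it
reaches the exhaustive sum-of-pairs optimum (see the test suite), but it
is a heuristic and makes no optimality guarantee.

Conservation is summarized per alignment column as information content
$I = \log_2 20 - H$ bits, $H$ the Shannon entropy of the non-gap residue
frequencies, without small-sample correction; all-gap columns carry 0
bits. `conserved_positions()` calls columns whose modal non-gap residue
frequency reaches a threshold, default 0.8 — "highly conserved" is not a
number anywhere, so 0.8 was fixed once as a reasonable reading and left
alone. Positions are alignment-column numbers, not residue numbers of
any one sequence.

## Structure comparison

Superposition is rigid-body least squares (Kabsch): SVD of the
cross-covariance matrix with the determinant correction so reflections
are never returned. Correspondence between two domains comes from the
ungapped columns of their global sequence alignment, restricted to
residues that have Cα atoms; fewer than 10 matched pairs attaches a
warning to the result rather than failing. Group superposition picks the
medoid (minimum mean pairwise RMSD) as the reference — deterministic and
cheap, at the cost of not iterating toward a mean structure.

Because the correspondence is sequence-guided and the fit is rigid,
RMSD values are comparable to, but not identical with, flexible
structure-alignment servers: flexible alignment bends at hinges and
reports lower deviations. Printed family means (~2 Å) are therefore
matched only within a stated tolerance (±0.3 Å in the acceptance
criteria), never exactly.

Radius of gyration is the root-mean-square distance of all heavy atoms
from their centroid, **unweighted by mass**. Mass weighting changes Rg
by well under 1% for proteins; unweighted matches the "collection of
atoms" definition and keeps the scaling law $R_g(kx) = kR_g(x)$ exact.

## Flexibility

Two sources, deliberately kept distinct:

* **Predicted fluctuations** (Å, absolute): read from external
  two-column tables (FlexPred-style SVR output; the predictor itself is
  *not* re-implemented — its trained weights are not reproducible from
  the literature). Classes: rigid < 3 Å, moderate 3–6 Å (boundaries
  inclusive), flexible > 6 Å.
* **Crystallographic B-factors** (Å², relative): standardized within the
  domain as population z-scores of the Cα B column; flexible at z > 1,
  moderate 0 ≤ z ≤ 1, rigid z < 0. B-factors have no absolute
  fluctuation scale and absorb refinement and resolution artifacts, so
  z-scores are the defensible normalization; published percentages
  computed with an unstated B-factor rule are consequently *not*
  comparable numbers and are not treated as targets.

`percent_flexible()` counts only the strictly flexible class — the most
literal reading of "most flexible domain" — with
`include_moderate = TRUE` as the alternative. A mathematical consequence
of the z > 1 rule worth knowing: no distribution can place more than
half its mass above mean + 1 sd (one-sided Chebyshev), so B-factor
percent flexibility is bounded by 50%, and the synthetic generator
refuses flexible fractions at or above that bound.

## Composition and statistics

Residues split into order-promoting {C, W, F, I, Y, V, L, H, T, N} and
disorder-promoting {D, M, A, R, G, Q, S, P, E, K} sets by their relative
abundance in ordered versus intrinsically disordered proteins; `X` is
excluded from numerator and denominator, so order% + disorder% = 100 for
X-free sequences.

Cross-kingdom comparisons use the Kruskal–Wallis rank test with
mid-ranks for ties and the tie-correction factor
$1 - \sum(t^3 - t)/(N^3 - N)$, referred to $\chi^2_{k-1}$. With group
sizes around 9/10/5 the chi-square approximation is standard and its
empirical type-I error is ~0.045 at nominal 0.05 (calibrated by
simulation in the acceptance tests); an exact permutation p-value of H
is available via `n_perm` for smaller groups. Degenerate input — all
values identical — is an error, not a p-value of 1: with n = a few
dozen, "no rank variation" almost always means a units or plumbing
mistake upstream.

## Dendrograms

Trees are descriptive output, not phylogenetic inference. UPGMA on
$d = 1 - \mathrm{id}/100$ gives an ultrametric, rooted, deterministic
dendrogram; ties on the minimum distance break lexicographically on
cluster labels so the same matrix always yields the same Newick string
(branch lengths to 6 decimals). On an exactly ultrametric input UPGMA
reconstructs the cophenetic matrix exactly, which is the main
correctness test. Neighbor-joining is available behind
`method = "nj"` for users who prefer an additive-tree view. No
bootstrap, no likelihood: at 5–50% identity over ~70 residues a
distance dendrogram supports qualitative statements ("these two exosome
components cluster together"), nothing stronger.

## The synthetic generator: what a green test establishes

`make_toy_structure()` builds an N/CA/C/O backbone along a compact
random walk, rescales about the centroid so the all-atom Rg equals the
target *exactly* (to 1e-9 in the returned structure; a re-parsed PDB
file recovers it to ~1e-4 because PDB fixed columns quantize
coordinates to 0.001 Å — a format limit), and fills the B column so
that exactly `round(f·n)` residues exceed the z > 1 threshold.
`make_sequence_pair()` mutates exactly `round((1−id)·L)` positions,
never back to the original residue, so ungapped identity is exact by
construction; note that below ~50% identity the *optimal affine-gap
alignment* of such a pair may legitimately introduce gaps and report a
slightly different percentage — the generator's contract is ungapped
identity, not alignment behaviour. `make_group_samples()` draws
location-shifted normals for power/calibration studies.

Defaults mirror the real dataset's stated world: 70-residue domains,
target Rg 12 Å, moderate flexible fractions, group sizes 9/10/5. What
the toys do **not** emulate: β-barrel geometry, protein-like
stereochemistry, related sequences, missing residues, altlocs, or NMR
ensembles. A green synthetic test therefore establishes that the
*measurement operators* are correct (Rg, z-classification, identity,
superposition), not that the pipeline's biological numbers are right —
those depend on real coordinates, which are fetched once from the PDB
and are the subject of the separate paper-number acceptance tests.

## Numerical policies and degenerate inputs

* PDB parsing: first model only, first-listed altloc, no HETATM, no
  hydrogens; residues keyed by author number + insertion code; missing
  residues inside a slice are tolerated (unmodelled loops), an empty
  slice is an error.
* Kabsch: < 3 pairs or a rank-deficient (collinear) point set is an
  error naming the condition.
* Zero-variance B columns (common in coarse cryo-EM depositions) are an
  explicit "uninformative B-factors" error; the pipeline logs the entry
  in the report's warning list and continues.
* All randomness goes through explicit integer seeds; the generators
  save and restore the caller's RNG state.
* TSV outputs are unrounded; only the human-readable summary rounds
  (identity to whole percent, RMSD/Rg to 0.01 Å).

## Known limitations

* Rigid, sequence-guided RMSD under-rates similarity between domains
  related by hinge motion, and over-rates dissimilarity when the
  sequence alignment misplaces the correspondence at very low identity.
* The progressive MSA is a guide-tree heuristic; column numbering of
  conserved positions is alignment-relative and changes if the input
  set changes.
* Identity percentages depend on the gap parameters and the denominator
  definition; both are configurable, and cross-study comparisons should
  state them.
* The bundled residue ranges and chains are curated defaults, not
  author-certified boundaries; per-entry numbers inherit that
  uncertainty (family means are robust to it).
* Predicted-fluctuation analyses consume external tables; the package
  ships no fluctuation predictor.
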