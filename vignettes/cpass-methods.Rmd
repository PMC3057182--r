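---
title: "Comparing ligand-defined binding sites: the model behind cpassr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ligand-defined binding sites: the model behind cpassr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpassr)
```

## The problem and the model

A large fraction of sequenced proteins carry no functional annotation, and
global sequence or structure comparison often fails precisely where
annotation is most needed. Ligand-binding sites, however, are more
evolutionarily stable than the rest of the fold: two proteins that bind the
same cofactor in geometrically and chemically similar pockets very likely
share a function. `cpassr` implements the CPASS approach (Comparison of
Protein Active-Site Structures, v.2): compare *experimentally*
ligand-defined binding sites — the set of residues with any heavy atom
within 6 Å of a bound ligand's heavy atoms — across structures, with no
regard for sequence order or global topology.

Two sites $a$ (the query, $n$ residues) and $b$ ($m$ residues) are compared
through a one-to-one residue correspondence and a rigid transform. The v.2
similarity score is

$$
S_{ab} \;=\; \log_5\!\big(5-\Delta\mathrm{RMSD}_{lig}\big)\;
\sum_{i,j} \frac{d_{min}}{d_i}\,
\big(\log_{10}(100-\Delta\mathrm{SASA}_{i,j})-1\big)\,
\big(e^{-\Delta\mathrm{RMSD}_{i,j}}\big)^2\, p_{i,j}
$$

with the sum over matched pairs $(i, j)$ and

* $p_{i,j}$ — the BLOSUM62 *replacement probability* of the two residue
  types. We use the published target (joint) frequency table $q_{ij}$, not
  the integer log-odds: probabilities are positive and on a common scale,
  so multiplying them by penalty factors in $[0,1]$ is meaningful. A unit
  test confirms the embedded table reproduces the integer BLOSUM62 matrix
  through $s_{ij} = \mathrm{round}\,2\log_2 q_{ij}/(p_i p_j)$ within the
  resolution of its four published decimals.
* $d_{min}/d_i$ — the distance weight, taken from the **query** site:
  $d_i$ is residue $i$'s shortest heavy-atom distance to the ligand and
  $d_{min}$ the smallest such distance in the site. The residue closest to
  the ligand weighs 1; residues near the 6 Å edge contribute little, which
  damps the effect of borderline inclusion/exclusion. Because the weights
  come from the query, $S_{ab} \neq S_{ba}$ by design.
* $\Delta\mathrm{RMSD}_{i,j}$ — the per-pair RMSD over Cα *and* Cβ
  positions (Cα only when either residue is glycine or lacks a Cβ record),
  reduced by 1 Å and floored at 0. The resulting factor
  $\exp(-\Delta\mathrm{RMSD}^2)$ is free within 1 Å — absorbing typical
  experimental coordinate error — and decays fast: below 0.11 by 2.5 Å,
  the scale beyond which two sites are simply not similar.
* $\Delta\mathrm{SASA}_{i,j}$ — the difference in *relative* solvent
  accessibility (percent). The factor $\max(0, \log_{10}(100-\Delta)-1)$
  is 1 at no difference, drops steeply past 60 points (the
  buried-versus-exposed distinction), and reaches 0 at 90.
* $\Delta\mathrm{RMSD}_{lig}$ — the inter-ligand RMSD under the site
  transform, mapped from the smaller ligand's heavy atoms to the nearest
  heavy atoms of the larger (extra atoms ignored), reduced by 0.5 Å. The
  global factor $\log_5(5-\Delta)$ is 1 within 0.5 Å raw RMSD and 0 from
  4.5 Å. The ligands play no part in the alignment itself, so their
  post-hoc overlap is independent evidence that two pockets agree.

Version 1 of the score is recovered by `score_options(version = "v1")`:
Cα-only distances, no SASA term, no ligand term.

Results are reported as **percent similarity** $100\,S_{ab}/S_{aa}$, the
score relative to the query's self-comparison. Self-comparison is exactly
100 because every penalty sits in its free region. Scores above ~30
suggest functional similarity; true negatives in library searches peak
near 10.

### Reading the exponent

The published form of the per-residue factor, $(e^{-\Delta\mathrm{RMSD}})^2$,
is typographically ambiguous. We read it as the Gaussian
$\exp(-\Delta\mathrm{RMSD}^2)$, because the stated anchor behaviour — an
insignificant contribution beyond 2.5 Å, i.e. a corrected RMSD of 1.5 Å —
matches $\exp(-1.5^2) \approx 0.11$, while $\exp(-2\cdot 1.5) \approx 0.05$
would already be negligible at 2 Å. The alternative reading
$\exp(-2\Delta)$ stays available as
`score_options(residue_penalty = "double_exp")` for comparison.

### Manual sites

When no co-structure exists, a site can be declared as a plain-text residue
list (`AA NUMBER CHAIN` per line). The ligand reference point is replaced
by the listed residues' heavy-atom center of mass (unweighted over heavy
atoms — the natural reading of "center of mass" without an atom
selection), $d_i$ is measured to that point, and the ligand factor is
disabled — also whenever *either* site of a comparison lacks a ligand.

## Site extraction and SASA

`extract_site()` takes every standard amino acid with at least one heavy
atom within the cutoff (default 6 Å) of any ligand heavy atom; hydrogens
never participate in distances. Relative SASA is computed on the
*ligand-free* protein: all heteroatoms and any bound polymer chain of at
most 13 residues are stripped first, so accessibility reflects the apo
state.

The SASA engine is an in-package Shrake–Rupley implementation: probe
1.4 Å, 960 deterministic golden-spiral test points per atom, element radii
C 1.87 / N 1.65 / O 1.40 / S 1.85 / P 1.90 Å, and per-residue areas
normalized by extended Ala-X-Ala tripeptide reference areas. Values are
clamped to [0, 100] (distorted termini can exceed their reference area,
and the SASA penalty's domain ends at 100). The test suite pins the engine
against an independently computed Shrake–Rupley reference (identical
radii, probe and point count) at better than 2% per residue; agreement
with other radii conventions will be looser, which is why tests are
tolerance-based rather than bit-exact.

## The alignment search

The method's definition of the best alignment is score-driven: the
correspondence and transform that maximize $S_{ab}$, ignoring sequence
order, one-to-one, with at least 3 pairs (a rigid transform is
underdetermined below that). The search is a deterministic heuristic:

1. **Seeds.** Candidate correspondences $(i, j)$ are ranked by
   replacement-favourable identity ($q_{ij}$ above the product of
   marginals). Triplets of mutually compatible correspondences (pairwise
   Cα–Cα distance discrepancy ≤ 1.5 Å) form seeds, ranked by favourable
   count then geometric discrepancy, capped at `max_seeds` (500). Small
   problems are seeded exhaustively with *every* triplet, which is what
   lets an enumeration oracle certify the search on small sites.
2. **Per seed.** Kabsch-superpose the triplet; then (a) a *growth ladder*
   adds one pair at a time — always the largest score contribution under
   the current refitted transform; (b) a maximum-weight bipartite
   assignment (Hungarian-style, via `igraph`) on the full contribution
   matrix proposes a saturated matching, re-superposed and iterated to
   convergence (≤ 20 iterations); (c) a *prune ladder* drops the weakest
   pair stepwise down to size 3. Every candidate matching met along the
   way is scored with its own least-squares transform.
3. **Winner.** The highest-scoring candidate over all seeds wins; exact
   ties go to the lexicographically smallest pair list, so results are
   reproducible to the byte. Seeds scoring far below the incumbent
   (`ladder_prune`, default 25%) skip the ladders — a pure speed device
   whose effect is checked by the oracle-equality tests.

`brute_force_alignment()` enumerates *all* partial matchings of size ≥ 3
(sites of at most 6 residues), scoring each with its own transform — the
independent oracle. The suite requires heuristic = oracle to $10^{-6}$ on
randomized small-site pairs, and score invariance to $10^{-6}$ under rigid
motion of either input.

Open choices resolved here: matching is one-to-one (not one-to-many), and
superposition is unweighted least squares (not $d_{min}/d_i$-weighted) —
the simplest readings consistent with the description.

## Database, search modes, evaluation

A library entry is one (structure, ligand) pair whose extracted site is
non-empty. Ligands are heteroatom groups not on an editable exclusion list
(water always excluded; buffers, cryoprotectants and lone ions by
default), or bound polymer chains of ≤ 13 residues when a longer receptor
chain is present. Two records are **duplicates** only if they share the
ligand code *and* have ≥ 90% global sequence identity (Needleman–Wunsch,
BLOSUM62, gap 10/0.5, identity over alignment length) *and* ≥ 80% residue
identity across the aligned site (relative to the smaller site). The
first-seen record survives; shuffling input order changes the surviving
representative, never the count. Records serialize to one diff-able text
file each plus a manifest.

Searches run in four modes (one-vs-all, single pair, one-vs-list,
list-vs-list over database records), with optional ligand-code filtering
and a reporting threshold (default 30%, never applied at scoring). Work
partitions into independent chunks over targets; scoring is deterministic,
so chunked, parallel and serial runs produce byte-identical tables.

Evaluation mirrors the standard protocol: three true-positive definitions
(identical 4-component E.C. number plus equivalent ligand; identical first
3 E.C. components; same ligand class), ROC curves swept over the full
score range with trapezoid AUC, and per-class score distributions at bin
width 10, each class normalized to unit area (scores ≥ 100 fall in a final
closed bin). "Very similar ligand" has no published metric, so ligand
equivalence is a user-supplied table (e.g. ATP ≈ ADP). E.C. annotations
are supplied per record; there are no live lookups.

## The synthetic-structure generator

Because the package must be testable without downloading structures, the
fixtures module generates PDB-writable protein–ligand scenes: a compact
ligand at the origin; site residues on well-separated directions with a
side-chain contact atom at a controlled distance of 3.2–5.0 Å (inside the
6 Å cutoff), Cβ at 1.53 Å from Cα; optionally a decoy shell beyond 6.5 Å
that must never be extracted. Relative SASA can be injected directly so
scoring tests stay analytic. All output is deterministic per seed.

The decoy library plants near-copies of a query at graded noise
σ ∈ [0.1, 0.3] Å — inside the experimental-error scale the score's
non-penalty regions (0.5 Å ligand, 1 Å residue) are designed to absorb,
which is what "functionally identical sites from independent experiments"
means under this model — alongside unrelated random sites with random
accessibility patterns and mixed ligand codes. On this library the v.2
terms cut the fraction of decoys above the 20% reporting region while
moving planted positives by under 5% relative, and ROC AUC against the
planted truth exceeds 0.9.

What the generator does **not** emulate: real side-chain rotamers, ligand
chemistry (decoy "ligands" are generic atom clusters), correlated backbone
motion, crystallographic artifacts, or realistic sequence context
(database sequences are random). Passing tests therefore certify the
*method's mechanics* — extraction rules, score algebra, alignment
optimality on small problems, determinism, evaluation arithmetic — not
biological benchmark performance. The reference comparison of an
aspartate-aminotransferase PLP site against four PLP-dependent enzymes
(`cpass_benchmark()`) runs only when the user supplies the five
experimental structures; its expected percent ladder spans ~83% down to
~31% with rank order preserved, within a ±10-point documented tolerance
that acknowledges the alignment algorithm is only qualitatively specified.

## Numerical choices and problem sizes

* Penalties are evaluated in closed form; the only iterative numerics are
  3×3 SVDs (Kabsch) and the assignment solver, both exact to machine
  precision for these sizes.
* Score ties at $10^{-12}$ break lexicographically; candidate caching
  keys on the canonical pair list.
* Relative SASA > 100 clamps to 100; $d_i$ floors at $10^{-6}$ Å.
* Default test problem sizes — sites of 3–7 residues, libraries of 10–200
  records, 20-replicate noise ladders — were chosen so the whole suite
  exercises every module (including exhaustive oracles, which grow
  factorially) in a few minutes on one core.

## Known limitations

* The exact probability table, percent normalization (query self-score
  here; `percent_norm = "max"` available) and SASA clamping convention of
  the original service are unpublished; scores can differ in detail even
  where anchors agree.
* The heuristic is certified optimal only where the oracle can reach
  (small sites); for large sites optimality is heuristic, with
  `max_seeds`, `dist_tol` and `ladder_prune` as the accuracy/cost dials.
* No mmCIF input, no symmetry/assembly expansion, no E-value model for
  scores, and no rebuild of a full PDB-scale library in-package (supported
  in principle through `build_database()` over any structure set).
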