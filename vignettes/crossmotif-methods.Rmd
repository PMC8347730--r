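---
title: "Methods: cross-family protein motif analysis with crossmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-family protein motif analysis with crossmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmotif)
```

## The question

Several unrelated protein families can be reported as receptors for the same
ligand — here the motivating case is a small glycan bound by members of the
laminin, cadherin and high-mobility-group-box families. If such families
shared a common binding module, one would expect a short sequence motif to
recur across them. `crossmotif` implements the full analysis needed to ask
that question reproducibly: collect large families of homologues, reduce
each family to an evenly spread set of representatives, align and build
trees, profile per-column conservation, discover motifs within and across
families with expectation maximization, and decide whether any motif is
genuinely shared rather than private to one family.

Because the original inputs are large public-database harvests, the package
ships a synthetic-family generator that emulates their statistical structure
(mutually unrelated ancestors, within-family divergence, redundancy,
optionally planted motifs with known ground truth). All tests and the
bundled acceptance analysis run on generated families, so the positive and
negative controls are verifiable without any download.

## The synthetic-family generator

`sim_config()` + `simulate_families()` produce families of protein sequences
by (i) drawing an independent uniform-random ancestor per family, (ii)
diverging each member by per-site substitutions (uniform over the 19
alternative residues) and indel events with geometric lengths (mean
`indel_length_mean`, capped at 10), and (iii) inserting realized instances of
degenerate motif patterns (`motif_plant()`), with truth coordinates recorded
per copy.

Key choices, fixed once:

* **Occupancy is an exact count** `round(occupancy * n)`, not a Bernoulli
  draw, so recovery tests are not flaky.
* **Default `substitution_rate = 0.3`** expected substitutions per site.
  The real harvests accepted homologues at extremely conservative
  similarity cut-offs, which implies clearly alignable but diverged members;
  0.3 gives roughly 70–75% within-family identity, a realistic middle
  ground. This is a package choice — the source data were characterized
  only by the acceptance cut-off, not by a divergence level.
* **Planted instances are inserted, not overwritten**, at least one residue
  from either end, never splitting an earlier copy; coordinates refer to
  the final sequence and are shifted when a later copy lands upstream.
* **`anchor = "random"` vs `"fixed"`.** By default each copy lands at a
  uniform random interior position, which is the right null for motif
  *discovery* (EM does not use position). For *alignment* experiments a
  randomly placed insertion can never stack into common columns — the
  homologous flanks dominate the alignment — so `anchor = "fixed"` plants
  the first copy of every carrier at one ancestor position per family,
  mapped through each sequence's indels, emulating a positionally conserved
  motif.
* One global seed; each family uses a sub-stream at a fixed offset, so
  adding a family never changes earlier families.

The generator does **not** emulate tree-structured evolution, rate
heterogeneity across sites, empirical exchangeabilities (substitutions are
uniform) or biased residue composition (backgrounds are near-uniform).
Passing controls on these families therefore demonstrate the pipeline's
statistical behaviour under clean homology + noise, not performance on real
proteomes with low-complexity regions or domain shuffling.

## Redundancy reduction

Families are compared by a k-mer set dissimilarity
`d = 1 − |Ka ∩ Kb| / min(|Ka|, |Kb|)` (default `k = 3`; at the family scale
the 8,000-word tripeptide vocabulary is informative and fast). Reduction to
`k` representatives sorts all pairs by ascending dissimilarity and walks the
list from the most similar pair downwards, removing one member of every
pair whose members both survive, until the target count remains. The member
removed is the one with the **smaller total distance to all current
survivors** — the more central sequence — so outliers persist and the
representative set keeps an even spread; ties remove the lexicographically
larger ID, and the pair ordering breaks distance ties lexicographically, so
the whole procedure is deterministic. On a one-dimensional toy metric the
greedy walk provably returns the extreme points; on random matrices it is
within a factor ~0.8 of the brute-force max–min 2-subset (asserted in the
tests; greedy is not optimal in general).

`select_nearest()` implements the complementary view: the n sequences most
similar to a chosen reference (the reference counted), used to focus
conservation displays on a protein's close homologues.

## Trees and progressive alignment

Neighbor joining (via **ape**, negative branch lengths clamped to zero)
builds trees from any distance matrix; merged multi-family sets yield one
clade per family when the families are unrelated, which is the package's
re-statement of the "three unrelated groups" observation.

`progressive_align()` is a guide-tree progressive profile aligner: the
(midpoint-rooted) NJ tree of the k-mer distances is traversed in post-order,
and at each node the two child alignments are merged by affine-gap dynamic
programming over their column frequency profiles. The profile–profile score
is the expected pairwise BLOSUM62 substitution score, with the gap treated
as a 21st frequency of substitution score zero. Gap costs follow the
Biostrings convention — a gap of length L costs `open + L·extend`, defaults
11/1 — which makes the two-sequence case *exactly* equal to
`Biostrings::pairwiseAlignment`, the independent oracle used in the tests.
Iterative refinement and consistency objectives are out of scope; this is a
deliberately plain progressive aligner for desk-scale sets (≤ ~2,000 rows).

## Conservation

Per-column variability is the normalized Shannon entropy
`S = −Σ p_a log20 p_a` over the 20 amino-acid types, so `S = 0` is a fully
conserved column and `S = 1` the uniform distribution. Gaps are excluded
and `p_a` renormalized over the residues present (the gap fraction is
reported separately; columns under 20% occupancy are flagged low-coverage);
all-gap columns have undefined entropy, reported as `NA` rather than a
number. Non-canonical codes (B, Z, X, U) are excluded from the
distributions.

`mask_to_reference()` and `map_reference_span()` convert between alignment
columns and one protein's own residue numbering (1-based inclusive
throughout), which is how a binding-site span such as residues 2454–2474 is
examined inside a large alignment. `consensus_pattern()` condenses a column
span into a degenerate pattern: a fixed letter when the top residue reaches
`t_fix` (default 0.7), a 2–3 residue bracket class when the top residues
jointly reach `t_class` (default 0.8; members listed by descending
frequency, alphabetical on exact ties), otherwise `X`. The thresholds are
exposed because the field's published consensus strings rarely state the
rule that produced them; this rule is one defensible formalization.

## Motif discovery

`em_motif()` fits the ZOOPS model — zero or one motif occurrence per
sequence — by expectation maximization: a width-W position probability
matrix (PPM) against a 0-order background, a global occupancy prior γ,
per-site and per-sequence posteriors in the E-step, Dirichlet-smoothed
(pseudocount 0.01) PPM and γ updates in the M-step. The tracked objective
is the MAP objective (data log-likelihood plus the PPM and γ priors), which
is non-decreasing under EM; every test asserts the monotonicity. Repeated
within-sequence copies (e.g. a motif recurring once per structural domain)
are intentionally not part of the EM model — they are recovered afterwards
by `scan_motif()`, which reports all windows above threshold.

**Starting points.** Candidate substrings are sampled from the data, each
seeds a PPM (matched residue probability 0.5), and candidates are ranked by
their total cross-sequence support (the sum over sequences of the best
window log-odds). The best `n_starts` get a 5-iteration EM and the winner
continues to convergence. Ranking candidates instead by background
surprisal is useless here: with near-uniform backgrounds every substring is
about equally surprising, so support against the other sequences is what
identifies a planted or conserved word.

**Width selection and masking.** `discover_motifs()` fits a coarse width
grid over [6, 30] (6, 8, 11, 15, 21, 30), refines ±2 around the winner
(by permutation E-value when enabled, ties and the default by
log-likelihood-ratio per column), then masks the winning occurrences —
masked positions are excluded from candidate windows, posterior windows and
background re-estimation — and repeats for the next rank.

**Significance.** Analytic motif E-values are deliberately not reproduced:
they are formula- and database-specific, and astronomically small values
(e.g. 10^−300) are meaningless at desk scale. Instead
`permutation_evalue()` shuffles residues within each sequence B times,
refits the same single-width EM on each shuffle and reports
`E = n_tests · (1 + #{llr_null ≥ llr_obs}) / (B + 1)`. This is the package's
only significance currency; with `B = 99` the smallest attainable E-value
is 0.01.

**Scan threshold.** `scan_motif()`'s default threshold is the log-odds
score whose chance probability per window under the motif's background is
10^−4 (the conventional scanning p-value), computed by exact discretized
convolution of the per-column score distributions. Fraction-of-maximum
thresholds were rejected: they let diffuse motifs collect chance and
homology hits, which corrupts the coverage statistic below.

## The shared-motif decision

`shared_motif_search()` pools families (the full set and, optionally, every
unordered pair), discovers motifs in each pooled set and calls a motif
**shared** only if all three hold:

1. **Coverage**: at least `c_min` (default 0.25) of the sequences of
   *every* family in the pool carry a scan hit. This blocks a motif private
   to one family plus a handful of chance sites.
2. **Coherence** (default ≥ 0.5): for every family pair, the per-family
   modal residues of the hit windows agree in at least half the motif
   columns. This guards a real degeneracy of mixture-model discovery on
   pooled homologous families: EM can converge to a *blend* whose bimodal
   columns superimpose two families' private conserved windows. A blend
   covers both families — every family is internally conserved somewhere —
   yet its hits share almost no residues across families (agreement ≈ the
   chance level, ~0.05–0.35 in the calibration runs, versus 0.8–1.0 for a
   genuinely planted shared motif). Without this criterion the negative
   control fails.
3. **Significance**: permutation E ≤ `alpha` (default 0.01), computed only
   for motifs that already pass (1) and (2), since it cannot change the
   verdict otherwise.

`compare_motif_sets()` reproduces the sliding-window comparison of
per-family motif sets: every cross-family pair of motif consensus strings
is aligned ends-free under BLOSUM62 (open 11 / extend 1) via
`Biostrings::pairwiseAlignment`, and the top pairs are reported with their
aligned strings. PPM-level correlation is intentionally not the primary
mode: the consensus-string alignment matches how such comparisons are
displayed in practice. No automated call of "biological meaning" is made
from weak top-scoring similarities; the table is the deliverable.

`run_pipeline()` chains both branches — reduction → merge → NJ tree, and
realignment → conservation → per-family motifs → pooled/pairwise
shared-motif search → comparison tables — writing every artifact (FASTA,
Newick, TSV, MEME-minimal motif files) plus a manifest of parameters and
seeds; any stage failure aborts with the stage name and a partial manifest.

## Numerical choices and edge cases

* Coordinates are 1-based inclusive everywhere.
* Alignments never contain all-gap columns; ungapping any row reproduces
  its input sequence exactly (asserted across all tests).
* EM log-sum-exp is used for posterior denominators; the objective
  tolerance is `tol = 1e-6` absolute, `max_iter = 100`.
* γ is kept strictly inside (0, 1) by its Beta(1.1, 1.1) prior; the PPM by
  its pseudocount. Both priors are part of the tracked objective, so
  monotonicity is exact up to floating-point noise.
* Distance ties in reduction and nearest-selection break lexicographically;
  all stochastic steps take explicit seeds, and derived sub-seeds keep every
  stage reproducible end to end.

## Problem sizes used by the tests

The test-suite calibration runs use sizes chosen to keep the whole analysis
on one desk-scale CPU while preserving the counts that matter: reduction is
exercised at 2,000 → 400 (sequence length ~300) and 6,000 → 5,000 (length
120); the merged set at 3 × 5,000 = 15,000; nearest-selection at 700 of
1,000; motif recovery at 100 sequences × 300 residues with a width-15 plant
at occupancy 0.9 and degradation 0.1 (20 replicates, default EM settings —
the start-point search depth matters here, since the planted motif competes
with the family's own ancestral conservation); the 30-motifs-per-family
comparison at 3 families × 50 sequences × 400 residues; verdict calibration
at 3 families × 30 sequences × 120 residues with B = 99 permutations
(20 negative and 20 positive replicates).

## Known limitations

* The aligner is strictly progressive; badly misaligned deep splits are
  not revisited.
* The permutation null (within-sequence shuffling) preserves composition
  but not local autocorrelation; motifs reflecting compositional bias would
  need a higher-order background.
* The reduction approximates the original "fast alignment" dissimilarities
  with k-mer distances; the published removal rule was not specified beyond
  the sorted-pair walk, so the centrality-based removal here is one
  concrete, deterministic realization.
* ZOOPS is the only EM model; OOPS and multi-occurrence EM variants are out
  of scope, as are gapped motifs.
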