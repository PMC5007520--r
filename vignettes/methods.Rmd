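---
title: "Methods: gene-family characterization on synthetic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization on synthetic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`genefam` re-implements the classic genome-wide gene-family survey — the
workflow used to characterize families such as the plant small
heat-shock proteins (Hsp20), whose membership criterion is a single
conserved alpha-crystallin domain — as a set of composable, tested
stages.  This vignette records the models behind each stage, the
parameters that matter, the numerical choices, and the design decisions
taken where the workflow as usually practiced leaves them open.  It
states no empirical result beyond what the package's own test suite and
`scripts/acceptance.R` compute.

## 1. Domain-based identification

**Model.** Family membership is decided by a gapless position-specific
log-odds profile: from a seed alignment (columns with more than 50% gaps
dropped), each retained column scores residue $a$ as
$\log_2 \frac{(c_a + 0.5)/(n + 10)}{b_a}$ bits, with a Jeffreys
pseudocount of 0.5 per residue and background $b$ (uniform by default).
Every window of a candidate protein is scored by summation; `X` and
other non-standard residues score 0 (background-neutral) at every
position.

A full profile HMM with insert/delete states was deliberately not built:
the family domains this pipeline targets are compact and well conserved,
so gapless window scanning loses little, and the simpler model admits an
exact self-consistency test (the consensus achieves the maximum possible
window score).  The simplification matters for families with frequent
domain indels, and is the first thing to revisit for such data.

**E-values.** Rather than importing an external search tool's e-value
machinery, significance is calibrated empirically: 10,000 decoys
(shuffles of the scanned proteins, or background draws) are scanned, the
per-decoy best window scores are fitted with a Gumbel distribution by
the method of moments ($\beta = s\sqrt{6}/\pi$,
$\mu = \bar{x} - \gamma\beta$), and the e-value of score $s$ in a
database of $N$ sequences is $N \Pr(S \ge s)$ under that fit.  The test
suite checks that observed decoy tail frequencies match the fitted
e-values within binomial error.  The identification gate is
`E < 1e-10`.  Extrapolating a moment-fitted Gumbel to $10^{-10}$ is
aggressive, but the decision boundary sits far from both score
populations (planted domains score hundreds of bits above decoys), so
recall/precision are insensitive to the exact tail shape; the
calibration test only probes the fit where decoy counts exist.

**Selection rule.** Exactly one passing, non-overlapping hit (overlaps
resolved best-score-first, ties to the leftmost window) accepts a
candidate; none rejects it as domain-free; two or more reject it as
multi-domain — multi-domain architectures are excluded from the family
by convention.  How multi-domain proteins are detected is not pinned
down by the original workflow; the non-overlap + per-hit-threshold rule
is this package's choice.

**Protein statistics.** Molecular weight is the sum of average residue
masses plus one water; `X` contributes the mean residue mass.  The
isoelectric point solves Henderson–Hasselbalch net charge = 0 (EMBOSS
pKa set, both termini included) by bisection on pH to
$|q| < 10^{-4}$.

## 2. Alignment, phylogeny, subfamilies

**Aligner.** Progressive alignment along an NJ guide tree of 3-mer
composition distances, merging profiles by affine-gap dynamic
programming (BLOSUM62; gap open 10, extend 0.5 — the classical
defaults of the tool family this emulates; a gap of length $L$ costs
$10 + 0.5L$, matching the pairwise engine used for `align_pair`).
Column scores between profiles are expected BLOSUM scores under the
column residue frequencies (gaps contribute zero).  No iterative
refinement is performed.  The pairwise primitive is checked against
exhaustive alignment enumeration on short strings.

**Distances.** Pairwise Poisson-corrected p-distances,
$d = -\ln(1-p)$, ignoring columns gapped in either row.  The distance
model used by the original tools is typically unstated; Poisson is the
standard protein default.  $p \ge 0.95$ is capped at $d = 3$ with a
warning — beyond that the correction explodes and NJ becomes
meaningless anyway; a pair with no comparable sites is an error, not a
guess.

**Trees.** Saitou–Nei neighbor joining, $Q_{ij} = (n-2)d_{ij} - r_i -
r_j$, ties broken by the lexicographically smallest pair so runs are
exactly reproducible.  Negative branch lengths are clamped to zero with
the deficit moved to the sister edge (total path length conserved).
The NJ consistency property — additive matrices are reconstructed with
exact topology and path lengths — is tested over random trees up to 12
leaves, and the topology is cross-checked against the independent
implementation in `ape`.

**Bootstrap.** Columns resampled with replacement, NJ per replicate,
internal-edge support = percentage of replicates containing the same
unrooted bipartition (canonical split keys).  Default 1000 replicates;
edges below 50% support are collapsed into multifurcations (the
collapsed edge's length is discarded, as in consensus-style displays).
The boundary is strict: support 49 collapses, 50 survives.

**Subfamilies.** Queries take the label of the smallest supported clade
(either side of an internal edge at support ≥ 50; leaf edges count as
trivially supported) containing the query and references of exactly one
label; queries in no such clade are orphans.  Note that orphan status
is only reachable when at least three labels surround the query (with
two labels, every edge splits them cleanly), which matches how isolated
long-branch genes behave after low-support edges are collapsed.
Assignment uses tree topology only; any in-silico localization evidence
that field studies sometimes fold in is out of scope.

## 3. Gene structure and motifs

Intron categories follow exon counts (0 / 1 / ≥ 2 introns).  Motifs are
discovered by ZOOPS (zero-or-one occurrence per sequence)
expectation-maximization: per candidate width, EM is restarted from 10
random seed windows and the best objective kept; widths are scanned
over the coarse grid {8, 12, 16, 21, 29, 41, 58, 81, 100} clipped to
the configured range, and the winner maximizes total
information content.  After each accepted motif its occurrences are
masked and the background re-estimated from unmasked residues.

Numerical choices worth recording:

* The M-step uses a background-proportional Dirichlet pseudocount of
  total mass 10 per column.  This is deliberately strong: weakly
  supported motifs stay near background, so the stop rule can reject
  them.  The monotonicity invariant asserted per iteration is therefore
  on the *penalized* objective (log posterior, including the Dirichlet
  term and a Beta(2,2) prior on the occurrence probability), which
  MAP-EM guarantees non-decreasing; the raw likelihood alone is not
  monotone under MAP updates.
* Information content per column is bias-corrected by the standard
  small-sample term $19/(2 n \ln 2)$ before the stop rule "mean IC per
  column < 0.5 bits" is applied.  Without the correction, EM on pure
  background with ~20 sequences reliably fabricates ≥ 0.5-bit motifs.
  The 0.5-bit threshold itself is a package choice; the original
  workflow only fixes "at most 8 motifs, widths 8–100".
* Motif re-mapping (`map_motifs`) reuses the profile-scan machinery
  with a per-motif decoy calibration at a loose `E < 1e-3` gate.

## 4. Duplication: tandem clusters and collinear blocks

**Tandem.** Per chromosome, family genes sorted by start; consecutive
genes with start-to-start distance ≤ 200 kb are linked and maximal
linked runs of ≥ 2 genes are clusters.  Because positions are ordered,
this equals the transitive closure of the pairwise 200-kb rule; the
test suite checks exact agreement with an independent pair-graph +
connected-components oracle on random layouts.

**Similarity links.** Smith–Waterman local alignment for every protein
pair, e-values Gumbel-calibrated against shuffled decoy pairs.  A link
is retained when (i) `E < 1e-20`, (ii) it lies within a factor
$10^{20}$ of the best non-self hit of either member, and (iii) the
alignment covers ≥ 50% of the longer protein.  Filter (ii) deserves a
note: the rule is usually stated as "the e-value did not exceed 1e-20
times the e-value of the best non-self hit", which read literally
excludes every hit including the best one (no e-value is $10^{20}$-fold
smaller than itself) unless e-values underflow to zero.  It is
implemented here in the only reading that does what the rule is said to
do — restrict links to each gene's closest relatives.

**Chaining.** Retained links become anchors on a chromosome pair,
projected to gene ranks over *all* genes (family and background).
Dynamic programming finds the longest chain whose anchors strictly
advance on both chromosomes (both orientations tried) with at most 6
intervening genes on each side between consecutive anchors; chains are
extracted best-first, each anchor joining at most one block, and blocks
need ≥ 2 anchors.  The rank-difference gap counts every intervening
gene, including anchors not chained; on the synthetic genomes this
matches the planted layouts exactly, and chaining is tested against an
exhaustive enumeration oracle for small anchor sets.  The "minimum of 6
unduplicated genes were allowed" phrasing the field uses is ambiguous;
it is read as the conventional max-gap parameter (`collinearity_gap`).

## 5. Ka/Ks and dating

Nei–Gojobori with Jukes–Cantor correction, chosen because it is the
classical default inside the tools such surveys run, and because it
admits an exact brute-force oracle: synonymous site counts per codon
come from single-nucleotide-neighbor enumeration with stop neighbors
excluded from denominators (so $S + N = 3$ per compared codon), and
observed differences are averaged over all minimal substitution
pathways with stop-crossing pathways discarded.  A codon pair whose
pathways all cross stops is skipped with a warning, as are alignment
columns containing stops or gaps.  $p \ge 3/4$ makes the correction
undefined; such pairs are flagged and excluded from dating.
Both the per-codon site counts and the pathway-averaged differences are
asserted equal to an independent enumerator over all sense codons and
random codon pairs.

Selection classes follow the standard reading: ratio > 1 positive,
= 1 (within $10^{-9}$) neutral, < 1 purifying, undefined at
$K_s = 0$.  Dates are $T = K_s/(2r)$ with $r = 2.6\times10^{-9}$
substitutions/site/year, divided by $10^6$ once at the reporting
boundary.  (Field papers sometimes gloss $K_a/K_s < 1$ as "rapid
evolution"; the package reports the class by the stated rule only.)

## 6. Expression

* Expressed: strictly `FPKM > 1` (the protocol wording; boundary values
  are logged so the non-strict reading remains recoverable).
* Differential: ratio with pseudocount 0.01 (the workflow is silent on
  zero-FPKM handling); strictly > 2 up, strictly < 0.5 down, else
  unchanged — so a ratio of exactly 2 is unchanged.
* Pattern clusters: average-linkage hierarchical clustering of
  $1-\text{Pearson}$ on $\log_2(\text{FPKM}+1)$ rows, tree cut at
  correlation 0.5.  The named clustering tool's "threshold ≥ 0.5" does
  not state whether it is a correlation, distance, or tree-height cut;
  correlation is the interpretation used here and is recorded as such.
  Constant rows have undefined correlation and become singleton
  clusters with a warning.
* qPCR: $\Delta C_t = C_t(\text{target}) - C_t(\text{reference})$ per
  replicate, $\Delta\Delta C_t$ between treatment and calibrator means,
  fold $= 2^{-\Delta\Delta C_t}$, replicate SDs propagated; a two-sided
  t-test on replicate $\Delta C_t$ values is provided for the
  significance-star convention.

## 7. The synthetic-data module

The simulator is first-class, tested code: it defines the conditions
under which every downstream claim is verified.

* **Genomes.** Default study shape: 5 chromosomes, 24 family genes in 4
  subfamilies, 60 decoys, two tandem clusters (2 and 3 genes at 120 kb
  and 90 kb spacing), two collinear blocks of 4 anchor pairs with 2
  intervening decoys, anchor pairs evolved at $K_s \sim U(0.1, 0.6)$,
  $\omega \sim U(0.15, 0.5)$ — sizes chosen so a desk-scale run
  exercises every rule (a cluster per rule, a block per orientation)
  while each genome builds in under a few seconds; tests use smaller
  variants of the same shape.  Family proteins carry exactly one
  diverged copy (substitution probability 0.1) of a fixed 103-residue
  synthetic domain consensus; decoys are drawn from the family residue
  composition and rejected against the consensus profile, so scan
  specificity is tested against a realistic background.  Intergenic and
  intronic sequence is uninformative filler: positional rules, not
  sequence composition, are what the genome layout tests.  Block-gene
  spacing is chosen so consecutive anchors never fall inside the tandem
  window, keeping the planted tandem truth exact.
* **Codon pairs.** A continuous-time codon process with equal codon
  frequencies and no transition/transversion bias — the same
  simplifications the estimator assumes, which is the point: parameter
  recovery is then a clean test of the estimator, not of model
  mismatch.  Per-codon rates are normalized so the synonymous flux of
  codon $c$ equals its Nei–Gojobori site count $S_c$ (and the
  nonsynonymous flux $\omega(3-S_c)$); each branch runs for
  $K_s/2$ time units, stop-creating changes are forbidden, and realized
  substitution counts are returned.  Without this normalization,
  stop-adjacent codons make the realized synonymous flux fall several
  percent below $S_c$ per unit time and the recovered $K_s$
  systematically undershoots its target.  Residual biases are the
  estimator's own: unweighted pathway averaging inflates $S_d$ when
  $\omega > 1$, which is why $\omega = 2$ recoveries sit ~10–15% low at
  high divergence — the documented behavior of this classical
  estimator, not a simulator artifact.
* **Expression and Ct tables.** Planted ratios are drawn outside a
  margin (default 1.5×) of the calling bounds, and the generator
  refuses margin/noise combinations whose 99.9% noise band crosses a
  bound — so noise-free calls reproduce the planted classes with zero
  mismatches by construction, and that is asserted, not assumed.  Ct
  tables are built by inverting the $2^{-\Delta\Delta C_t}$ formula
  (reference gene flat at Ct 15, control target at 24), so zero-noise
  recovery is exact.

**What passing these tests does and does not show.**  The synthetic
genomes have no indels within domains, no isoforms, no fragmented gene
models, and clean intergenic spacing; the expression generator plants
unambiguous classes.  Green tests therefore certify the *rules* —
thresholds applied as stated, estimators matching their oracles,
structures recovered when present — not robustness to the noise,
annotation error, or model misspecification of real genomes.

## 8. Problem sizes and reproducibility

Test and acceptance runs use desk-scale sizes chosen as the package's
own defaults: genomes of 8–24 family genes, 3000-codon simulations with
20 replicates per condition, 100–500 property-test draws, 100–200
bootstrap replicates in end-to-end runs (the configuration default
remains 1000).  Every stochastic step takes an explicit seed and the
generators draw from a single seeded stream per call; identical seeds
give byte-identical artifacts, which is itself a test.
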