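---
title: "The anatomy of a protein family from SSE annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The anatomy of a protein family from SSE annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sseanatomy)
```

## The problem

Families of homologous protein structures — the cytochromes P450 are the
motivating case — share a conserved fold whose helices and strands carry
family-standard names (helix A through L, strands β1-1, β1-2, ...). Once
every domain's secondary structure elements (SSEs) have been annotated
with these labels, a family-wide "anatomy" can be computed: how often
each SSE class occurs, how long it typically is, how conserved its
sequence is, and which single residue best anchors a generic,
family-level residue numbering of the kind used for GPCRs
(Ballesteros–Weinstein-style `X.50` schemes). sseanatomy implements that
analysis layer. It does **not** compute the annotations themselves (no
coordinates are read); it consumes per-domain annotation JSON files plus
a domain metadata table, and everything downstream is offline and
deterministic.

## Data model

One JSON file per domain lists its SSEs: label, type (`H`/`E`),
inclusive 1-based residue range, amino-acid sequence (`X` for
non-standard residues), and optionally an annotation-confidence metric
and a β-sheet id. An `annotation_set` bundles the domains with a
canonical ordering of class labels; labels outside that order are kept
and reported as unclassified rather than dropped, since family
structures can contain extra elements. An SSE "exists" in a domain when
it is annotated with at least one residue, and its length is the
inclusive residue count `end − start + 1` (helix I spanning 284–316 has
33 residues).

## End-gap-only alignment

To anchor one generic number per alignment column, every sequence of a
class must occupy a contiguous block of columns: gaps are allowed before
the first and after the last residue, never inside. An alignment is
therefore just one non-negative start-column offset per sequence.

The objective is a sum-of-pairs score: for each unordered pair of
sequences, substitution scores (BLOSUM62 by default) are summed over
columns where both have residues, and a linear terminal-gap penalty
(default 10) is charged per column where exactly one of the pair has a
residue. Columns where neither has a residue cost nothing, which makes
the pair contribution a function of the pair's relative offset alone.
Three consequences are exploited:

* the score of any offset vector is a sum of `O(n²)` precomputed
  pairwise lookup tables;
* tiny instances (≤ 4 sequences within an enumeration budget) are
  solved **exactly** by enumerating relative offsets — local search by
  single- and even pairwise joint re-placement can provably miss the
  optimum on unrelated sequences, and for so few short sequences
  enumeration is cheap;
* larger instances use a deterministic progressive heuristic: sequences
  sorted by descending length (ties by input order), each placed at the
  offset maximizing its summed pairwise score against those already
  placed, followed by iterated single-sequence re-placement (plus
  pairwise joint re-placement when there are at most 12 sequences) until
  no strict improvement, and finally compared with the refined unshifted
  stacking so that the result never scores below the all-offsets-zero
  alignment.

Ties are always broken toward the smallest offset (lexicographically
smallest offset vector for the exact search), so results are
deterministic for a fixed input order. `oracle_align()` is a deliberately
naive global enumerator over absolute offset vectors, kept as an
independent cross-check of the production path; the test suite verifies
score agreement on hundreds of random instances.

The choice of a *linear per-column* terminal gap cost (rather than
per-run or overlap-only) is this package's own: it is the simplest
objective consistent with a single scalar gap penalty for short SSE
sequences, and it is stated here rather than asserted as anyone else's
convention. `X` scores 0 against everything — neutral, neither rewarded
nor penalized — but still counts as an occupied column.

## Logo statistics

For column $i$, with $A$ the 20 standard amino acids, $p_i^a$ the
fraction of *all* sequences carrying amino acid $a$ at $i$, and $p_i$
the fraction carrying any residue there (occupancy):

$$R_i = \log_2 20 + \sum_{a \in A} \frac{p_i^a}{p_i} \log_2 \frac{p_i^a}{p_i},
\qquad c_i = p_i R_i,$$

with $0 \log_2 0 := 0$. $R_i$ (bits) runs from 0 for twenty equiprobable
residues to $\log_2 20 \approx 4.32$ for a perfectly conserved column;
$c_i$ is the area of the logo column (width $p_i$, height $R_i$). No
small-sample correction or pseudocount is applied — the printed formula
is computed as-is, so small alignments have optimistically high $R_i$.
`X` counts toward $p_i$ but toward no $p_i^a$, so the inner sum can fall
short of 1; this treats unknown residues as occupancy without letting
them pretend to be conserved. Classes are ranked by the
occupancy-weighted mean column height

$$R_{\mathrm{avg}} = \frac{\sum_i p_i R_i}{\sum_i p_i}.$$

The **reference residue** of a class is the column with the greatest
$c_i$ (leftmost on ties); the class is eligible for generic numbering
only when that maximum *strictly* exceeds 2 bits. Columns of an
end-gap alignment can never be all-gap, so $p_i > 0$ always holds.

## Generic numbering

The reference column is numbered 50; a residue in column $j$ gets
$50 + (j - j_{\mathrm{ref}})$, written `@C.46` or, with the structure's
own residue, `W120^@C.46` (mutations as `W120A^@C.46`). Because no
internal gaps exist, numbers within one domain increase by exactly 1 per
residue. Numbers are assigned only inside the annotated SSE — no loop
extension. For a domain whose block does not span the reference column
the same column arithmetic is extrapolated and the domain is flagged;
a generic number below 1 (an SSE reaching more than 49 residues before
the reference) is refused rather than silently renumbered.

## Occurrence, lengths, and the anatomy report

Per-class occurrence $k/n$ over $n$ domains carries an Agresti–Coull
interval: with $z$ the normal $1-\alpha/2$ quantile,
$\tilde n = n + z^2$, $\tilde p = (k + z^2/2)/\tilde n$, interval
$\tilde p \pm z\sqrt{\tilde p(1-\tilde p)/\tilde n}$ clamped to
$[0,1]$. $z$ is computed from $\alpha$, never hard-coded. Length
summaries use only the domains where the class exists; the median of an
even-sized multiset is the mean of the two central values. The anatomy
report joins ranges (from a chosen reference domain), $R_{\mathrm{avg}}$,
occurrence and mean length, sorted from most conserved to most variable
with ties keeping the canonical label order.

## Group comparison

Two sets (typically a bacterial and a eukaryotic subset, from
`split_by_superkingdom()`) are compared per class:

* **occurrence** by the test of equal proportions (`prop.test`), with
  Yates continuity correction on by default and a flag to disable it.
  When both groups sit at the same boundary (a class present in every
  domain of both, or absent from both) the 2×2 table has a zero margin
  and the chi-square statistic is undefined; this is reported as
  $p = 1$ — no evidence of a difference — rather than `NaN`.
* **length** by the two-sample Kolmogorov–Smirnov test (`ks.test`,
  asymptotic), *gated on the medians*: equal medians yield a skipped
  result. Lengths are integers, so medians are multiples of ½ and the
  equality check is exact. The asymptotic p-value is approximate under
  the ties that integer lengths produce; it is documented as such rather
  than patched.

No multiple-testing correction is applied by default (each class is
tested at its own $\alpha$); a Benjamini–Hochberg option exists per test
kind. A caveat worth stating: at $\alpha = 0.05$ the two-sample KS test
is intrinsically conservative at moderate sample sizes because the D
statistic is discrete — even on perfectly continuous data, 40-per-group
samples reject at roughly 2%. Calibration checks of the KS route
therefore use 100-per-group samples with a wide length distribution,
where the empirical size comes out at 3–4%: below, never above, the
nominal level.

## Dataset curation

`select_nonredundant()` keeps one best-quality domain per UniProt
accession (quality ties broken by the lexicographically smallest domain
id — the tie rule is this package's choice) and drops unmapped domains.
`select_template()` picks the "most average" structure: the one with
the highest mean pairwise similarity $Q_{\mathrm{avg}}$ against all the
others, from a precomputed symmetric Q-score matrix; structural
alignment itself is out of scope and the matrix is an input.

## The synthetic generator

`generate_annotation_set()` emulates exactly the statistical structure
the pipeline measures: per-class Bernoulli occurrence, per-class length
distributions — constant, discretized normal, or two-point bimodal
(modeling a helix that is 10 residues long in one taxon and 15 in
another) — and sequences drawn i.i.d. from a background distribution
(uniform by default, which makes the information-content baseline
analytic) except for one planted consensus position. Every
(domain, class) pair draws from its own substream, seeded by a
counter-based hash of (master seed, domain index, class label), so
adding a class never shifts another class's draws and fixtures stay
stable as tests grow. The caller's RNG state is saved and restored.

What the generator does **not** emulate: 3D coordinates, structural
irregularities (kinks, bulges), correlated presence between classes,
unmodeled-loop censoring beyond independent dropout, and realistic
amino-acid composition or phylogenetic correlation between sequences.
Passing tests on synthetic families therefore demonstrate that the
statistics, alignment and numbering machinery behave as specified under
a known truth — not that any biological conclusion about a real family
is reproduced.

`cyp_like_family_spec()` fixes the default study conditions to a
P450-shaped family: a long near-ubiquitous core helix (33 ± 1.5
residues), a conserved mid-size helix with a strong consensus residue,
a bimodal 10/15 helix, a short 61%-occurrence helix, a ubiquitous
5-residue strand and a rare 2-residue strand.

## Numerical choices and problem sizes

* Alignment tie-breaks: smallest offset / lexicographically smallest
  offset vector; `which.max` semantics give the leftmost reference
  column on conservation ties.
* The exact-search window fixes one sequence at offset 0 and bounds the
  rest by ± the total sequence length; an optimal solution always
  exists inside it, because disjoint blocks can be slid together at no
  cost.
* Verification sizes, chosen to make the checks sharp yet quick: 200
  random instances for aligner-vs-oracle agreement (≤ 4 sequences of
  ≤ 8 residues); 1000 replicates for 95% interval coverage at
  $p = 0.7$, $n = 200$; 500 replicates for each null-calibration rate
  (occurrence at $p = 0.5$, 60 per group; KS at 100 per group); 100
  replicates each for the two power checks (10-vs-15 bimodal contrast
  and 0.3-vs-0.9 occurrence contrast) and for reference-residue
  recovery (50 sequences, 0.9 consensus).

## Limitations

* The aligner's progressive path is a heuristic for more than 4
  sequences; it is guaranteed not to score below the unshifted stacking
  and is exhaustively verified only on small instances.
* Logo information content has no small-sample correction, by design;
  compare classes of similar depth.
* KS p-values under heavy ties are approximate, and the median gate
  means genuinely different distributions with equal medians are never
  tested.
* The importer reads the schema documented here plus a best-effort
  mapping of similar field layouts; exotic annotation exports may need
  adjustment.
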