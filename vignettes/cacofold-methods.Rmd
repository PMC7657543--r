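---
title: "Covariation-constrained consensus RNA structure prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariation-constrained consensus RNA structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A conserved structural RNA leaves two complementary traces in a multiple
sequence alignment. Basepaired columns accumulate compensatory double
substitutions and therefore *covary*; columns that vary freely without
covarying are unlikely to be paired at all. `cacofold` turns both signals
into constraints for consensus structure prediction: significantly
covarying column pairs (**positive** pairs) must appear in the final
structure, and highly variable pairs without covariation (**negative**
pairs) are forbidden from pairing with each other. Because positive pairs
may cross, share residues, or run parallel to the backbone, the final
structure is built as a cascade of nested folds whose union can represent
pseudoknots, triplets and alternative helices.

## Pipeline overview

For an input alignment (Stockholm or aligned FASTA):

1. **Column selection.** Columns with more than `gap_cutoff` (default
   0.75) gap symbols are excluded; all statistics and folding run on the
   analyzed columns, with an exact map back to original coordinates.
   Setting `gap_cutoff = 1` analyzes every column. Gap fractions are
   computed over unweighted sequences; a sequence-weighting option was
   considered and deliberately left out of the default path because the
   classification contract is defined on raw counts.
2. **Covariation statistics.** For every analyzed pair the G-test
   statistic is computed on the 16-cell joint nucleotide count table,
   \(G = 2\sum_{xy} n_{xy}\ln(n_{xy}/e_{xy})\), which equals \(2n\,MI\)
   with MI in nats. Counts rather than frequencies are used, so of two
   pairs with equal MI the one with fewer gaps scores higher. Ambiguity
   codes contribute fractionally; gapped rows are excluded per pair.
   Scores receive the average-product correction (APC),
   \(\mathrm{APC}(i,j) = G(i,j) - \bar G_i \bar G_j / \bar G\), with means
   taken over the analyzed pairs (i.e. after masking).
3. **Phylogenetic null and E-values.** A neighbor-joining tree is built
   from pairwise-identity distances and midpoint-rooted. Null alignments
   evolve each column independently down this tree under a
   composition-preserving substitution process whose rate is calibrated,
   per column, to the parsimony substitution count of the real column.
   Because parsimony undercounts substitutions actually placed on a tree,
   two pilot null alignments are generated first and per-column rates are
   rescaled so that the null's *measured* (parsimony) variation matches
   the input's; the scale is clamped to [1, 4]. APC-G scores of all pairs
   of `n_null` (default 20) null alignments are pooled; the upper quartile
   is fitted with a gamma survival function by maximum likelihood, the
   empirical survival is used below the threshold, and
   \(E(s) = n_{tests}\times \widehat{S}(s)\). E-values are monotone
   non-increasing by construction and extrapolate smoothly beyond the
   largest null score. Like all extrapolated tail estimates they are
   order-of-magnitude quantities in the extreme tail; on structure-free
   simulations the realised false-positive rate at \(E<0.05\) stays
   within a small factor of the nominal 0.05 (the acceptance suite bounds
   it by a factor of five).
4. **Covariation power.** Per-column substitution counts are estimated by
   parsimony (`phangorn::fitch`); a pair's aggregate count
   \(s_i + s_j\) is mapped through a monotone calibration curve to the
   probability that a true basepair with that much variation would reach
   \(E<0.05\). The curve was fitted once, by isotonic regression of
   detection against substitutions on synthetic fully compensatory
   alignments produced by this package's own generator
   (`scratch/make_calibration.R`), and is shipped as
   `inst/extdata/power_calibration.tsv`. Invariant pairs have power 0 and
   power never decreases with added substitutions.
5. **Classification.** Strictly: positive if \(E < 0.05\); negative if
   \(E > 1\) and power \(> 0.95\); otherwise allowed (may pair, not
   forced). All three cutoffs are configurable. In `improve` mode two
   independent tests are run — one on the annotated structure's pairs,
   one on all other pairs — each with its own multiple-testing burden
   \(n_{tests}\) equal to its own set size, sharing one null fit.
6. **Cascade maxCov.** Positive pairs are grouped into layers: each layer
   is a maximum-weight nested, residue-disjoint subset of the remaining
   positives (weight \(-\log E\), E floored at \(10^{-50}\) so zero
   E-values stay finite), found by the Nussinov recursion on coordinates
   compressed to the pair endpoints (an exact reduction, since nesting,
   crossing and residue sharing depend only on endpoint order). Ties
   prefer pairing, then the lexicographically smallest (i, j), making the
   layering deterministic and invariant to input order. A residue in two
   positive pairs forces them into different layers, which is how
   triplets arise. With no positives a single unconstrained layer is
   folded, and the result is flagged as lacking evolutionary support.
7. **Constrained folding.** Layer 0 is folded with the RBG grammar, whose
   productions model hairpin, bulge, internal-loop and multiloop
   architecture with explicit loop-length distributions and stacked-pair
   emissions; later layers use the helix-centric G6X grammar. Both run as
   CYK over the *profile sequence*: emissions are scored as
   composition-weighted expected log-probabilities over each column's
   raw nucleotide proportions, so sparsely occupied columns contribute
   near-neutrally. The per-layer constraints are applied by masking:
   forbidden pairs (all negatives plus positives of other layers) score
   \(-\infty\); positions of forced pairs may neither be unpaired nor
   pair elsewhere, so every finite parse contains every forced pair.
8. **Helix filtering, merge and annotation.** Alternative-layer folds are
   decomposed into helices (contiguous pairs; 1–2-nt single-strand bulges
   and 1x1 internal loops do not split a helix; a single pair counts as a
   helix). Positive helices are always kept; unsupported helices need at
   least `min_alt_helix` (15) pairs and at most `max_overlap_frac` (50%)
   of their residues inside the union of previously selected helices,
   seeded with the layer-0 structure and accumulated in cascade order.
   Kept helices are merged with the nested structure; alternative helices
   sharing no residue with it are labelled `pk`, overlapping ones `tr`,
   and extra covarying pairs within one helix are refined to `sc`
   (same-strand) or `xc` (cross-strand). The merge verifies the two
   central guarantees — every positive pair appears exactly once, no
   negative pair appears — and fails loudly if either is violated.

## Grammar inventories and parameters

The exact production inventories are a design choice of this package:

* **RBG**: `S -> aS | F0 S | eps`; `F0/F5 -> a F5 a' | a P a'` (F5 emits a
  pair conditioned on its enclosing pair — one 16x16 emission table, the
  "16 nonterminals" shorthand); `P -> loop | loop F0 | F0 loop |
  loop F0 loop | M1 M`; `M -> M1 M | R`; `M1 -> a M1 | F0`;
  `R -> R a | M1`. Loop lengths carry trained distributions, truncated at
  30 nt with a geometric tail (ratio 0.9) out to 400 nt. The minimum
  hairpin loop is 3 nt, relaxed to 0 only under a forced closing pair so
  that constraint sets are always representable.
* **G6X**: `S -> L S | eps`; `L -> a F a' | a`;
  `F -> a F a' | L S | eps`. `F -> eps` admits zero-length hairpin loops,
  so backbone-adjacent forced pairs parse; a full-span pair inside `F`
  must use the stacked rule, which keeps the grammar unambiguous.
  Parallel-orientation forced pairs are emitted through a dedicated
  16-cell emission and flagged in the output; they occupy the same (i, j)
  cell, keeping CYK \(O(L^3)\).

Both grammars are unambiguous — every nested structure has exactly one
parse — so maximum-likelihood training reduces to counting rule and
emission uses over the training structures, with pseudocount 0.5.
Stacked-pair emission tables are sparse in any small training set, so
each context row is smoothed towards the unconditional pair distribution
(one pseudo-observation per row) rather than towards uniform; without
this, rare stacking contexts make arbitrary non-canonical stacks too
cheap and alternative layers over-extend their helices. The shipped
default parameters were trained on a bundled synthetic set of nested
structures with canonical pair composition
(`inst/extdata/training_structures.txt`); regenerate them with
`Rscript scratch/train_defaults.R`. They are *not* the parameters of any
published tool; folding details beyond the forced/forbidden constraints
should be read as plausible completion, not evidence.

Numerical choices: log-space scores use a finite sentinel \(-10^{30}\)
instead of `-Inf` (no NaN from arithmetic); single-stranded run sums keep
blocked positions out of the prefix sums so the sentinel cannot erode
precision; CYK tie-breaks are fixed by candidate order (first listed
wins), so folds are reproducible to the bit.

## The synthetic-alignment generator

`generate_alignment()` evolves an ancestral sequence folded to a planted
structure down a star or balanced binary tree: pair sites draw
Poisson(2·rate) events per branch, each compensatory (a new canonical
pair type on both columns) with probability `compensatory_fraction`,
otherwise one-sided; unpaired columns draw Poisson(rate) independent
substitutions. It emulates the covariation structure of curated seed
alignments at desk scale and is the basis of the power calibration, the
toy pseudoknot integration test (three nested plus two crossing planted
pairs around two conserved stems, with conserved A background so that
only the planted signal covaries), and the null-control fixtures. It
deliberately does **not** model indels, non-canonical pair evolution,
rate variation across sites beyond the planted structure, or biased
codon-like constraints — so green tests demonstrate the machinery's
correctness and calibration under those idealised conditions, not
performance on real alignments with alignment errors or heterogeneous
gap structure.

Problem sizes used by the tests and the acceptance script are the
package's chosen desk-scale conditions: alignments of 24–32 sequences
and 30–60 columns, 15–20 null alignments per calibration, 12–16
structure-free replicates for the false-positive check, and 20 planted
pairs for the sensitivity check. Enumeration oracles run at length 9
(parses) and 12 pairs (maxCov), where exhaustive search is exact.

## Known limitations

* E-values beyond the largest pooled null score rely on the gamma tail;
  across the moderate tail they run within a small factor of nominal
  (slightly anticonservative), which is why the negative-pair rule also
  requires high power before forbidding a pair.
* Parsimony substitution counts saturate on deep trees; the pilot-based
  rate rescaling compensates globally per column but not per branch.
* The profile emission treats columns as independent and ignores
  sequence weighting; strongly redundant alignments may overstate
  effective counts.
* Alternative-layer folds may legitimately propose helices overlapping
  the nested structure (competing structures); they are reported with
  `tr` labels rather than suppressed, mirroring the cascade's design.
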