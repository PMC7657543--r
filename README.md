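# cacofold

Covariation-constrained prediction of conserved RNA consensus structures
from multiple sequence alignments.

## What it does and for whom

Given an alignment of homologous structural RNAs (Rfam-style Stockholm or
aligned FASTA), `cacofold` predicts a consensus secondary structure —
including pseudoknots, base triplets and alternative helices — anchored in
two kinds of evolutionary evidence:

* **positive basepairs**: column pairs whose covariation is statistically
  significant after removing phylogenetic background (APC-corrected G-test,
  E-value < 0.05 against a tree-based null); every positive pair is
  incorporated into the final structure;
* **negative basepairs**: column pairs with plenty of variation
  (covariation power > 0.95) but no covariation (E-value > 1); these are
  forbidden from pairing with each other.

It is aimed at RNA biologists and curators who want to know which parts of
a proposed (or de novo) consensus structure are actually supported by the
alignment, and at method developers who need a self-contained, testable
implementation of covariation-constrained folding.

## The method in brief

For each analyzed column pair the G-test statistic
`G = 2 Σ n_xy ln(n_xy / e_xy)` (equal to `2·n·MI` in nats, but on counts)
is computed and APC-corrected. E-values come from null alignments evolved
column-independently on a neighbor-joining tree with the input's base
composition and substitution load, with a gamma fit to the null tail.
Covariation power maps a pair's parsimony substitution count through a
calibration curve to the probability that a true basepair with that much
variation would have been detected.

Positive pairs are grouped by the cascade **maxCov** algorithm: each layer
is a maximum-weight (Σ −log E) nested, residue-disjoint subset of the
remaining positives, found with the Nussinov recursion. Layer 0 is folded
with the probabilistic RBG grammar (hairpins, bulges, internal loops,
multiloops, stacked pairs), later layers with the helix-centric G6X
grammar; both run constrained CYK on the alignment's profile sequence,
forcing the layer's positives and forbidding all negatives and all other
positives. Alternative helices are filtered (positive helices always kept;
unsupported ones need ≥ 15 pairs and ≤ 50% residue overlap with what is
already selected), merged with the nested structure, and annotated `pk`
(residue-disjoint from the nested fold), `tr` (overlapping), or `sc`/`xc`
(side/cross covariations within one helix).

## Worked example

A bundled generator builds a small two-hairpin alignment with three nested
and two crossing planted covarying pairs (the crossing helix sits between
the two hairpin loops):

```r
library(cacofold)
toy <- generate_pseudoknot_toy(seed = 1)
res <- cacofold_fold(toy$msa, run_config(n_null = 20, seed = 101))
print(res)
#> cacofold fold result
#>   analyzed columns: 30 of 30
#>   pairs tested: 435 | positive: 5 | negative: 3
#>   cascade layers: 2
#>   structure: 8 nested + 2 alternative pairs
#>   alternative labels: pk=2
```

All five planted pairs are recovered as positives (435 pairs tested):

```r
res$stats[res$stats$class == "positive", c("i","j","gtest","apc","evalue","power")]
#>      i  j gtest  apc   evalue power
#> 49   4 11  38.8 28.9 2.83e-04 0.931
#> 58   3 12  42.5 32.5 6.51e-05 0.931
#> 198  8 21  33.8 24.8 1.44e-03 0.462
#> 217  7 22  36.5 22.4 3.80e-03 0.931
#> 343 18 27  35.2 23.8 2.15e-03 0.613
```

The three mutually nested positives go into layer 0 and seed the main
nested structure (8 pairs after RBG completion); the two crossing pairs
need a second layer, come back as one alternative helix, and are labelled
as a pseudoknot because they share no residue with the nested fold:

```r
res$structure$alt
#>   i  j layer helix positive label
#> 1 7 22     1     1     TRUE    pk
#> 2 8 21     1     1     TRUE    pk
```

`write_reports(res, "toy")` writes the annotated Stockholm file (SS_cons
plus one line per extra layer), the per-pair TSV (G, APC-G, E-value,
power, class), the layer TSV, the final structure TSV and an SVG arc
diagram. `cacofold_improve()` does the same starting from an annotated
structure, testing the proposed pairs and all other pairs independently
and reporting the positives the annotation was missing. A thin
command-line wrapper lives at `inst/cli/cacofold.R`.

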