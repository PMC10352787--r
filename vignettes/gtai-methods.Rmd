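---
title: "Species-specific tAI: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-specific tAI: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtai)
```

## The model

The tRNA adaptation index scores how well a gene's synonymous codon choices
match the cellular tRNA pool.  For each sense codon $i$, the absolute
adaptiveness is

$$W_i = \sum_{j=1}^{n_j} (1 - S_{ij})\, tGCN_{ij},$$

summed over the $n_j$ anticodons that can decode codon $i$ under the wobble
rules, where $tGCN_{ij}$ is the gene copy number of the $j$-th such anticodon
(a proxy for tRNA abundance) and $S_{ij} \in [0,1]$ is the coupling
inefficiency of that codon–anticodon pairing: 0 is a perfect interaction, 1
a pairing too weak to contribute.  Each $W_i$ is normalized to the maximum to
give the relative adaptiveness $w_i \in (0,1]$, and a gene's tAI is the
geometric mean of the $w_i$ over its codon occurrences,

$$tAI_g = \exp\!\Big(\tfrac{1}{O_{tot}} \sum_i O_i \log w_i\Big).$$

The wobble model distinguishes one Watson–Crick pairing per codon plus one
wobble pairing at the third position: G34 reading NNU (G:U), inosine
(genomically A34) reading NNC (I:C) and NNA (I:A), U34 reading NNG (U:G),
and — in prokaryote mode — lysidine-modified CAT reading AUA (L:A).  AUG and
UGG are restricted to Watson–Crick so initiator-Met and Trp tRNAs are not
credited with wobble decoding.  Watson–Crick pairings are pinned at
$S = 0$; the wobble classes are the free parameters.

## Inferring S weights without expression data

Because highly expressed genes are under translational selection to use
codons adapted to the tRNA pool, their codon usage carries information about
the wobble efficiencies.  The package therefore:

1. computes the improved effective number of codons (ENc) per gene, using
   the pseudocounted family homozygosity
   $F_{CF} = \sum_i ((n_i+1)/(n+m))^2$ so sparse genes remain defined;
2. takes the lowest-ENc fraction of genes (default 5%, at least 5 genes) as
   the putatively highly expressed reference set;
3. pools the reference set's codon counts into RSCU values,
   $RSCU_c = O_{ac} / (\frac{1}{k_a}\sum_{c'} O_{ac'})$; and
4. searches for the $S$ vector maximizing the Spearman rank correlation,
   across codons, between reference RSCU and $W_i$.

The search is a real-valued genetic algorithm: chromosomes are the free $S$
values, initialized uniformly on $[0,1]$; each generation applies tournament
selection (k = 2), uniform crossover (probability 0.8), Gaussian mutation
(rate 0.1, sd 0.1, clipped to the bounds) and single-individual elitism.
Elitism makes the best-fitness history non-decreasing in every run, and a
fixed seed makes runs bit-reproducible.  The defaults — population 60,
100 generations, both held constant across an analysis — sit on the plateau
of the fitness trajectory: longer runs gain essentially nothing (the
acceptance script measures the median generation-100 to generation-1000 gap
at zero to a few thousandths), and the run-to-run coefficient of variation
of the best fitness across population sizes 10–100 is far below 1%.  Only
the operator probabilities are package choices; all are exposed in
`ga_config()`.

Tie handling everywhere is average-rank Spearman, because pooled reference
RSCU values tie frequently in small reference sets.  Codon families with
zero reference counts have undefined RSCU and are excluded from the
correlation; six-fold families are split into two-fold + four-fold blocks
(by first-two-nucleotide identity), which is the family structure the
improved ENc assumes and what caps the index at 61.  Codons with $W = 0$
(no recognizing tRNA copies) receive the geometric mean of the non-zero
$w_i$ so the tAI log stays defined; they are flagged in the output.

The `otai_sij()` preset ships the fixed literature weights of the original
yeast-calibrated tAI (s(G:U) = 0.41, s(I:C) = 0.28, s(I:A) = 0.9999,
s(U:G) = 0.68, s(L:A) = 0.89) as external constants, for comparison runs
that bypass the optimizer.

## The synthetic-genome generator

`simulate_genome()` produces genomes in which the selection assumption holds
by construction, with known ground truth.  A tRNA repertoire is drawn (all
G34/C34/U34 anticodons, A34 only in the eight classic inosine families,
copies 1 + Poisson(2) — the magnitudes typical of compact genomes), a true
$S$ vector fixes the true $w_i$, and genes are built codon by codon: amino
acids uniform, then, within each family, highly expressed genes choose codon
$c$ with probability $\propto w_c^\beta$ while background genes follow a
purely mutational GC tilt.  Defaults are 200 highly expressed genes, 1800
background genes, lengths uniform on 100–400 codons, $\beta = 5$, no GC
bias, and true weights $S = (0.4, 0.3, 0.7, 0.6)$ for (G:U, I:C, I:A, U:G) —
mid-range values spanning the magnitude of the literature wobble penalties,
deliberately away from the boundary so every class matters.  At $\beta = 0$
and GC bias 0.5 the two gene classes are distributionally identical, giving
an exact null for testing.

The generator emulates exactly the premise the fitness exploits — a
within-family codon tilt toward adapted codons in highly expressed genes —
and nothing else.  It does not model amino-acid composition bias, expression
levels, GC skew between genes of the same class, horizontal transfer, or any
mechanistic translation dynamics.  Passing tests on these genomes show the
pipeline recovers what the model assumes; they cannot certify behavior on
genomes violating those assumptions (e.g. weakly biased genomes, which the
method itself flags as its hard case).

## What the optimizer can and cannot recover

On simulated genomes the reference set is almost purely composed of the
truly highly expressed genes, ENc separates the classes cleanly, and the GA
reliably finds the global optimum of its objective (it matches an exhaustive
two-parameter grid to within 0.01).  The inferred weights, however, should
be read as *effective* wobble penalties, not point estimates of the true
ones: RSCU is capped at the family size $k_a$ and only encodes
within-family relative usage, while $W_i$ is an absolute quantity, so the
codon-level rank correlation between them is maximized by $S$ vectors that
push wobble-only codons toward the bottom of the global $W$ ranking — even
with a noiseless reference RSCU, the objective's argmax is displaced from
the generating $S$.  Concretely, on default simulations the best objective
value exceeds the objective evaluated at the true $S$, individual recovered
weights can differ from truth by several tenths, and the rank correlation
between true and estimated $w_i$ settles around 0.7–0.85 rather than above
0.9.  This mirrors the method's behavior on real genomes, where the best
achievable correlation ranges roughly 0.4–0.8 by organism and genomes with
weak overall codon bias give the least reliable weights.  Downstream gene
ranking is far more robust than the individual weights, because the
within-family orderings — which the tAI geometric mean consumes — are
recovered well.

## Numerical and degenerate-input choices

* CDS validation defaults: at least 30 codons, at most 5% ambiguous bases,
  internal-stop rejection on; codons containing N are skipped in counting
  (and tallied), never attributed to a codon.
* A fold class with no observed codons contributes its uniform-limit term
  $K_m m$ to ENc, the continuous limit of the pseudocounted $F_{CF}$ as
  counts vanish; a table with *no* multi-codon-family counts errors.
* CAI weights use the Sharp–Li 0.5 pseudocount for zero reference counts;
  single-codon families are excluded from CAI and SCUO.
* ENc-based reference selection breaks ties by input order, so a fixed input
  file always yields the same reference set.
* Williams' test (two dependent correlations sharing a variable,
  $df = n-3$, two-sided) rejects degenerate correlation matrices
  ($K \le 0$); subsample replicates whose draw is constant are recorded as
  missing, not redrawn.
* All randomness (simulation, GA, subsampling) flows through explicit
  integer seeds.

Problem sizes in the shipped tests and acceptance script — genomes of 1000
to 2000 genes, GA populations 10–100, one 1000-generation run per genome —
were chosen so the full validation cycle completes in about a minute while
keeping the reference pool above twenty thousand codons, where RSCU
estimates are stable.

## Known limitations

Weights are effective, not mechanistic (above).  The wobble rule set applies
the inosine rules uniformly to all codons rather than per-family (absent
anticodons contribute zero, so this only matters if a genome genomically
encodes A34 outside the inosine families).  tGCN is a proxy for tRNA
abundance and ignores expression-dependent modulation.  The reference
fraction is a free parameter with no in-package estimator; 5% is
conventional, and very small genomes fall back to a 5-gene floor.
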