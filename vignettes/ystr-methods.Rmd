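---
title: "Y-STR haplotype analysis: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR haplotype analysis: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

`ystrkit` analyzes Y-chromosomal short tandem repeat (Y-STR) haplotype
tables: forensic summary parameters, per-locus statistics, pairwise
population distances with ordination and clustering, and median-joining
haplotype networks, together with a stepwise-mutation simulator that makes
the whole chain testable without access to real genotypes. This vignette
records the models implemented, the conventions chosen where the field
offers several, and the limits of what a passing test establishes.

## Data model

A *haplotype* is one male's vector of repeat counts over a marker panel.
Panels describe marker order, copy number, mutation-rate class and plausible
allele ranges. Two markers of the built-in 27-value panel (DYS385a/b,
DYF387S1a/b) amplify two loci at once; their genotype is an *unordered*
allele pair, stored in nondecreasing order so `14-11` and `11-14` are one
state. Three anomaly classes are first-class allele states rather than
missing data:

* **microvariants** — partial repeats (`17.2`; fractional part restricted to
  .1/.2/.3), distinct frequency classes in every statistic;
* **duplications** — two alleles at a normally single-copy locus (`15,16`);
* **nulls** — deletions/failed amplification (`-`).

Haplotype *identity* uses the full canonical allele string including all
three classes: two records match only if every state matches. Per-locus
statistics, by contrast, exclude null/duplicated records from that locus's
denominator only. This split reproduces both styles of published table
(full-resolution haplotype counts; per-locus frequency tables) from the same
parsed object. Anomaly flags are a pure function of the canonical tokens, so
`flag_anomalies()` output can be compared exactly against a simulator's
injection log.

Allele-range violations are warnings by default and errors under
`strict = TRUE`, because genuine microvariants and rare alleles routinely
fall outside textbook ranges.

## Forensic parameters

Everything haplotype-level derives from the multiplicity spectrum
(multiplicity $m$ → number of distinct haplotypes seen exactly $m$ times).
With $n_i$ the count of haplotype $i$, $p_i = n_i/n$:

$$\mathrm{HD} = \frac{n\,(1 - \sum_i p_i^2)}{n-1}, \qquad
  \mathrm{HMP} = \sum_i p_i^2, \qquad
  \mathrm{DC} = \frac{\#\{\text{distinct}\}}{n}.$$

The identity $1-\mathrm{HD} = \sum_i n_i(n_i-1)\,/\,(n(n-1))$ (the
unordered distinct-pair match probability) is asserted exactly in the test
suite against a brute-force pair-counting oracle, on 1000 random spectra.

Display rounding is half-up at the conventional precision (4 d.p. for
diversities, 2 d.p. for percentages); raw values are always returned. Note
that surveys are not always internally consistent here: a spectrum of 427
distinct haplotypes in 468 men gives DC = 91.239…%, which half-up rounding
prints as 91.24% although at least one published table prints 91.23%. The
package does not reproduce truncation artifacts; it keeps half-up rounding
throughout.

Per-locus parameters follow the conventions of the STRAF program family for
haploid data, with $H = \sum_a p_a^2$ and $h = 1-H$:
GD $= \frac{n}{n-1}h$ (unbiased gene diversity), PM $= H$, PD $= 1-H$,
Botstein's PIC $= 1 - H - \big[(\sum_a p_a^2)^2 - \sum_a p_a^4\big]$,
PE $= h^2(1-2hH)$, TPI $= 1/(2H)$. PE and TPI are diploid-casework
quantities applied to haploid frequencies by convention; they are provided
because forensic reports tabulate them, and they are flagged here as
convention-dependent rather than canonical.

## Population distances

**R<sub>ST</sub>** is the microsatellite fixation index: a one-level haploid
AMOVA on repeat scores, appropriate under stepwise mutation. For two
populations of sizes $n_1, n_2$ ($N = n_1+n_2$), squared Euclidean distances
over loci give $SSD_{total}$ and $SSD_{within}$;
$\sigma_w^2 = SSD_w/(N-2)$,
$n' = (N - \sum_k n_k^2/N)/(P-1)$,
$\sigma_a^2 = (MSD_a - \sigma_w^2)/n'$ and
$R_{ST} = \sigma_a^2/(\sigma_a^2+\sigma_w^2)$, clamped to $[0,1]$ (negative
variance-component estimates are a finite-sample artifact). Dual-copy loci
are excluded — alleles cannot be assigned to copies, so a repeat-score
difference is undefined — and microvariants are rounded half-up to integer
repeats by default (`microvariants = "drop"` removes the records instead).
The implementation uses per-locus sum identities; the tests recompute every
matrix entry from the definitional pairwise sums of squares. Permutation
p-values are available (`permutations = N`) but off by default.

**Nei distance** defaults to the 1972 standard distance
$D = -\ln\!\big(J_{XY}/\sqrt{J_X J_Y}\big)$ with gene identities accumulated
over shared single-copy loci; `variant = "da"` gives Nei's 1983 $D_A$. The
source tooling for published figures of this kind rarely states its variant;
the choice is therefore exposed as an argument rather than hidden. $D$ is
non-metric in general, so no triangle inequality is asserted — only
symmetry, zero diagonal and nonnegativity.

**Ordination/clustering.** MDS is classical Torgerson scaling: eigendecompose
the double-centered $-\tfrac12 D^2$, keep the top-$k$ positive eigenvalues,
scale eigenvectors by $\sqrt\lambda$. On exact Euclidean input the
configuration reproduces the distances to numerical tolerance (tested via
Procrustes against the generating coordinates, error < 1e-8); negative
eigenvalues — the normal situation for genetic distances — are dropped with
a diagnostic. The dendrogram is UPGMA (average linkage), chosen over
neighbor-joining because the published figures this mirrors are drawn from
the same distance matrices without a stated method, and UPGMA's ultrametric
output (equal root-to-leaf depths, asserted in tests) matches how such
dendrograms are read. Ties break deterministically by input label order.
Both MDS and UPGMA are implemented in-package so that `stats::cmdscale`,
`hclust` and `ape` remain available as *independent* oracles in the tests.

## Median-joining networks

Input preparation mirrors standard practice for STR network software:
dual-copy loci are excluded, microvariant repeat numbers are rounded half-up
to the nearest integer, records with nulls at included loci are excluded
(and logged), and identical vectors collapse into one node with summed
multiplicity. Distance is weighted Manhattan
$d(u,v) = \sum_l w_l\,|u_l - v_l|$ with default weight 10 per locus (the
convention of the NETWORK program; per-locus down-weighting of rapidly
mutating loci is a user option). `DYS389II` is used as typed by default;
`dys389_adjust = TRUE` subtracts the contained DYS389I stretch first.

The algorithm: (1) build the ε-relaxed minimum spanning network — a link is
feasible iff its length is within ε of the minimax (bottleneck) connection
cost between its endpoints; at ε = 0 this is exactly the union of all
minimum spanning trees. (2) For every feasible link $(u,v)$ and every third
node $w$, the candidate median is the per-locus middle order statistic of
$(u,v,w)$ — equivalently $w$ clamped coordinate-wise to $[\min(u,v),
\max(u,v)]$. Candidates that strictly reduce the triple's connection cost
are collected and, per pass, only those of minimal connection cost are
added. This minimality rule matters: admitting *every* improving median each
pass grows the node set explosively when sampled clusters are many mutation
steps apart, while the minimal-cost rule adds the same medians over more
passes and keeps intermediate sets small. (3) Iterate until no median is
added (bounded by `max_iter`). (4) Delete median nodes of degree ≤ 2 that
lie on no shortest path between sampled nodes.

One stated invariant deserves a caveat: the *final* network need not retain
direct sampled–sampled MST links, because an added median legitimately
supersedes them (in the canonical three-haplotype example the 3-edge star
through the median replaces the 2-edge direct tree). What is guaranteed —
and tested against an independent Kruskal/bottleneck oracle — is that the
network contains a minimum spanning tree *of its realized node set*, and
that its total length never exceeds the sampled-only MST length.

Maximum-parsimony post-processing removes links and medians that are in no
minimum-length spanning structure of the sampled nodes. Up to a configurable
size (default 20 candidate links, ≤ 14 medians) this is exact: all median
subsets are enumerated, each scored by restricted-graph MST, and every node
and link participating in some optimal structure is retained (ties keep all
alternatives — two equally parsimonious medians both survive). Above the
bound a shortest-path-union heuristic is used and flagged in
`meta$mp = "heuristic"`. On random instances with ≤ 5 haplotypes and ≤ 4
loci the pruned network attains the brute-force Steiner optimum over the
allele bounding box (enumerated exhaustively in the tests); this is an
empirical property of small instances, not a theorem — median joining is a
heuristic and can miss Steiner points on larger inputs.

## The simulator: what it emulates, and what it does not

`simulate_sample()` draws each record by choosing a founder lineage from a
mixture, copying its allele vector, and adding per locus the net sum of
$M \sim \mathrm{Poisson}(\mu_l G)$ single-step mutations, each ±1 with equal
probability. Defaults state a world resembling a haplogroup-structured
Central Asian sample: six founder lineages of which one carries 1/3 of the
mixture (a strong founder-effect cluster), three subpopulations of sizes
80/253/135, G = 30 generations of lineage depth, and per-generation rates
of 2×10⁻³ (standard loci) / 1×10⁻² (rapidly mutating class) — order-of-
magnitude realistic for Y-STRs. Which eight loci count as "rapidly
mutating" is itself convention; the default set (DYS576, DYS627, DYS570,
DYS518, DYS449, DYS460, DYS533, DYS389II) is config-driven.

Subpopulation *divergence* is implemented as shared drift: each
subpopulation's copy of each founder vector first mutates for
`divergence_generations` before records are drawn. A per-record extra
exposure would only add independent noise and could never raise
R<sub>ST</sub>; shared drift is the minimal mechanism that makes mean
R<sub>ST</sub> increase with divergence time, which the acceptance tests
verify across 0/50/200 generations. Anomalies are injected per record at
configured rates on distinct single-copy loci (nulls may hit any locus), and
logged so flag counts can be compared exactly.

The model deliberately omits: multi-step mutations, locus-specific mutational
asymmetry, allele-range boundary effects (alleles are clamped at 1), true
genealogy (every record is an independent draw at depth G rather than a leaf
of a shared tree), and any linkage to real haplogroup nomenclature. A green
simulation test therefore establishes that the pipeline's statistics respond
correctly to a stylized stepwise-mutation world — not that they reproduce
any particular population's values. For the founder-recovery acceptance
check the stated regime is $\mu G \le 0.3$ per locus; the test runs at
$\mu G = 0.06$ (the standard-locus default), since at the upper bound on all
23 loci a record expects ~7 mutations and no star topology survives for any
method to recover.

`make_fixture_spectrum()` builds samples whose multiplicity spectrum is
exact by construction: distinctness comes from deterministic base-5 digit
offsets over single-copy loci added to a seeded random base haplotype, not
from rejection sampling.

## Numerical choices and degenerate inputs

* Rounding of microvariants to integers is half-up (`floor(x + 0.5)`), the
  same rule used for display rounding.
* Distance matrices must be symmetric within 1e-12; diagonals are forced to
  exactly 0; RST is clamped to [0,1]; Nei identity 0 yields `Inf` with a
  warning rather than an error.
* Comparison tolerances inside the network algorithms are 1e-9 on weighted
  step distances, which are integer multiples of the locus weights, so ties
  are exact and the tolerance only guards floating-point accumulation.
* Single-haplotype networks are single nodes, not errors; empty samples,
  n < 2 diversity requests, and populations with < 2 usable records after
  exclusions are errors naming the offending input.
* All stochastic code paths take one integer seed; the global RNG state is
  saved and restored, and the CLI records every parameter and every excluded
  record in `run_log.json`.

## Known limitations

* Reduced-median networks are not implemented; median-joining at ε = 0 is
  the substitute, which can differ on reticulate data.
* The MJ implementation targets panel-scale data (hundreds of distinct
  haplotypes); it is not tuned for thousands.
* Permutation p-values for R<sub>ST</sub> use naive resampling and are
  intended for small population counts.
* No external-database comparisons (the published inter-regional distance
  values depend on proprietary reference data and are out of scope); no
  haplogroup prediction; no plotting.
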