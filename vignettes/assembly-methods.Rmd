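---
title: "Inferring soil community assembly processes: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring soil community assembly processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilassembly)
```

# What this package computes

`soilassembly` analyses factorial soil microbiome surveys — two plantation
types (Chinese pine, CP; Chinese scholar tree, CS) sampled over four seasons
(SP/SU/AU/WI) with replicated composite samples — and quantifies which
ecological processes structure the bacterial, fungal and protistan
communities. Its core is the phylogenetic null-model framework that
partitions pairwise community turnover into five assembly processes, wrapped
in the supporting statistics the study design calls for: alpha/beta
diversity and PERMANOVA, soil multifunctionality indices, eco-enzymatic
stoichiometry, high-throughput qPCR (QMEC) functional-gene filtering,
protist trophic profiles and Spearman co-occurrence networks.

# The assembly model

## Beta mean nearest taxon distance

For two communities $A$ and $B$ with relative abundances $f$ on a rooted
phylogeny with patristic distance $d$,

$$\beta\mathrm{MNTD}(A,B) = \tfrac12\Big[\sum_{i \in A} f_i \min_{j \in B} d(i,j)
+ \sum_{j \in B} f_j \min_{i \in A} d(j,i)\Big].$$

It is zero when the communities share every taxon and grows as their taxa
become phylogenetically unrelated. Abundance weighting is the default; a
presence/absence switch (`abundance_weighted = FALSE`) uses uniform weights
over present taxa.

## The beta nearest taxon index

$\beta$NTI is the z-score of the observed $\beta$MNTD against a null built
by shuffling taxon labels across the tips of the tree — richness and
abundances untouched — with one shuffle per null replicate shared across all
sample pairs. The default is 999 replicates. $\beta$NTI $< -2$ indicates
communities more phylogenetically similar than chance (homogeneous
selection); $\beta$NTI $> +2$ indicates less similar than chance (variable
selection). On degenerate geometries (a star tree, where every shuffle
leaves all distances unchanged) the null has zero spread; such pairs are
flagged `undefined` and excluded from process fractions with their count
reported, rather than raising an error.

## Abundance-based Raup–Crick

Pairs inside the $\pm 2$ band are split by the null-standardised Bray–Curtis
index. Null communities preserve each sample's observed richness and total
abundance: occupancy is drawn without replacement with probability
proportional to occurrence frequency across samples, one individual seeds
each occupant (fixing richness), and the remaining abundance is filled by a
multinomial on the pooled relative abundances of the occupants. With $n$
null replicates,

$$RC = 2\,\frac{\#\{BC_\mathrm{null} < BC_\mathrm{obs}\} + \tfrac12 \#\{\mathrm{ties}\}}{n} - 1 .$$

Ties enter at half weight, which keeps $RC \in [-1, 1]$ and makes the
statistic symmetric. One null realisation per sample per replicate is shared
across the pairs of that replicate; the marginal distribution of each pair's
RC is unchanged and the cost drops by the number of pairs.

## The five-way partition

With the published thresholds: $\beta$NTI $> +2$ → variable selection;
$\beta$NTI $< -2$ → homogeneous selection (the deterministic test takes
precedence); otherwise $RC > +0.95$ → dispersal limitation, $RC < -0.95$ →
homogenizing dispersal, and anything else undominated. Fractions per group
are exact rationals on pair counts. Pairs are formed within
plantation-by-season cells by default; `grouping = NULL` pools all samples,
mirroring per-plantation analyses.

# The synthetic-data generator

Every downstream stage is testable without sequencing data through seeded
generators that emulate the study design: a 2 plantation x 4 season x 3
replicate frame, a 32-attribute soil panel in the 16/10/6 categories plus an
excluded pH column, a 72-gene QMEC Ct matrix, and community tables under
five controllable assembly regimes on a simulated phylogeny.

## Tree geometry matters

The default tree is *clustered*: tight family-level clades (shallow
coalescent subtrees, depth 0.15) hanging from a deep coalescent backbone
(depth 2). This mimics marker-gene OTU phylogenies and is what makes
nearest-taxon statistics informative. On trees whose terminal branches
rival their deep ones (a plain coalescent), a random taxon set already has
small nearest-taxon distances and the tip-shuffle null loses its contrast;
we verified this directly while designing the generator. Plain coalescent
and pure-birth models remain available.

## Traits and selection

A trait evolves by Brownian motion on the tree and is blended with iid
noise: `sqrt(lambda) * BM + sqrt(1 - lambda) * noise`, both standardised,
so `lambda` (default 0.95) controls phylogenetic signal without changing
the trait variance. Selection regimes draw membership with probability
proportional to `exp(-s (trait - opt)^2)` with `s = 30` by default, cut off
below 1% of its maximum. The kernel deliberately contains no
regional-abundance factor: under strong selection, fitness rather than
regional commonness sets local dominance, and weighting by a heavy-tailed
regional abundance would concentrate the nearest-taxon statistic onto a
handful of taxa and destroy its power at desk scale. A consequence worth
stating plainly: at `selection_strength = 0` the kernel degenerates to a
*uniform* pool, not to the lognormal pool of the neutral regime.

Each selected sample is additionally thinned by a within-niche lottery
(`niche_keep = 0.7`): replicate communities filtered by the same optimum
share clades without sharing every member. Without this turnover the
supports of replicate samples are nearly identical and $\beta$MNTD is zero
under any tip shuffle — homogeneous selection would be undetectable by
construction, not by biology.

Homogeneous selection applies one shared optimum (the 0.9 trait quantile —
an extreme-environment filter; mid-trait taxa are phylogenetically
scattered, extreme-trait taxa cluster in the clades that drifted furthest).
Variable selection alternates the 0.1 and 0.9 quantile optima across the
samples within each group. The study's acceptance surface scores the modal
process over within-group pairs, so the two environments must both occur
within a group; the returned environment vector records each sample's
optimum.

## Drift, dispersal and calibration

Neutral communities are multinomial draws from a lognormal pool
(`sdlog = 2`, with any single taxon's relative abundance capped at 5% —
soil OTU tables are heavy-tailed but their top taxon rarely exceeds a few
percent, and an uncapped lognormal occasionally concentrates half the
pool on one taxon, which distorts the Raup–Crick null's occupancy step)
after one generation of Dirichlet demographic drift at concentration
`drift_size` (default 800). The drift stage is essential for
honesty, not convenience: the Raup–Crick null contains occupancy-level
variance, and pure read-depth multinomial noise contains none, so a
"neutral" generator without drift is systematically *more* similar than the
null and RC collapses to $-1$. The default was chosen by scanning the
neutral regime's calibration — the fraction of pairs with $|RC| > 0.95$ and
$|\beta\mathrm{NTI}| \ge 2$ — across drift sizes; 800 centres both (the scan
is re-run as an acceptance check).

Dispersal limitation applies drift an order of magnitude stronger
(concentration `drift_size / 10`) independently per sample from mildly
divergent group pools, with migration `m` mixing the pool back in; at
`m ≈ 0` abundances diverge strongly while occupancy stays high, the regime's
detectable signature. Homogenizing dispersal gives each group one realised
pool draw and mixes every sample toward it with weight `m`; at `m ≈ 1`
within-group pairs are far more similar than the pooled metacommunity
predicts. Because the RC null conditions on the pooled table, this excess
similarity is only detectable when the metacommunity is broader than one
group — the generator therefore simulates several groups.

## Problem sizes

Defaults are 1024 taxa in the regional pool, read depth 2000, per-sample
richness roughly 100–300. Desk-scale runs in this package use 12–24 samples
and 199–999 null replicates; these sizes give the nearest-taxon z-score
enough terms to resolve $|\beta\mathrm{NTI}| \ge 2$ (its resolution scales
with the effective number of abundance-weighted taxa) while keeping a full
five-regime parameter-recovery experiment within minutes on one CPU.

## What passing tests do and do not show

The generator produces idealised regimes: one process at a time, clean
niche structure, no spatial autocorrelation, no sequencing error, chimeras
or primer bias, and a phylogeny with uniform clade depths. Parameter
recovery on these data demonstrates that the inference machinery is
mathematically correct and well calibrated — not that real soil communities
are this separable. Real surveys mix processes within every pair set, and
their trees, depths and taxon pools differ in ways that move $\beta$NTI and
RC continuously.

# Supporting statistics

**Diversity.** Shannon (natural log, relative abundances), Simpson
($1 - \sum p^2$), observed richness, ACE (rare threshold 10, via vegan) and
Faith's PD (including the root path, via picante). Chao1 uses the classic
estimator $S_{obs} + F_1^2 / (2 F_2)$, switching to the bias-corrected
$F_1 (F_1 - 1) / (2 (F_2 + 1))$ only when $F_2 = 0$; this differs from
vegan's `estimateR`, which applies the bias-corrected form unconditionally.

**PERMANOVA.** A thin surface over `vegan::adonis2` with sequential
(Type-I) term entry, an explicit seeded permutation matrix for
reproducibility, whole-sample permutations, and
$p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})$. For $n \le 8$ an
exhaustive mode enumerates all $n!$ label orders, making the p-value exact;
tests verify it against a brute-force pseudo-F computed directly from
pairwise distances. Aliased (one-to-one confounded) factors are rejected by
name. Both one-model-sequential and separate single-term modes are
provided, since published per-variable explained percentages can come from
either.

**Multifunctionality.** Attributes are z-scored over all samples jointly
(sample $n-1$ SD; a common scale is required to compare groups), excluding
pH always and dropping zero-spread attributes with a warning; missing
values are excluded pairwise. Narrow indices are unweighted means of their
category's z-scores; the net index is the mean over all 32, so with a full
panel `net = (16 NS + 10 OMD + 6 MFG) / 32` exactly.

**QMEC.** An entry is present only if Ct lies strictly below 31 (a Ct of
exactly 31 counts as absent — the detection limit read as
threshold-exclusive, configurable), amplification efficiency lies in
[1.8, 2.2], and the upstream melting-curve flag (if supplied) is clean.
Detected entries get relative copies $10^{(31 - Ct)/(10/3)}$; the exponent
convention is a config key, and normalisation to the 16S row is optional —
the source text does not state whether its relative copies were
16S-normalised, so neither convention is claimed.

**Enzymes.** EES ratios are ln-activity quotients (C:N =
ln BGC / ln(NAG+LAP), C:P = ln BGC / ln ALP, N:P = ln(NAG+LAP) / ln ALP).
Activities at or below 1 nmol h⁻¹ g⁻¹ make a logarithm non-positive; such
ratios are flagged undefined per sample rather than returned as artefacts.

**Networks.** Spearman correlations on relative abundances across shared
samples; edges require $|\rho| \ge 0.6$ and BH-adjusted $p < 0.05$
(t approximation), taxa below 50% prevalence are excluded — the dominant
field conventions, all exposed, since the source never states its edge
criteria. AD $= 2|E|/|V|$; ACC is mean local clustering with degree-<2
nodes contributing 0; APL and betweenness are computed on the largest
connected component (disconnected pairs have no finite path). Key nodes are
the top ten by betweenness with ties broken lexicographically by id.

# Reproducibility

Every stochastic stage derives its seed deterministically from the master
seed and the stage name (`stage_seed`), so one integer fully determines
every output file; the pipeline writes a manifest with the config hash and
all derived seeds, and re-running a config byte-identically reproduces the
outputs. Generators are pure functions of their arguments and seed.

# Known limitations

- The per-clade (bin-wise) refinement of the null-model framework and
  distance-decay analyses are out of scope.
- The RC statistic from a finite sampled null is a Monte-Carlo estimate;
  its agreement with exhaustive enumeration is exact only in expectation,
  and tests check it within the binomial error band.
- The 32-attribute roster, the 71-gene QMEC panel and the protist trophic
  map ship as editable best-effort templates; the authoritative rosters
  live in supplementary material of the underlying studies and should be
  supplied as CSVs for real analyses.
- Compositional correlation methods (SparCC-type) are deliberately not
  implemented; the Spearman + FDR convention is used instead.
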