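# soilassembly

Quantitative analysis of seasonal soil microbiome surveys: which ecological
processes assemble the bacterial, fungal and protistan communities of a
factorial plantation-by-season design, and how soil functioning co-varies
with them.

The package is built for the common design of two forest plantation types
(Chinese pine, `CP`; Chinese scholar tree, `CS`) sampled in four seasons
(`SP`/`SU`/`AU`/`WI`) with replicated composite soil samples, but every
function takes plain tables and trees and applies to any comparable survey.

## The core method

Community assembly is inferred pair-by-pair with the phylogenetic
null-model framework. For two communities the **beta mean nearest taxon
distance**

βMNTD(A,B) = ½ [ Σᵢ∈A fᵢ minⱼ∈B d(i,j) + Σⱼ∈B fⱼ minᵢ∈A d(j,i) ]

measures abundance-weighted phylogenetic turnover (d = patristic distance,
f = relative abundance). The **beta nearest taxon index** (βNTI) is its
z-score against a null that shuffles taxon labels across the tips of the
tree (999 replicates by default). The **abundance-based Raup–Crick index**
(RC) standardises Bray–Curtis dissimilarity against null communities that
preserve each sample's richness and depth, with occupancy drawn by
occurrence frequency and abundances filled from the pooled relative
abundances. Pairwise turnover is then partitioned:

| condition | process |
|---|---|
| βNTI > +2 | variable selection |
| βNTI < −2 | homogeneous selection |
| \|βNTI\| ≤ 2, RC > +0.95 | dispersal limitation |
| \|βNTI\| ≤ 2, RC < −0.95 | homogenizing dispersal |
| otherwise | undominated |

Around this core the package provides α-diversity (Shannon, Simpson,
Chao1, ACE, observed richness, Faith's PD), Bray–Curtis β-diversity and
PERMANOVA (`vegan::adonis2` with seeded, optionally exhaustive
permutations), soil multifunctionality indices (z-scored 16/10/6 attribute
panel plus a 32-attribute net index; pH excluded), eco-enzymatic
stoichiometry ratios, QMEC HT-qPCR filtering (Ct < 31, efficiency
1.8–2.2, melting-curve flag), protist trophic profiles, and Spearman
co-occurrence networks with AD/ACC/APL summaries and betweenness-ranked
key nodes. A seeded synthetic-data generator produces phylogenies,
community tables under five assembly regimes, attribute panels and Ct
matrices so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(soilassembly)

tree <- simulate_tree(1024, seed = 5)
spec <- regime_spec("homogeneous_selection", n_samples_per_group = 3,
                    n_groups = 4, seed = 101)
sim  <- simulate_communities(tree, spec)

asm <- assembly_analysis(sim$table, sim$tree, sim$frame,
                         n_null = 199, seed = 7)
head(asm$pairs[, c("sample_i", "sample_j", "bnti", "rc", "process")], 3)
#>   sample_i sample_j      bnti        rc               process
#> 1  CP_AU_1  CP_AU_2 -3.406157 0.9648241 homogeneous_selection
#> 2  CP_AU_1  CP_AU_3 -3.472246 1.0000000 homogeneous_selection
#> 3  CP_AU_2  CP_AU_3 -3.653975 0.8190955 homogeneous_selection

asm$fractions[1, c("group", "homogeneous_selection", "undominated")]
#>   group homogeneous_selection undominated
#> 1 CP.AU                     1           0
```

βNTI below −2 on every within-group pair: the communities are more
phylogenetically similar than the tip-shuffle null expects, so turnover in
this simulated regime is governed by homogeneous selection — and the
partition recovers exactly the regime the generator planted. On neutral
simulations the same pipeline leaves ~all pairs `undominated`.

The full pipeline (diversity → assembly → multifunctionality → network →
QMEC → cross-stage correlation report) runs from one config:

```r
run_pipeline(default_config(out_dir = "run1", seed = 42))
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/soilassembly run --out run1 --seed 42
Rscript inst/cli/soilassembly simulate --out fixtures --regime neutral --seed 1
```

Outputs are tidy CSVs plus a manifest recording the config hash and every
derived stage seed; a fixed master seed reproduces every output file
byte-for-byte.

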