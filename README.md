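# auxofill

Filling gaps in bacterial amino-acid biosynthesis pathways from pooled
mutant fitness data.

## The problem

Automated genome annotations routinely predict that free-living,
prototrophic bacteria are auxotrophs: for one or more amino acids, a
required biosynthetic reaction has no assigned gene — a *gap* — even
though the organism grows in minimal media. Most gaps are annotation
artifacts; a few are genuine holes in biological knowledge whose
enzymes remain to be discovered. `auxofill` is an R package for
auditing and filling these gaps with genome-wide fitness data from
pools of randomly barcoded transposon mutants (RB-TnSeq / BarSeq), for
microbial geneticists and genome curators working with such compendia.

The core quantities:

* **Gene fitness** `f`: the log2 change in the relative abundance of a
  gene's mutants over a pooled growth experiment (condition vs. paired
  time0 sample), estimated per strain as
  `log2(cpm_cond + p) − log2(cpm_t0 + p)`, averaged over the gene's
  central insertions (central 10–90% of the gene) with time0-read
  weights capped at 20, and median-centered per scaffold so typical
  genes score 0. Fitness under −2 is a strong growth defect.
* **Essentiality**: genes long enough to judge are called essential
  when both their GC-normalized central insertion-site density and
  central reads per nucleotide are below 20% of the median gene's
  value.
* **Gap classification**: per amino acid, the pathway variant with the
  fewest unannotated steps defines the gaps; a gene annotated with the
  missing capability by ≥ 2 of 3 independent resources is a *clear
  candidate*; fitness evidence classifies each gap
  (auxotrophic / essential / redundant / genuine), and a genome-wide
  rescue scan (mean fitness under −2 in minimal media, above −1 with
  the amino acid added) proposes fillers for genuine gaps.
* **Cofitness**: Pearson correlation of fitness profiles across
  experiments; pathway partners correlate strongly. Phylogenetic
  presence/absence profiles corroborate functional links.

A synthetic-data generator (`simulate_world()`) plants essential genes,
auxotrophy roles, redundant pairs and annotation gaps with known truth,
so the entire pipeline is testable end to end without external data.

## Worked example

```r
library(auxofill)

w <- simulate_world(n_genes = 200, target_strains = 4000, seed = 7)
w
#> <auxo_world>
#>   genome:      1 scaffold(s), 213,248 nt
#>   genes:       200 (20 essential, 18 auxotrophy roles)
#>   pool:        4000 strains
#>   experiments: 20 conditions, 2 time0 sample(s)

an <- analyze_world(w)
an$ledger
#> <gap_ledger> 6 gap(s)
#> # A tibble: 4 × 3
#>   group           subgroup              cases
#>   <chr>           <chr>                 <int>
#> 1 Clear candidate "auxotrophic"             2
#> 2 Clear candidate "other (redundant)"       1
#> 3 Transaminase    ""                        2
#> 4 Genuine gap     "filled (this study)"     1

dplyr::select(an$gaps, amino_acid, reaction_id, classification, filled_by)
#> # A tibble: 6 × 4
#>   amino_acid reaction_id                       classification    filled_by
#>   <chr>      <chr>                             <chr>             <chr>
#> 1 his        histidinol_phosphate_transaminase transaminase      <NA>
#> 2 his        histidinol_phosphate_phosphatase  genuine_filled    g0170
#> 3 met        cog2122_activation                clear_auxotrophic <NA>
#> 4 ser        phosphoserine_transaminase        transaminase      <NA>
#> 5 thr        aspartate_kinase                  clear_redundant   <NA>
#> 6 thr        homoserine_kinase                 clear_auxotrophic <NA>
```

Reading the ledger: the two baseline-only annotation drops surface as
clear candidates confirmed auxotrophic by the fitness data; the
reaction backed by a planted redundant gene pair is classified
redundant (two clear candidates, neither with a phenotype); the
geneless transaminase steps are exempt from auxotrophy prediction; and
the histidinol-phosphate phosphatase — annotated by no resource — is a
genuine gap that the rescue scan fills with `g0170`, which is exactly
the planted gene (`w$truth` confirms). The rescue evidence itself:

```r
head(rescue_scan(an$gene_fit, w$experiments, "his"), 3)
#> # A tibble: 3 × 5
#>   gene_id compound fitness_minimal fitness_supplemented rescued
#>   <chr>   <chr>              <dbl>                <dbl> <lgl>
#> 1 g0119   his                -4.44              0.0155  TRUE
#> 2 g0096   his                -4.39              0.0186  TRUE
#> 3 g0001   his                -4.24             -0.00325 TRUE
```

Histidine-pathway mutants are sick in minimal media (fitness ≈ −4.4)
and healthy with 1 mM histidine (≈ 0) — the genetic signature of a
histidine biosynthesis gene. `plot_rescue()`, `plot_gene_fitness()`
and the `autoplot()` methods draw the corresponding figures;
`top_cofit()` ranks cofitness partners; `tidy()`/`glance()` expose the
GC-density fit. See the methods vignette
(`vignettes/gap-filling-methods.Rmd`) for the models, thresholds and
their rationale.

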