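---
title: "Methods: filling amino-acid biosynthesis gaps from pooled mutant fitness data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filling amino-acid biosynthesis gaps from pooled mutant fitness data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxofill)
```

## The problem

Automated metabolic reconstructions routinely predict that free-living,
prototrophic bacteria cannot synthesize several amino acids: the
annotation pipeline finds no gene for one or more required reactions and
calls the organism an auxotroph, even though the organism demonstrably
grows in minimal media. Each such missing reaction is a *gap*. Most gaps
are annotation artifacts — the gene exists but was missed by the
baseline resource — while a minority are genuine holes in biological
knowledge whose enzymes remain to be discovered.

`auxofill` implements a genetics-driven audit of these gaps using
genome-wide fitness data from pools of randomly barcoded transposon
mutants (RB-TnSeq). The logic is:

1. **Enumerate gaps.** For each amino acid, choose the pathway variant
   with the fewest unannotated steps under the baseline resource; the
   remaining unannotated steps are the gaps.
2. **Look for clear candidates.** A gene annotated with the missing
   enzymatic capability by at least two of three independent annotation
   resources is a *clear candidate*: the gap is almost certainly an
   artifact of the baseline.
3. **Test candidates with fitness data.** A real biosynthesis gene
   should be important for fitness in defined minimal media (fitness
   ≤ −2 is a strong defect) and near-neutral wherever amino acids are
   supplied; or it may be essential outright, because its pathway
   overlaps another essential process.
4. **Fill genuine gaps by rescue.** For gaps with no clear candidate,
   scan the whole genome for genes whose mutants are sick in minimal
   media (mean fitness under −2) but healthy when the one relevant
   amino acid is added (mean fitness above −1). A rescued gene not
   already assigned to another step of the pathway is the proposed
   filler.
5. **Corroborate with cofitness.** Genes acting in one pathway have
   correlated fitness profiles across a diverse compendium, and
   phylogenetic presence/absence profiles of interacting proteins are
   concordant across genomes.

Transaminase gaps are exempt from auxotrophy prediction: amino-acid
transaminases are promiscuous, and organisms typically carry several
genes with overlapping substrate ranges, so the absence of the
specifically named transaminase means little.

## The fitness statistic

For strain $s$ in an experiment with condition sample $c$ and paired
before-growth (time0) sample $t$, the raw strain fitness is

$$
f_s \;=\; \log_2\!\big(\mathrm{cpm}_c(s) + p\big)
      \;-\; \log_2\!\big(\mathrm{cpm}_t(s) + p\big),
$$

where cpm is counts per million within the sample and $p$ (default 1)
is a pseudocount on the cpm scale, as in standard log-cpm transforms.
Working on relative abundances makes the statistic exactly invariant to
sequencing depth and exactly antisymmetric under swapping the two
samples — properties the test suite asserts at $10^{-12}$. Strains with
fewer than 3 time0 reads are dropped.

Gene fitness is the weighted mean of the gene's *central* strains —
insertions with central fraction $f_c = (\mathrm{pos} - \mathrm{begin} +
0.5)/\mathrm{length}$ in $[0.1, 0.9]$, since terminal insertions often
leave the protein functional — with weights $\min(t_s, 20)$ time0
reads. The cap keeps one deeply sequenced strain from dominating. A
gene × experiment value is reported only when the qualifying strains
carry ≥ 30 summed time0 reads (the coverage threshold is a package
default; the underlying assay literature does not fix one). Each
experiment is then centered by subtracting the per-scaffold median
(genome-wide median for scaffolds with < 10 genes with values), so the
typical gene scores 0. Downstream classification averages fitness
within replicate groups before applying thresholds.

Experiment quality uses two simplified internal-consistency metrics:
the correlation between gene fitness computed from each gene's first
and second half, and the fraction of genes with $|f| > 1$. The
correlation criterion only applies when at least 10 genes show
$|f| > 1$: with no phenotypes anywhere (e.g., a clean rich-media
experiment) the half-gene correlation is pure noise and would otherwise
flag exactly the amino-acid-replete experiments the classifier needs as
its neutral reference.

## Essentiality calling

A gene is putatively essential when its mutants are absent from the
pool: among genes long enough to judge, both the density of distinct
central insertion locations — a location is a (scaffold, position,
strand) triple, since transposon junctions are strand-specific — and
the central reads per nucleotide must be below 20% of the typical
(median) gene's value. Insertion density depends on local GC, so the
density is first normalized by an ordinary least-squares fit of density
on gene GC, floored at 10% of the median density; with a degenerate GC
spread (< 0.01) the model falls back to the constant median. The
default length floor is derived from the pool itself: the smallest
length whose expected central insertion count $0.8 \cdot L \cdot
\hat d$ reaches 4, so that zero insertions is genuinely surprising
(about 250–500 nt at realistic pool densities).

## Gap classification vocabulary

Each gap receives exactly one classification:

| classification | meaning |
|---|---|
| `clear_auxotrophic` | clear candidate, sick in minimal media, rescued by amino acids |
| `clear_essential` | clear candidate in the essential set |
| `clear_nodata` | clear candidate without usable fitness data |
| `clear_redundant` | ≥ 2 measured, phenotype-free clear candidates (genetic redundancy) |
| `clear_multiple` | ≥ 2 clear candidates, evidence insufficient to choose |
| `clear_other` | clear candidate, measured, unexpectedly phenotype-free |
| `gene_model_error` | curated: sequencing or gene-calling artifact |
| `transaminase` | promiscuous transaminase step, exempt from prediction |
| `known` | curated: already filled in the literature |
| `genuine_filled` | no clear candidate; rescue scan proposes a filler |
| `genuine_unfilled` | no clear candidate and no rescued gene |

The split between `clear_redundant` and `clear_multiple` required a
decision: we call a gap redundant only when at least two clear
candidates were *measured* and show no phenotype — the observable
signature of genetic redundancy — and `clear_multiple` otherwise (for
example, candidates without fitness data). Similarly, "important in
most defined media conditions" is operationalized as fitness ≤ −2 in at
least 50% of defined-minimal replicate groups with data, with the
median replete fitness ≥ −0.5; both knobs are exposed
(`phenotype_call()` arguments `t_defect`, `t_neutral`,
`frac_defined`). Rescue thresholds use strict inequalities (under −2,
above −1). A rescued gene already annotated to another step of the same
pathway variant is excluded as a filler, so an upstream-pathway
auxotroph (e.g., homoserine dehydrogenase rescued by threonine) cannot
spuriously fill a downstream gap.

Casamino acids is treated as amino-acid replete although it lacks
tryptophan; a configuration flag in `amino_acid_available()` controls
whether it covers `trp` when judging tryptophan genes.

## The synthetic-data generator

Because the original fitness compendia live in an interactive browser
rather than flat archives, every stage is validated against synthetic
worlds with planted ground truth (`simulate_world()`):

* **Genome and genes** — non-overlapping genes on alternating strands,
  lengths uniform in ±30% of 900 nt, per-gene GC uniform in
  [0.35, 0.65] and realized in the sequence composition.
* **Truth** — 10% essential genes; one auxotrophy gene per
  non-transaminase step of the packaged histidine, methionine (DUF39
  route), serine and threonine pathways, each with effect −4 (log2) in
  defined media lacking its amino acid and 0 wherever it is available;
  one redundant pair (both neutral) on aspartate kinase.
* **Pool** — 20 strains per gene (the empirical density of real
  barcoded Tn5 libraries, roughly 80k insertions per 4k-gene genome),
  insertion probability proportional to $1 + s\,(\mathrm{GC}_{local} -
  0.5)$ floored at 0.05, no insertions in the central 10–90% of
  essential genes (edge insertions allowed), unique random 20-nt
  barcodes, ≥ 2 mapping reads per strain.
* **Counts** — time0 abundances log-normal with σ = 0.5 log2 units (the
  assay literature reports no abundance distribution; this is a
  declared guess), condition abundance $a_0 \cdot 2^{g + f}$ with g
  drawn in [4, 8] generations, Poisson counts at 50 reads/strain
  (negative-binomial overdispersion available). Effects apply to
  central insertions only, matching the estimator's central-window
  assumption.
* **Experiments** — per replicate: minimal glucose and minimal
  succinate, minimal + each amino acid at 1 mM, casamino acids, rich
  media; plus one amino-acid-as-nitrogen-source experiment per amino
  acid. Twenty conditions in all, so cofitness has n ≥ 15.
* **Annotations** — a baseline plus three resources annotate every role
  gene with its reaction, except where the drop specification removes
  them. The default world plants: a genuine gap (histidinol-phosphate
  phosphatase, annotated nowhere), two clear-candidate gaps (dropped
  from the baseline only), a redundant pair behind a baseline-dropped
  reaction, and the geneless transaminase steps.

What the generator does **not** emulate: operon structure and polar
effects, sequencing error and chimeric barcodes, read-level data,
condition-specific effect heterogeneity, and the mild non-Poisson
overdispersion of real BarSeq counts. Passing recovery tests therefore
demonstrate the pipeline's correctness and statistical behavior under
its own model, not robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

* Median centering is exact: per-scaffold medians are 0 to within
  1e−9 after normalization.
* Variant selection ties break on the lexicographically smallest
  variant id; candidate ties break on descending support, then a
  preference for phenotype-informative candidates, then gene id.
* Cofitness is undefined (dropped, not NA-propagated) below 15 shared
  experiments or at zero variance; the all-pairs surface is restricted
  to a query gene (`top_cofit()`) to stay linear in interest.
* A gene with zero central strains yields a missing fitness entry, not
  an error; an all-zero time0 sample is an error.
* Worlds are byte-deterministic given a seed: rerunning
  `simulate_world()` and `write_world()` reproduces identical files.

## Problem sizes used in validation

The recovery suite runs twenty replicate default worlds (500 genes,
10,000 strains, 20 conditions, 50 reads/strain) and checks: gene
fitness mean absolute error < 0.3 against planted effects in
{0, −2, −4}; auxotroph recovery at ≥ 95% sensitivity and precision;
essential recovery at ≥ 90%; the planted genuine gap filled by the
correct gene in ≥ 95% of replicates; fitted GC-bias slope within 2
standard errors of its analytic expectation; and within-pathway median
cofitness at least 0.5 above background. These sizes keep a full run in
a few minutes on one core while leaving every per-gene statistic
well-powered.

## Limitations

* The classification of real organisms depends on curated inputs (known
  gaps, gene-model errors) that the package accepts but cannot derive.
* The baseline resource's internal pathway logic is opaque in the wild;
  the fewest-missing-steps variant rule is a declared approximation,
  and a per-organism override table can represent baselines that make
  no prediction either way.
* Essentiality calls conflate "essential" with "required for good
  growth in rich media"; domain-level essentiality within genes is out
  of scope.
* The homology searches that produce the annotation tables are
  upstream of this package: it consumes their outputs and never runs
  them.
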