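#' Per-strain fitness from barcode counts
#'
#' Strain fitness is the log2 change in a strain's relative abundance
#' between a condition sample and its paired time0 (before-growth)
#' sample. Counts are converted to counts per million within each sample
#' (which makes the statistic exactly invariant to sequencing depth and
#' exactly antisymmetric under swapping the two samples) and smoothed
#' with an additive pseudocount on the CPM scale, as in standard
#' log-cpm transforms:
#' `raw = log2(cpm_cond + pseudocount) - log2(cpm_t0 + pseudocount)`.
#' Strains with fewer than `min_t0_reads` time0 reads are set to `NA`:
#' their abundance is too uncertain to use.
#'
#' @param counts Wide count table: `barcode` plus one column per sample.
#' @param experiments Experiments table linking each `exp_id` to its
#'   `time0_id`.
#' @param pseudocount Additive smoother on the counts-per-million scale
#'   (> 0).
#' @param min_t0_reads Minimum time0 reads for a usable strain.
#' @return Long tibble: `barcode`, `exp_id`, `raw_fitness`, `t0_reads`,
#'   `cond_reads`.
#' @export
strain_fitness <- function(counts, experiments, pseudocount = 1,
                           min_t0_reads = 3) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  assert_columns(counts, "barcode", "`counts`")
  assert_columns(experiments, c("exp_id", "time0_id"), "`experiments`")
  missing <- setdiff(
    c(experiments$exp_id, experiments$time0_id), names(counts)
  )
  if (length(missing) > 0) {
    abort(sprintf("`counts` lacks sample column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- vector("list", nrow(experiments))
  for (i in seq_len(nrow(experiments))) {
    e <- experiments[i, ]
    t0 <- counts[[e$time0_id]]
    cond <- counts[[e$exp_id]]
    if (sum(t0) == 0) {
      abort(sprintf("time0 sample '%s' has no reads.", e$time0_id))
    }
    cpm_t0 <- t0 / sum(t0) * 1e6
    cpm_c <- cond / sum(cond) * 1e6
    raw <- log2(cpm_c + pseudocount) - log2(cpm_t0 + pseudocount)
    raw[t0 < min_t0_reads] <- NA_real_
    out[[i]] <- tibble(
      barcode = counts$barcode, exp_id = e$exp_id,
      raw_fitness = raw, t0_reads = t0, cond_reads = cond
    )
  }
  bind_rows(out)
}

#' Per-gene fitness from strain fitness
#'
#' Gene fitness is a weighted mean of the raw fitness of the gene's
#' central strains (insertions in the central 10-90% of the gene), with
#' weights `min(t0_reads, 20)` so that a single deeply sequenced strain
#' cannot dominate. A gene x experiment entry is reported only when at
#' least one qualifying strain exists and the qualifying strains' summed
#' time0 reads reach `min_t0_reads_per_gene`; otherwise the entry is
#' missing (insufficient coverage is not an error).
#'
#' @param strain_fit Output of [strain_fitness()].
#' @param pool Insertion pool table.
#' @param genes Gene table.
#' @param min_t0_reads_per_strain Per-strain time0 read floor.
#' @param min_t0_reads_per_gene Per-gene summed time0 read floor.
#' @param weight_cap Cap on the per-strain time0-read weight.
#' @return Tibble `gene_id`, `exp_id`, `fitness`, `n_strains`,
#'   `t0_reads` (summed over used strains).
#' @export
gene_fitness <- function(strain_fit, pool, genes,
                         min_t0_reads_per_strain = 3,
                         min_t0_reads_per_gene = 30,
                         weight_cap = 20) {
  pool2 <- if ("central" %in% names(pool)) pool else assign_genes(pool, genes)
  central <- pool2 |>
    filter(.data$central) |>
    select("barcode", "gene_id")
  strain_fit |>
    inner_join(central, by = "barcode") |>
    filter(!is.na(.data$raw_fitness),
           .data$t0_reads >= min_t0_reads_per_strain) |>
    group_by(.data$gene_id, .data$exp_id) |>
    summarise(
      fitness = sum(pmin(.data$t0_reads, weight_cap) * .data$raw_fitness) /
        sum(pmin(.data$t0_reads, weight_cap)),
      n_strains = n(),
      t0_reads = sum(.data$t0_reads),
      .groups = "drop"
    ) |>
    filter(.data$t0_reads >= min_t0_reads_per_gene)
}

#' Normalize gene fitness so typical genes score zero
#'
#' Subtracts, per experiment, the median fitness of each scaffold's
#' genes, so that the typical (phenotype-free) gene has fitness 0 and
#' values are comparable across experiments. Scaffolds with fewer than
#' `min_genes_per_scaffold` genes with values fall back to the
#' genome-wide median for that experiment.
#'
#' @param gene_fit Tibble from [gene_fitness()].
#' @param genes Gene table (for the gene-to-scaffold map).
#' @param min_genes_per_scaffold Minimum genes for a per-scaffold median.
#' @return `gene_fit` with `fitness` centered.
#' @export
normalize_fitness <- function(gene_fit, genes, min_genes_per_scaffold = 10) {
  gene_fit |>
    left_join(select(genes, "gene_id", "scaffold_id"), by = "gene_id") |>
    group_by(.data$exp_id) |>
    mutate(genome_median = median(.data$fitness)) |>
    group_by(.data$exp_id, .data$scaffold_id) |>
    mutate(
      center = if (n() >= min_genes_per_scaffold)
        median(.data$fitness) else .data$genome_median[1],
      fitness = .data$fitness - .data$center
    ) |>
    ungroup() |>
    select(-"center", -"genome_median", -"scaffold_id")
}

#' Wide gene-by-experiment fitness matrix
#'
#' @param gene_fit Long fitness tibble.
#' @return Tibble with `gene_id` and one column per experiment; missing
#'   entries are `NA`.
#' @export
fitness_matrix <- function(gene_fit) {
  gene_fit |>
    select("gene_id", "exp_id", "fitness") |>
    tidyr::pivot_wider(names_from = "exp_id", values_from = "fitness") |>
    arrange(.data$gene_id)
}

#' Simplified per-experiment quality metrics
#'
#' For each experiment, computes (a) the correlation between gene
#' fitness estimated from insertions in the first half of each gene and
#' from the second half (an internal-consistency check: genuine
#' phenotypes reproduce across independent insertion sites), (b) the
#' median absolute gene fitness, and (c) the fraction of genes with
#' |fitness| > 1. An experiment is flagged low quality when the
#' half-gene correlation falls below `min_cor` - provided at least
#' `min_strong_genes` genes show |fitness| > 1, since the correlation
#' is uninformative when nothing has a phenotype - or when the strong
#' fraction exceeds `max_strong_frac` (a symptom of a failed assay).
#'
#' @param strain_fit Output of [strain_fitness()].
#' @param pool,genes Pool and gene tables.
#' @param min_cor Half-gene correlation threshold.
#' @param max_strong_frac Maximum tolerated fraction of |f| > 1 genes.
#' @param min_strong_genes Minimum phenotype-bearing genes for the
#'   correlation criterion to apply.
#' @return Tibble `exp_id`, `half_cor`, `median_abs_f`, `strong_frac`,
#'   `n_strong`, `low_quality`.
#' @export
experiment_quality <- function(strain_fit, pool, genes, min_cor = 0.4,
                               max_strong_frac = 0.25,
                               min_strong_genes = 10) {
  pool2 <- if ("central" %in% names(pool)) pool else assign_genes(pool, genes)
  central <- pool2 |>
    filter(.data$central) |>
    select("barcode", "gene_id", "central_frac")
  dat <- strain_fit |>
    inner_join(central, by = "barcode") |>
    filter(!is.na(.data$raw_fitness), .data$t0_reads >= 3)

  full <- dat |>
    group_by(.data$exp_id, .data$gene_id) |>
    summarise(f = weighted_fitness(.data$raw_fitness, .data$t0_reads),
              .groups = "drop")
  halves <- dat |>
    mutate(half = if_else(.data$central_frac < 0.5, "f1", "f2")) |>
    group_by(.data$exp_id, .data$gene_id, .data$half) |>
    summarise(f = weighted_fitness(.data$raw_fitness, .data$t0_reads),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "f")
  if (!"f1" %in% names(halves)) halves$f1 <- NA_real_
  if (!"f2" %in% names(halves)) halves$f2 <- NA_real_

  cors <- halves |>
    group_by(.data$exp_id) |>
    summarise(
      half_cor = safe_cor(.data$f1, .data$f2),
      .groups = "drop"
    )
  full |>
    group_by(.data$exp_id) |>
    summarise(
      median_abs_f = median(abs(.data$f)),
      strong_frac = mean(abs(.data$f) > 1),
      n_strong = sum(abs(.data$f) > 1),
      .groups = "drop"
    ) |>
    left_join(cors, by = "exp_id") |>
    mutate(
      low_quality = .data$strong_frac > max_strong_frac |
        (.data$n_strong >= min_strong_genes &
           (is.na(.data$half_cor) | .data$half_cor < min_cor))
    ) |>
    select("exp_id", "half_cor", "median_abs_f", "strong_frac",
           "n_strong", "low_quality")
}

weighted_fitness <- function(raw, t0, cap = 20) {
  w <- pmin(t0, cap)
  sum(w * raw) / sum(w)
}

safe_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}
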