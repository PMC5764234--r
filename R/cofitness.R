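#' Cofitness of two genes
#'
#' Pearson correlation of two genes' fitness profiles over the
#' experiments where both have values (pairwise-complete). High
#' cofitness across a diverse compendium is evidence of shared
#' function. The record is undefined - a zero-row tibble - when fewer
#' than `min_experiments` shared experiments exist or either profile
#' has zero variance: small-n correlations are noise.
#'
#' @param gene_fit Long fitness tibble (normalized).
#' @param gene_a,gene_b Gene ids (must be present in the matrix).
#' @param min_experiments Minimum shared experiments.
#' @return Tibble `gene_a`, `gene_b`, `r`, `n` (0 or 1 rows).
#' @export
cofitness <- function(gene_fit, gene_a, gene_b, min_experiments = 15) {
  wide <- fitness_matrix(gene_fit)
  for (g in unique(c(gene_a, gene_b))) {
    if (!g %in% wide$gene_id) abort(sprintf("Unknown gene '%s'.", g))
  }
  a <- profile_of(wide, gene_a)
  b <- profile_of(wide, gene_b)
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < min_experiments ||
      stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  r = numeric(0), n = integer(0)))
  }
  tibble(gene_a = gene_a, gene_b = gene_b,
         r = cor(a[ok], b[ok]), n = n)
}

profile_of <- function(wide, gene) {
  as.numeric(wide[match(gene, wide$gene_id), -1])
}

#' Top cofit partners of a gene
#'
#' Ranks all other genes by descending cofitness with `gene` (ties
#' broken by gene id) and returns the strongest `k` defined records.
#' Undefined pairs (too few shared experiments, zero variance) are
#' dropped, so fewer than `k` records may return.
#'
#' @param gene_fit Long fitness tibble.
#' @param gene Query gene id.
#' @param k Number of partners to return.
#' @param min_experiments Minimum shared experiments per pair.
#' @return Tibble `gene_a`, `gene_b`, `r`, `n`.
#' @export
top_cofit <- function(gene_fit, gene, k = 10, min_experiments = 15) {
  if (k < 1) abort("`k` must be at least 1.")
  wide <- fitness_matrix(gene_fit)
  if (!gene %in% wide$gene_id) abort(sprintf("Unknown gene '%s'.", gene))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  x <- m[gene, ]
  others <- setdiff(wide$gene_id, gene)
  shared <- colSums(!is.na(t(m[others, , drop = FALSE])) & !is.na(x))
  r <- suppressWarnings(
    as.numeric(cor(x, t(m[others, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
  )
  tibble(gene_a = gene, gene_b = others, r = r, n = as.integer(shared)) |>
    filter(.data$n >= min_experiments, is.finite(.data$r)) |>
    arrange(desc(.data$r), .data$gene_b) |>
    slice_head(n = k)
}

#' Phylogenetic-profile concordance
#'
#' Fraction of genomes on which two presence/absence profiles agree.
#' Profiles share one genome ordering (the non-id columns of
#' `profiles`); manual overrides - e.g., a protein split into two genes
#' that an ortholog scan misses - are applied before comparison.
#'
#' @param profiles Tibble: `entity_id` plus one 0/1 column per genome.
#' @param entity_a,entity_b Entity ids to compare.
#' @param overrides Optional tibble `entity_id`, `genome`, `value`
#'   (0/1), `note`.
#' @return Tibble `entity_a`, `entity_b`, `concordance`, `n_genomes`.
#' @export
profile_concordance <- function(profiles, entity_a, entity_b,
                                overrides = NULL) {
  assert_columns(profiles, "entity_id", "`profiles`")
  genomes <- setdiff(names(profiles), "entity_id")
  if (!is.null(overrides) && nrow(overrides) > 0) {
    assert_columns(overrides, c("entity_id", "genome", "value"), "`overrides`")
    bad <- setdiff(overrides$genome, genomes)
    if (length(bad) > 0) {
      abort(sprintf("Override genome(s) not in profile table: %s",
                    paste(bad, collapse = ", ")))
    }
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$entity_id[i], profiles$entity_id)
      if (!is.na(j)) profiles[j, overrides$genome[i]] <- overrides$value[i]
    }
  }
  row_of <- function(id) {
    j <- match(id, profiles$entity_id)
    if (is.na(j)) abort(sprintf("Unknown entity '%s'.", id))
    as.numeric(profiles[j, genomes])
  }
  a <- row_of(entity_a)
  b <- row_of(entity_b)
  tibble(
    entity_a = entity_a, entity_b = entity_b,
    concordance = mean(a == b), n_genomes = length(genomes)
  )
}
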