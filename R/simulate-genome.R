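#' Simulate a bacterial genome with non-overlapping gene models
#'
#' Generates one or more scaffolds of A/C/G/T sequence carrying
#' non-overlapping protein-coding genes on alternating strands. Each gene
#' is assigned an intended GC content drawn uniformly from `gc_range`,
#' which is realized in its nucleotide composition; intergenic sequence is
#' drawn at the midpoint GC of the range. Genes are laid down every 1000
#' genes per scaffold (the last scaffold may hold fewer).
#'
#' @param n_genes Number of genes to simulate.
#' @param mean_gene_len Mean gene length in nt; individual lengths are
#'   drawn uniformly in `[0.7, 1.3] * mean_gene_len`.
#' @param gc_range Length-2 numeric, low and high GC fraction (0 < low <=
#'   high < 1).
#' @param intergenic_len Length of intergenic spacers in nt.
#' @param genes_per_scaffold Genes per scaffold (default 1000).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `genome` (named character vector, scaffold id to
#'   sequence) and `genes` (tibble: `gene_id`, `scaffold_id`, `begin`,
#'   `end`, `strand`, `gc_intended`, `description`; 1-based inclusive
#'   coordinates).
#' @examples
#' gn <- simulate_genome(5, seed = 1)
#' gn$genes
#' @export
simulate_genome <- function(n_genes, mean_gene_len = 900,
                            gc_range = c(0.35, 0.65), intergenic_len = 150,
                            genes_per_scaffold = 1000, seed = 1L) {
  stop_if_not_scalar_count(n_genes, "n_genes")
  if (length(gc_range) != 2 || any(is.na(gc_range)) ||
      gc_range[1] <= 0 || gc_range[2] >= 1 || gc_range[1] > gc_range[2]) {
    abort("`gc_range` must satisfy 0 < low <= high < 1.")
  }
  intergenic_len <- as.integer(intergenic_len)
  withr::with_seed(seed, {
    lens <- as.integer(round(runif(n_genes, 0.7, 1.3) * mean_gene_len))
    gcs <- runif(n_genes, gc_range[1], gc_range[2])
    scaffold_of <- (seq_len(n_genes) - 1L) %/% genes_per_scaffold + 1L
    scaffold_ids <- sprintf("sc%02d", scaffold_of)
    mid_gc <- mean(gc_range)

    genome <- character(0)
    rows <- vector("list", n_genes)
    for (sc in unique(scaffold_of)) {
      idx <- which(scaffold_of == sc)
      pieces <- character(2 * length(idx) + 1)
      pieces[1] <- random_seq(intergenic_len, mid_gc)
      at <- as.integer(intergenic_len)
      for (j in seq_along(idx)) {
        i <- idx[j]
        pieces[2 * j] <- random_seq(lens[i], gcs[i])
        rows[[i]] <- tibble(
          gene_id = sprintf("g%04d", i),
          scaffold_id = scaffold_ids[i],
          begin = at + 1L,
          end = at + lens[i],
          strand = if (j %% 2 == 1) "+" else "-",
          gc_intended = gcs[i],
          description = ""
        )
        pieces[2 * j + 1] <- random_seq(intergenic_len, mid_gc)
        at <- at + lens[i] + intergenic_len
      }
      genome[sprintf("sc%02d", sc)] <- paste(pieces, collapse = "")
    }
    list(genome = genome, genes = bind_rows(rows))
  })
}

random_seq <- function(len, gc) {
  if (len == 0) return("")
  paste(
    sample(NUCLEOTIDES, len, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""
  )
}

#' Plant ground-truth phenotypes onto simulated genes
#'
#' Assigns biological roles used by the downstream recovery tests:
#' essential genes (whose mutants are absent from the pool), auxotrophy
#' genes (each providing one reaction of an amino-acid biosynthesis
#' pathway, with a strong fitness defect in defined media lacking that
#' amino acid and none when it is available), optional genetically
#' redundant pairs (two genes for one reaction, each individually
#' dispensable), and neutral genes.
#'
#' @param genes Gene table from [simulate_genome()].
#' @param pathways,reactions Pathway steps and reaction registry (see
#'   [aa_pathways()]). Transaminase steps never receive auxotrophy roles,
#'   mirroring their promiscuous substrate ranges.
#' @param frac_essential Fraction of genes made essential.
#' @param auxotroph_spec Either a named integer vector (`c(his = 3)`:
#'   assign genes to the first 3 non-transaminase steps of the preferred
#'   histidine variant) or a named list of reaction-id character vectors
#'   for explicit step control.
#' @param effect_size True fitness effect (log2 units, < 0) of an
#'   auxotroph mutant in defined media lacking its amino acid; a scalar
#'   or a vector named by amino acid.
#' @param redundant_spec Named character vector, amino acid to reaction
#'   id: plant one redundant gene pair on that reaction (each partner has
#'   effect 0).
#' @param seed Integer seed.
#' @return Truth tibble: `gene_id`, `essential`, `role` (reaction id or
#'   NA), `amino_acid`, `effect`, `redundancy_partner`. Essential genes
#'   have `effect = NA` (their mutants never enter the pool).
#' @export
plant_truth <- function(genes, pathways, reactions = NULL,
                        frac_essential = 0.1, auxotroph_spec = integer(0),
                        effect_size = -4, redundant_spec = character(0),
                        seed = 1L) {
  assert_columns(genes, "gene_id", "`genes`")
  validate_pathways(pathways, reactions)

  role_map <- resolve_roles(pathways, reactions, auxotroph_spec)
  n_roles <- sum(lengths(role_map))
  n_red <- 2L * length(redundant_spec)
  n_ess <- round(frac_essential * nrow(genes))
  if (n_roles + n_red + n_ess > nrow(genes)) {
    abort("Requested roles exceed the number of available genes.")
  }

  withr::with_seed(seed, {
    truth <- tibble(
      gene_id = genes$gene_id,
      essential = FALSE,
      role = NA_character_,
      amino_acid = NA_character_,
      effect = 0,
      redundancy_partner = NA_character_
    )
    free <- sample(truth$gene_id)

    take <- function(k) {
      out <- free[seq_len(k)]
      free <<- free[-seq_len(k)]
      out
    }

    for (aa in names(role_map)) {
      steps <- role_map[[aa]]
      ids <- take(length(steps))
      eff <- effect_for(effect_size, aa)
      i <- match(ids, truth$gene_id)
      truth$role[i] <- steps
      truth$amino_acid[i] <- aa
      truth$effect[i] <- eff
    }
    for (aa in names(redundant_spec)) {
      ids <- take(2L)
      i <- match(ids, truth$gene_id)
      truth$role[i] <- redundant_spec[[aa]]
      truth$amino_acid[i] <- aa
      truth$effect[i] <- 0
      truth$redundancy_partner[i] <- rev(ids)
    }
    if (n_ess > 0) {
      i <- match(take(n_ess), truth$gene_id)
      truth$essential[i] <- TRUE
      truth$effect[i] <- NA_real_
    }
    arrange(truth, .data$gene_id)
  })
}

effect_for <- function(effect_size, aa) {
  if (is.null(names(effect_size))) return(effect_size[[1]])
  if (!aa %in% names(effect_size)) {
    abort(sprintf("`effect_size` has no entry for amino acid '%s'.", aa))
  }
  effect_size[[aa]]
}

# Expand an auxotroph_spec into a named list: amino acid -> reaction ids.
resolve_roles <- function(pathways, reactions, auxotroph_spec) {
  if (is.list(auxotroph_spec)) {
    unknown <- setdiff(unlist(auxotroph_spec), pathways$reaction_id)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown reaction(s) in `auxotroph_spec`: %s",
                    paste(unknown, collapse = ", ")))
    }
    return(auxotroph_spec)
  }
  out <- list()
  for (aa in names(auxotroph_spec)) {
    sub <- filter(pathways, .data$amino_acid == aa)
    if (nrow(sub) == 0) {
      abort(sprintf("Amino acid '%s' is not in the pathway table.", aa))
    }
    variant <- sort(unique(sub$variant_id))[1]
    steps <- sub |>
      filter(.data$variant_id == variant) |>
      arrange(.data$step_index) |>
      pull(.data$reaction_id)
    if (!is.null(reactions)) {
      trans <- reactions$reaction_id[reactions$is_transaminase]
      steps <- setdiff(steps, trans)
    }
    k <- auxotroph_spec[[aa]]
    out[[aa]] <- steps[((seq_len(k) - 1L) %% length(steps)) + 1L]
  }
  out
}
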