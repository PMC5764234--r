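#' Simulate a complete synthetic study with planted ground truth
#'
#' Orchestrates the generator modules into one coherent "world": a
#' genome with gene models, planted essential/auxotrophy/redundancy
#' roles covering every non-transaminase step of the packaged histidine,
#' methionine (DUF39 route), serine and threonine pathways, a barcoded
#' insertion pool, a replicated experiment design, barcode count tables,
#' and multi-resource annotation tables with planted gaps.
#'
#' The default gap plan mirrors the situations the classifier must tell
#' apart: one genuine gap (the histidinol-phosphate phosphatase gene is
#' unannotated everywhere, so only the fitness data can find it), two
#' clear-candidate gaps (reactions dropped from the baseline but kept by
#' all other resources), one redundant pair behind a baseline-dropped
#' reaction, and the transaminase steps, which carry no dedicated gene
#' at all.
#'
#' @param n_genes Number of genes (default 500).
#' @param target_strains Pool size; default 20 strains per gene.
#' @param mean_depth_per_strain Sequencing depth per strain per sample.
#' @param frac_essential Fraction of essential genes.
#' @param effect_size Auxotroph fitness effect (log2) in unsupplemented
#'   defined media.
#' @param gc_bias_slope Insertion-density GC bias passed to
#'   [simulate_pool()].
#' @param genuine_gap Named character vector (amino acid -> reaction id)
#'   of gaps whose gene is annotated by no resource.
#' @param clear_gaps Named character vector of gaps dropped from the
#'   baseline only (clear candidates, support 3/3).
#' @param redundant_spec Named character vector of reactions carrying a
#'   redundant gene pair, also dropped from the baseline.
#' @param n_reps Replicates per condition.
#' @param seed Integer seed controlling every random draw.
#' @return An object of class `auxo_world`: a list with `genome`,
#'   `genes`, `truth`, `pool`, `experiments`, `counts`, `annotations`,
#'   `pathways`, `reactions`, `drop_spec`, and `params`.
#' @examples
#' \donttest{
#' w <- simulate_world(n_genes = 60, target_strains = 1200, seed = 1)
#' w
#' }
#' @export
simulate_world <- function(n_genes = 500,
                           target_strains = 20 * n_genes,
                           mean_depth_per_strain = 50,
                           frac_essential = 0.1,
                           effect_size = -4,
                           gc_bias_slope = 0,
                           genuine_gap = c(his = "histidinol_phosphate_phosphatase"),
                           clear_gaps = c(met = "cog2122_activation",
                                          thr = "homoserine_kinase"),
                           redundant_spec = c(thr = "aspartate_kinase"),
                           n_reps = 2,
                           seed = 1L) {
  pathways <- aa_pathways()
  reactions <- aa_reactions()

  # Every non-transaminase step of the preferred variant gets a role
  # gene, except steps reserved for redundant pairs; transaminase steps
  # are intentionally geneless (their activity is promiscuous).
  trans <- reactions$reaction_id[reactions$is_transaminase]
  role_map <- list()
  for (aa in c("his", "met", "ser", "thr")) {
    sub <- filter(pathways, .data$amino_acid == aa)
    variant <- sort(unique(sub$variant_id))[1]
    steps <- sub |>
      filter(.data$variant_id == variant) |>
      arrange(.data$step_index) |>
      pull(.data$reaction_id)
    steps <- setdiff(steps, trans)
    if (aa %in% names(redundant_spec)) {
      steps <- setdiff(steps, redundant_spec[[aa]])
    }
    # aspartate-semialdehyde dehydrogenase is shared between the
    # threonine pathway and the DUF39 methionine route; keep it under thr
    if (aa == "met") steps <- setdiff(steps, "aspartate_semialdehyde_dehydrogenase")
    role_map[[aa]] <- steps
  }

  gn <- simulate_genome(n_genes, seed = seed)
  truth <- plant_truth(
    gn$genes, pathways, reactions,
    frac_essential = frac_essential,
    auxotroph_spec = role_map,
    effect_size = effect_size,
    redundant_spec = redundant_spec,
    seed = seed + 1L
  )
  pool <- simulate_pool(gn$genome, gn$genes, truth, target_strains,
                        gc_bias_slope = gc_bias_slope, seed = seed + 2L)
  experiments <- simulate_experiments(
    amino_acids = c("his", "met", "thr", "ser"),
    n_reps = n_reps, seed = seed + 3L
  )
  counts <- simulate_counts(pool, gn$genes, truth, experiments,
                            mean_depth_per_strain = mean_depth_per_strain,
                            seed = seed + 4L)
  drop_spec <- bind_rows(
    tidyr::expand_grid(
      reaction_id = unname(genuine_gap),
      resource_id = c("baseline", sprintf("res%d", 1:3))
    ),
    tibble(reaction_id = unname(clear_gaps), resource_id = "baseline"),
    tibble(reaction_id = unname(redundant_spec), resource_id = "baseline")
  )
  annotations <- simulate_annotations(truth, pathways, reactions,
                                      n_resources = 3, drop_spec = drop_spec,
                                      seed = seed + 5L)
  structure(
    list(
      genome = gn$genome, genes = gn$genes, truth = truth, pool = pool,
      experiments = experiments, counts = counts, annotations = annotations,
      pathways = pathways, reactions = reactions, drop_spec = drop_spec,
      params = list(
        n_genes = n_genes, target_strains = target_strains,
        mean_depth_per_strain = mean_depth_per_strain,
        frac_essential = frac_essential, effect_size = effect_size,
        gc_bias_slope = gc_bias_slope, genuine_gap = genuine_gap,
        clear_gaps = clear_gaps, redundant_spec = redundant_spec,
        seed = seed
      )
    ),
    class = "auxo_world"
  )
}

#' @export
print.auxo_world <- function(x, ...) {
  cat("<auxo_world>\n")
  cat(sprintf("  genome:      %d scaffold(s), %s nt\n",
              length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  genes:       %d (%d essential, %d auxotrophy roles)\n",
              nrow(x$genes), sum(x$truth$essential),
              sum(!is.na(x$truth$role) & !x$truth$essential &
                    x$truth$effect < 0, na.rm = TRUE)))
  cat(sprintf("  pool:        %d strains\n", nrow(x$pool)))
  cat(sprintf("  experiments: %d conditions, %d time0 sample(s)\n",
              nrow(x$experiments), length(unique(x$experiments$time0_id))))
  invisible(x)
}

#' Run the full gap-filling analysis on a synthetic world
#'
#' Convenience pipeline: strain and gene fitness with per-scaffold
#' normalization, experiment quality, insertion statistics and
#' essentiality calls, gap enumeration with candidate consensus and
#' special-case flags, phenotype calls, per-amino-acid rescue scans, gap
#' classification and the final ledger summary.
#'
#' @param world An `auxo_world` from [simulate_world()].
#' @param organism Organism label used in gap records.
#' @param ... Passed on to [phenotype_call()] (thresholds).
#' @return A list with elements `strain_fit`, `gene_fit` (normalized),
#'   `quality`, `stats`, `essentials`, `gaps` (classified), `candidates`,
#'   `phenotypes`, `rescues`, and `ledger`.
#' @export
analyze_world <- function(world, organism = "synthetic", ...) {
  sf <- strain_fitness(world$counts, world$experiments)
  gf <- gene_fitness(sf, world$pool, world$genes)
  gfn <- normalize_fitness(gf, world$genes)
  qual <- experiment_quality(sf, world$pool, world$genes)
  stats <- gene_insertion_stats(world$pool, world$genes, world$genome)
  ess <- call_essential(stats)
  ess_ids <- ess$gene_id[ess$called]

  gaps <- find_gaps(world$annotations, world$pathways, organism = organism)
  cands <- clear_candidates(gaps, world$annotations)
  gaps <- flag_special(gaps, world$reactions)
  phen <- phenotype_call(gfn, world$experiments, ess_ids, ...)

  scanable <- intersect(
    unique(gaps$amino_acid),
    unlist(supplement_names(world$experiments$supplements))
  )
  rescues <- purrr::map_dfr(
    scanable,
    function(aa) rescue_scan(gfn, world$experiments, aa)
  )
  gaps <- classify_gaps(gaps, cands, phen, rescues,
                        world$annotations, world$pathways)
  list(
    strain_fit = sf, gene_fit = gfn, quality = qual, stats = stats,
    essentials = ess, gaps = gaps, candidates = cands, phenotypes = phen,
    rescues = rescues, ledger = summarize_ledger(gaps)
  )
}
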