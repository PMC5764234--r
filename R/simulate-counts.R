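#' Simulate an experiment design for a pooled fitness compendium
#'
#' Builds a defined/rich condition panel of the kind used in pooled
#' fitness compendia: replicated minimal-media experiments on two carbon
#' sources, one amino-acid-supplemented pair per amino acid of interest,
#' one experiment per amino acid with that amino acid as sole nitrogen
#' source, plus casamino-acids-supplemented and rich-media experiments.
#' Each condition sample is paired with a before-growth (time0) sample,
#' and each culture grows a total of 4-8 generations (drawn uniformly).
#'
#' @param amino_acids Amino acids to probe with supplements.
#' @param n_reps Replicates per condition (each replicate links to its
#'   own time0 sample).
#' @param supplement_mM Supplement concentration in mM.
#' @param extra_carbon Second carbon source for extra minimal replicates
#'   (`NULL` to omit).
#' @param seed Integer seed (generations are random).
#' @return Experiments tibble: `exp_id`, `media_class`, `supplements`
#'   (semicolon-separated `compound:mM`, empty when none),
#'   `carbon_source`, `nitrogen_source`, `replicate_group`, `time0_id`,
#'   `generations`.
#' @export
simulate_experiments <- function(amino_acids = c("his", "met", "thr", "ser"),
                                 n_reps = 2, supplement_mM = 1,
                                 extra_carbon = "succinate", seed = 1L) {
  stop_if_not_scalar_count(n_reps, "n_reps")
  withr::with_seed(seed, {
    rows <- list()
    add <- function(id, media, supp, carbon, nitrogen, group, rep) {
      rows[[length(rows) + 1L]] <<- tibble(
        exp_id = sprintf("%s_r%d", id, rep),
        media_class = media,
        supplements = supp,
        carbon_source = carbon,
        nitrogen_source = nitrogen,
        replicate_group = group,
        time0_id = sprintf("T0_%d", rep)
      )
    }
    for (r in seq_len(n_reps)) {
      add("min_glucose", "defined", "", "glucose", "ammonia", "min_glucose", r)
      if (!is.null(extra_carbon)) {
        add(paste0("min_", extra_carbon), "defined", "", extra_carbon,
            "ammonia", paste0("min_", extra_carbon), r)
      }
      for (aa in amino_acids) {
        add(paste0("plus_", aa), "defined",
            sprintf("%s:%g", aa, supplement_mM), "glucose", "ammonia",
            paste0("plus_", aa), r)
      }
      add("casamino", "defined", "casamino_acids:5", "glucose", "ammonia",
          "casamino", r)
      add("rich", "rich", "", "rich", "rich", "rich", r)
    }
    for (aa in amino_acids) {
      add(paste0(aa, "_nitrogen"), "defined", "", "glucose", aa,
          paste0(aa, "_nitrogen"), 1L)
    }
    bind_rows(rows) |>
      mutate(generations = runif(n(), 4, 8))
  })
}

#' True per-gene fitness effects for a set of experiments
#'
#' Expands a truth table over an experiment design: an auxotrophy-role
#' gene carries its planted effect in defined media where its amino acid
#' is unavailable, and 0 wherever the amino acid is supplied (directly,
#' as carbon or nitrogen source, via casamino acids or yeast extract, or
#' in rich media). Neutral and redundant genes are 0 everywhere;
#' essential genes are absent (their mutants do not exist).
#'
#' @param truth Truth tibble from [plant_truth()].
#' @param experiments Experiments tibble from [simulate_experiments()].
#' @return Long tibble `gene_id`, `exp_id`, `effect`.
#' @export
true_effects <- function(truth, experiments) {
  bad <- setdiff(unique(experiments$media_class), c("rich", "defined"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown media class(es): %s", paste(bad, collapse = ", ")))
  }
  aux <- filter(truth, !.data$essential, !is.na(.data$amino_acid),
                .data$effect < 0)
  grid <- tidyr::expand_grid(
    gene_id = filter(truth, !.data$essential)$gene_id,
    exp_id = experiments$exp_id
  ) |>
    mutate(effect = 0)
  for (aa in unique(aux$amino_acid)) {
    off <- experiments$exp_id[
      experiments$media_class == "defined" &
        !amino_acid_available(experiments, aa)
    ]
    gs <- filter(aux, .data$amino_acid == aa)
    hit <- grid$gene_id %in% gs$gene_id & grid$exp_id %in% off
    grid$effect[hit] <- gs$effect[match(grid$gene_id[hit], gs$gene_id)]
  }
  grid
}

#' Simulate barcode count tables for a pooled fitness assay
#'
#' Each strain's before-growth abundance is log-normal (sigma in log2
#' units); its abundance after growth is `a0 * 2^(g + f)` where `g` is
#' the experiment's total generations and `f` the true fitness effect of
#' the strain's gene in that condition (0 for neutral strains and for
#' insertions outside the central 10-90% of a gene, which are assumed
#' not to disrupt function). Counts are Poisson around abundances scaled
#' to the target sequencing depth; set `overdispersion > 0` for
#' negative-binomial noise instead.
#'
#' @param pool Pool tibble from [simulate_pool()].
#' @param genes Gene table.
#' @param truth Truth tibble from [plant_truth()].
#' @param experiments Experiments tibble from [simulate_experiments()].
#' @param mean_depth_per_strain Mean reads per strain per sample.
#' @param sigma_log2 Log2 standard deviation of time0 abundances.
#' @param overdispersion Negative-binomial overdispersion (0 = Poisson).
#' @param seed Integer seed.
#' @return Wide count tibble: `barcode`, then one non-negative integer
#'   column per time0 sample and per experiment.
#' @export
simulate_counts <- function(pool, genes, truth, experiments,
                            mean_depth_per_strain = 50, sigma_log2 = 0.5,
                            overdispersion = 0, seed = 1L) {
  if (nrow(experiments) == 0) abort("`experiments` must be non-empty.")
  if (mean_depth_per_strain <= 0) abort("`mean_depth_per_strain` must be > 0.")
  effects <- true_effects(truth, experiments)
  pool2 <- assign_genes(pool, genes)

  withr::with_seed(seed, {
    n <- nrow(pool2)
    a0 <- 2^rnorm(n, 0, sigma_log2)
    total <- n * mean_depth_per_strain
    draw <- function(lambda) {
      if (overdispersion > 0) {
        rnbinom(n, mu = lambda, size = 1 / overdispersion)
      } else {
        rpois(n, lambda)
      }
    }
    out <- tibble(barcode = pool2$barcode)
    for (t0 in unique(experiments$time0_id)) {
      out[[t0]] <- draw(a0 / sum(a0) * total)
    }
    eff_wide <- effects |>
      tidyr::pivot_wider(names_from = "exp_id", values_from = "effect")
    eff_i <- match(pool2$gene_id, eff_wide$gene_id)
    for (j in seq_len(nrow(experiments))) {
      e <- experiments[j, ]
      f <- ifelse(pool2$central & !is.na(eff_i),
                  eff_wide[[e$exp_id]][eff_i], 0)
      f[is.na(f)] <- 0
      ac <- a0 * 2^(e$generations + f)
      out[[e$exp_id]] <- draw(ac / sum(ac) * total)
    }
    out
  })
}
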