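#' Phenotype call per gene from fitness and essentiality evidence
#'
#' Partitions the experiments into defined-minimal (defined media
#' without an amino-acid-replete supplement) and amino-acid-replete
#' (rich media, or casamino acids / yeast extract added), averages
#' fitness within replicate groups, and classifies each gene:
#' `essential` (in the essential set, regardless of fitness data),
#' `no_data` (fitness missing in at least half the defined replicate
#' groups), `auxotrophic` (fitness at or below `t_defect` in at least
#' `frac_defined` of the defined groups with data, and median replete
#' fitness at or above `t_neutral` - the mutant is sick without amino
#' acids and healthy with them), else `no_phenotype`.
#'
#' @param gene_fit Normalized long fitness tibble.
#' @param experiments Experiments table.
#' @param essential_ids Character vector of essential gene ids.
#' @param t_defect Strong-defect threshold (log2 fitness).
#' @param t_neutral Near-neutral threshold for replete media.
#' @param frac_defined Fraction of defined groups that must show the
#'   defect.
#' @return Tibble `gene_id`, `class`, `median_defined`,
#'   `median_replete`, `n_defined`, `n_replete`.
#' @export
phenotype_call <- function(gene_fit, experiments, essential_ids = character(0),
                           t_defect = -2, t_neutral = -0.5,
                           frac_defined = 0.5) {
  parts <- partition_experiments(experiments)
  if (length(parts$defined) == 0) {
    abort("No defined-minimal experiments in the metadata.")
  }
  grp <- replicate_means(gene_fit, experiments)
  n_defined_groups <- experiments |>
    filter(.data$exp_id %in% parts$defined) |>
    pull(.data$replicate_group) |>
    n_distinct()

  calls <- grp |>
    group_by(.data$gene_id) |>
    summarise(
      n_defined = sum(.data$replicate_group %in% parts$defined_groups),
      n_replete = sum(.data$replicate_group %in% parts$replete_groups),
      median_defined = median(
        .data$fitness[.data$replicate_group %in% parts$defined_groups]),
      median_replete = median(
        .data$fitness[.data$replicate_group %in% parts$replete_groups]),
      frac_low = mean(
        .data$fitness[.data$replicate_group %in% parts$defined_groups] <=
          t_defect),
      .groups = "drop"
    ) |>
    mutate(
      class = dplyr::case_when(
        .data$gene_id %in% essential_ids ~ "essential",
        .data$n_defined <= n_defined_groups / 2 ~ "no_data",
        .data$frac_low >= frac_defined & !is.na(.data$median_replete) &
          .data$median_replete >= t_neutral ~ "auxotrophic",
        TRUE ~ "no_phenotype"
      )
    )
  # essential genes may lack fitness rows entirely
  missing_ess <- setdiff(essential_ids, calls$gene_id)
  if (length(missing_ess) > 0) {
    calls <- bind_rows(calls, tibble(
      gene_id = missing_ess, n_defined = 0L, n_replete = 0L,
      median_defined = NA_real_, median_replete = NA_real_,
      frac_low = NA_real_, class = "essential"
    ))
  }
  calls |>
    select("gene_id", "class", "median_defined", "median_replete",
           "n_defined", "n_replete") |>
    arrange(.data$gene_id)
}

partition_experiments <- function(experiments) {
  assert_columns(experiments,
                 c("exp_id", "media_class", "supplements", "replicate_group"),
                 "`experiments`")
  replete <- experiments$media_class == "rich" |
    has_supplement(experiments$supplements, "casamino_acids") |
    has_supplement(experiments$supplements, "yeast_extract")
  defined <- experiments$media_class == "defined" & !replete
  list(
    defined = experiments$exp_id[defined],
    replete = experiments$exp_id[replete],
    defined_groups = unique(experiments$replicate_group[defined]),
    replete_groups = unique(experiments$replicate_group[replete])
  )
}

replicate_means <- function(gene_fit, experiments) {
  gene_fit |>
    inner_join(select(experiments, "exp_id", "replicate_group"),
               by = "exp_id") |>
    group_by(.data$gene_id, .data$replicate_group) |>
    summarise(fitness = mean(.data$fitness), .groups = "drop")
}

#' Genome-wide amino-acid rescue scan
#'
#' Compares each gene's mean fitness in unsupplemented defined-minimal
#' media against defined media supplemented with `compound`, averaging
#' within replicate groups first. A gene is rescued when its minimal
#' fitness is strictly below `f_low` and its supplemented fitness is
#' strictly above `f_high`: the mutant fails without the compound and
#' recovers with it - the genetic signature of a biosynthesis gene for
#' that compound.
#'
#' @param gene_fit Normalized long fitness tibble.
#' @param experiments Experiments table; `compound` must occur in at
#'   least one experiment's supplements.
#' @param compound Supplement name (e.g., an amino acid code).
#' @param f_low Minimal-media threshold (strict `<`).
#' @param f_high Supplemented-media threshold (strict `>`).
#' @return Tibble `gene_id`, `compound`, `fitness_minimal`,
#'   `fitness_supplemented`, `rescued`, genes with both means defined,
#'   strongest rescue (largest fitness gain) first.
#' @export
rescue_scan <- function(gene_fit, experiments, compound,
                        f_low = -2, f_high = -1) {
  supplemented <- experiments$exp_id[
    experiments$media_class == "defined" &
      has_supplement(experiments$supplements, compound)
  ]
  if (length(supplemented) == 0) {
    abort(sprintf("No experiment is supplemented with '%s'.", compound))
  }
  minimal <- experiments$exp_id[
    experiments$media_class == "defined" &
      experiments$supplements == "" &
      experiments$carbon_source != compound &
      experiments$nitrogen_source != compound
  ]
  if (length(minimal) == 0) {
    abort("No unsupplemented defined-minimal experiments available.")
  }
  grp <- replicate_means(gene_fit, experiments)
  groups_of <- function(ids) unique(
    experiments$replicate_group[experiments$exp_id %in% ids]
  )
  means <- grp |>
    group_by(.data$gene_id) |>
    summarise(
      fitness_minimal = mean(
        .data$fitness[.data$replicate_group %in% groups_of(minimal)]),
      fitness_supplemented = mean(
        .data$fitness[.data$replicate_group %in% groups_of(supplemented)]),
      .groups = "drop"
    ) |>
    filter(!is.na(.data$fitness_minimal), !is.na(.data$fitness_supplemented))
  means |>
    mutate(
      compound = compound,
      rescued = .data$fitness_minimal < f_low &
        .data$fitness_supplemented > f_high
    ) |>
    arrange(desc(.data$fitness_supplemented - .data$fitness_minimal),
            .data$gene_id) |>
    select("gene_id", "compound", "fitness_minimal",
           "fitness_supplemented", "rescued")
}

#' Classify gaps from candidate, phenotype and rescue evidence
#'
#' Applies the classification decision tree to each gap record that was
#' not already flagged special (see [flag_special()]):
#'
#' * With at least one clear candidate: if two or more clear candidates
#'   exist and none is auxotrophic or essential, the gap is
#'   `clear_redundant` when at least two of them were measured and show
#'   no phenotype (the signature of genetic redundancy), otherwise
#'   `clear_multiple`. Otherwise the best candidate's phenotype decides:
#'   `clear_auxotrophic`, `clear_essential`, `clear_nodata`, or
#'   `clear_other`.
#' * With no clear candidate the gap is genuine: `genuine_filled` with
#'   `filled_by = g` when the rescue scan for the gap's amino acid
#'   proposes a rescued gene `g` not already annotated to another step
#'   of that pathway variant, else `genuine_unfilled`.
#'
#' @param gaps Gap records (after [flag_special()]).
#' @param candidates Candidate table from [clear_candidates()].
#' @param phenotypes Phenotype calls from [phenotype_call()].
#' @param rescues Row-bound [rescue_scan()] results over the relevant
#'   compounds.
#' @param annotations Annotation tibble (for the already-assigned
#'   exclusion).
#' @param pathways Pathway steps table.
#' @return `gaps` with `classification` and `filled_by` completed, plus
#'   `n_clear` and `best_candidate`.
#' @export
classify_gaps <- function(gaps, candidates, phenotypes, rescues,
                          annotations, pathways) {
  class_of <- function(gene) {
    i <- match(gene, phenotypes$gene_id)
    if_else(is.na(i), "no_data", phenotypes$class[i])
  }
  out <- gaps
  out$n_clear <- 0L
  out$best_candidate <- NA_character_
  for (i in seq_len(nrow(out))) {
    g <- out[i, ]
    cand <- candidates |>
      filter(.data$organism == g$organism,
             .data$amino_acid == g$amino_acid,
             .data$reaction_id == g$reaction_id)
    clear <- filter(cand, .data$clear)
    out$n_clear[i] <- nrow(clear)
    if (!is.na(g$classification)) next  # special classes preempt

    if (nrow(clear) >= 1) {
      cls <- class_of(clear$gene_id)
      # prefer phenotype-informative candidates at equal support
      pri <- match(cls, c("auxotrophic", "essential", "no_phenotype",
                          "no_data"))
      ord <- order(-clear$support, pri, clear$gene_id)
      best <- clear$gene_id[ord[1]]
      out$best_candidate[i] <- best
      if (nrow(clear) >= 2 && !any(cls %in% c("auxotrophic", "essential"))) {
        out$classification[i] <-
          if (sum(cls == "no_phenotype") >= 2) "clear_redundant"
          else "clear_multiple"
      } else {
        out$classification[i] <- switch(
          class_of(best),
          auxotrophic = "clear_auxotrophic",
          essential = "clear_essential",
          no_data = "clear_nodata",
          "clear_other"
        )
      }
    } else {
      assigned <- pathway_assigned_genes(g, annotations, pathways)
      props <- rescues |>
        filter(.data$compound == g$amino_acid, .data$rescued,
               !.data$gene_id %in% assigned)
      if (nrow(props) > 0) {
        out$classification[i] <- "genuine_filled"
        out$filled_by[i] <- props$gene_id[1]
      } else {
        out$classification[i] <- "genuine_unfilled"
      }
    }
  }
  out
}

# Genes annotated (by any resource) to another step of the gap's
# pathway variant; such genes cannot fill the gap - an upstream-pathway
# auxotroph rescued by the same amino acid is not a new enzyme.
pathway_assigned_genes <- function(gap, annotations, pathways) {
  other_steps <- pathways |>
    filter(.data$amino_acid == gap$amino_acid,
           .data$variant_id == gap$variant_id,
           .data$reaction_id != gap$reaction_id) |>
    pull(.data$reaction_id)
  annotations |>
    filter(.data$reaction_id %in% other_steps) |>
    pull(.data$gene_id) |>
    unique()
}
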