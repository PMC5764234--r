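#' Enumerate amino-acid biosynthesis gaps from a baseline annotation
#'
#' For each amino acid in the pathway database, selects the pathway
#' variant with the fewest missing steps under the baseline resource's
#' annotations (ties broken by lexicographically smallest variant id)
#' and reports the missing steps as gap records. An amino acid with no
#' gaps is a predicted prototroph. A reaction shared by several amino
#' acids yields one gap record per amino acid that needs it.
#'
#' @param annotations Annotation tibble (`gene_id`, `resource_id`,
#'   `reaction_id`).
#' @param pathways Pathway steps table (see [aa_pathways()]).
#' @param baseline_resource Resource id whose predictions are audited.
#' @param organism Organism label carried through the gap records.
#' @param amino_acids Amino acids to assess; defaults to those present
#'   in `pathways`. Requested amino acids absent from the database get
#'   status `"no_definition"` and no gaps.
#' @return `predict_status()`: tibble `organism`, `amino_acid`,
#'   `status` (`prototroph` / `auxotroph_predicted` / `no_definition`),
#'   `variant_id`, `n_gaps`. `find_gaps()`: tibble `organism`,
#'   `amino_acid`, `variant_id`, `reaction_id`, `classification` (NA
#'   until classified), `filled_by` (NA).
#' @export
predict_status <- function(annotations, pathways,
                           baseline_resource = "baseline",
                           organism = "organism", amino_acids = NULL) {
  assert_columns(annotations, c("gene_id", "resource_id", "reaction_id"),
                 "`annotations`")
  validate_pathways(pathways)
  amino_acids <- amino_acids %||% sort(unique(pathways$amino_acid))
  annotated <- annotations |>
    filter(.data$resource_id == baseline_resource) |>
    pull(.data$reaction_id) |>
    unique()
  purrr::map_dfr(amino_acids, function(aa) {
    variant <- select_variant(pathways, aa, annotated)
    if (is.null(variant)) {
      return(tibble(organism = organism, amino_acid = aa,
                    status = "no_definition", variant_id = NA_character_,
                    n_gaps = 0L))
    }
    steps <- pathways |>
      filter(.data$amino_acid == aa, .data$variant_id == variant)
    n_gaps <- sum(!steps$reaction_id %in% annotated)
    tibble(
      organism = organism, amino_acid = aa,
      status = if (n_gaps == 0) "prototroph" else "auxotroph_predicted",
      variant_id = variant, n_gaps = as.integer(n_gaps)
    )
  })
}

#' @rdname predict_status
#' @export
find_gaps <- function(annotations, pathways, baseline_resource = "baseline",
                      organism = "organism", amino_acids = NULL) {
  status <- predict_status(annotations, pathways, baseline_resource,
                           organism, amino_acids)
  annotated <- annotations |>
    filter(.data$resource_id == baseline_resource) |>
    pull(.data$reaction_id) |>
    unique()
  status |>
    filter(.data$status == "auxotroph_predicted") |>
    purrr::pmap_dfr(function(organism, amino_acid, status, variant_id, n_gaps) {
      pathways |>
        filter(.data$amino_acid == !!amino_acid,
               .data$variant_id == !!variant_id,
               !.data$reaction_id %in% annotated) |>
        arrange(.data$step_index) |>
        mutate(organism = !!organism) |>
        select("organism", "amino_acid", "variant_id", "reaction_id")
    }) |>
    mutate(classification = NA_character_, filled_by = NA_character_)
}

#' Candidate genes for gaps by multi-resource consensus
#'
#' For each gap, every gene annotated with the gap's reaction by at
#' least one non-baseline resource is a candidate; its support is the
#' number of distinct non-baseline resources agreeing. A gene supported
#' by at least two resources is a clear candidate. At least three
#' non-baseline resources must be present in the annotation table for
#' the consensus to be meaningful.
#'
#' @param gaps Gap records from [find_gaps()].
#' @param annotations Annotation tibble.
#' @param baseline_resource Baseline resource id (excluded from
#'   support).
#' @param min_support Support needed for a clear candidate.
#' @return Tibble `organism`, `amino_acid`, `reaction_id`, `gene_id`,
#'   `support`, `clear`, sorted by descending support then gene id
#'   within each gap.
#' @export
clear_candidates <- function(gaps, annotations, baseline_resource = "baseline",
                             min_support = 2) {
  resources <- setdiff(unique(annotations$resource_id), baseline_resource)
  if (length(resources) < 3) {
    abort("At least 3 non-baseline annotation resources are required.")
  }
  gaps |>
    distinct(.data$organism, .data$amino_acid, .data$reaction_id) |>
    inner_join(
      annotations |> filter(.data$resource_id != baseline_resource),
      by = "reaction_id", relationship = "many-to-many"
    ) |>
    group_by(.data$organism, .data$amino_acid, .data$reaction_id,
             .data$gene_id) |>
    summarise(support = n_distinct(.data$resource_id), .groups = "drop") |>
    mutate(clear = .data$support >= min_support) |>
    arrange(.data$organism, .data$amino_acid, .data$reaction_id,
            desc(.data$support), .data$gene_id)
}

#' Flag special gap classes that preempt candidate-based classification
#'
#' Applies, in order of precedence: curated gene-model errors (the gap
#' is an artifact of the genome sequence or gene calling), transaminase
#' reactions (transaminases are promiscuous, so their apparent absence
#' should not be used to predict auxotrophy), and curated known gaps
#' (steps already filled in the literature but missing from the
#' databases). Other gaps pass through unclassified.
#'
#' @param gaps Gap records.
#' @param reactions Reaction registry with `is_transaminase`.
#' @param curated_known Optional tibble (`organism`, `reaction_id`) of
#'   literature-filled gaps.
#' @param curated_gene_model_errors Optional tibble (`organism`,
#'   `reaction_id`) of curated gene-model errors.
#' @return `gaps` with `classification` set where a special class
#'   applies.
#' @export
flag_special <- function(gaps, reactions, curated_known = NULL,
                         curated_gene_model_errors = NULL) {
  in_list <- function(g, lst) {
    if (is.null(lst) || nrow(lst) == 0) return(rep(FALSE, nrow(g)))
    paste(g$organism, g$reaction_id) %in%
      paste(lst$organism, lst$reaction_id)
  }
  trans <- reactions$reaction_id[reactions$is_transaminase]
  gaps |>
    mutate(
      classification = dplyr::case_when(
        in_list(gaps, curated_gene_model_errors) ~ "gene_model_error",
        .data$reaction_id %in% trans ~ "transaminase",
        in_list(gaps, curated_known) ~ "known",
        TRUE ~ .data$classification
      )
    )
}

#' Read and write gap-record tables
#'
#' Plain-TSV round-trip for gap records (empty strings encode missing
#' classifications and fillers).
#'
#' @param gaps Gap records tibble.
#' @param path File path.
#' @return `read_gaps()` returns the gap tibble; `write_gaps()` its
#'   input, invisibly.
#' @export
write_gaps <- function(gaps, path) {
  readr::write_tsv(gaps, path, na = "")
  invisible(gaps)
}

#' @rdname write_gaps
#' @export
read_gaps <- function(path) {
  readr::read_tsv(
    path, na = "",
    col_types = readr::cols(
      organism = readr::col_character(),
      amino_acid = readr::col_character(),
      variant_id = readr::col_character(),
      reaction_id = readr::col_character(),
      classification = readr::col_character(),
      filled_by = readr::col_character()
    )
  )
}
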