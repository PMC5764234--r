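#' Packaged amino-acid pathway definitions
#'
#' Curated biosynthesis pathway tables for the four amino acids most often
#' behind annotation gaps in heterotrophic Proteobacteria: histidine,
#' methionine (with both the succinylated-homoserine route and the
#' DUF39/NIL-ferredoxin/COG2122 route found in sulfate reducers), serine,
#' and threonine. Each pathway is a set of variants; a variant is an
#' ordered list of reactions, and a reaction missing from the annotation
#' of every gene is a gap. A complete 20-amino-acid database is
#' user-supplied in the same format.
#'
#' @return `aa_pathways()`: a tibble with columns `amino_acid`,
#'   `variant_id`, `step_index`, `reaction_id`. `aa_reactions()`: a tibble
#'   with columns `reaction_id`, `name`, `is_transaminase`.
#' @export
aa_pathways <- function() {
  path <- system.file("extdata", "pathways_aa4.tsv", package = "auxofill")
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      amino_acid = readr::col_character(),
      variant_id = readr::col_character(),
      step_index = readr::col_integer(),
      reaction_id = readr::col_character()
    )
  )
  validate_pathways(out)
  out
}

#' @rdname aa_pathways
#' @export
aa_reactions <- function() {
  path <- system.file("extdata", "reactions_aa4.tsv", package = "auxofill")
  readr::read_tsv(
    path,
    col_types = readr::cols(
      reaction_id = readr::col_character(),
      name = readr::col_character(),
      is_transaminase = readr::col_logical()
    )
  )
}

validate_pathways <- function(pathways, reactions = NULL) {
  assert_columns(
    pathways,
    c("amino_acid", "variant_id", "step_index", "reaction_id"),
    "`pathways`"
  )
  empty <- pathways |>
    group_by(.data$amino_acid, .data$variant_id) |>
    summarise(n = n(), .groups = "drop") |>
    filter(.data$n < 1)
  if (nrow(empty) > 0) {
    abort("Every (amino_acid, variant_id) must have at least one step.")
  }
  if (!is.null(reactions)) {
    unknown <- setdiff(pathways$reaction_id, reactions$reaction_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "Pathway steps reference reactions absent from the registry: %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  invisible(pathways)
}

# Steps of the variant of `amino_acid` selected by the fewest-missing rule
# given a set of annotated reactions; ties broken by variant_id.
select_variant <- function(pathways, amino_acid, annotated_reactions) {
  variants <- pathways |>
    filter(.data$amino_acid == !!amino_acid) |>
    group_by(.data$variant_id) |>
    summarise(
      n_missing = sum(!.data$reaction_id %in% annotated_reactions),
      .groups = "drop"
    ) |>
    arrange(.data$n_missing, .data$variant_id)
  if (nrow(variants) == 0) return(NULL)
  variants$variant_id[1]
}
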