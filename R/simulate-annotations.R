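#' Simulate multi-resource enzyme annotation tables
#'
#' Emulates a baseline annotation source (the one whose pathway
#' predictions are audited) plus `n_resources` independent resources
#' (e.g., HMM families, KEGG best hits, SEED roles). Every
#' pathway-role gene in the truth table is annotated with its reaction by
#' every resource, except where `drop_spec` removes a (reaction,
#' resource) pair - dropping a reaction from the baseline plants a gap,
#' dropping it from other resources degrades the candidate consensus.
#' Neutral genes receive no pathway annotations unless `spurious_rate >
#' 0`, in which case each neutral gene has that probability per resource
#' of picking up one random reaction annotation.
#'
#' @param truth Truth tibble from [plant_truth()].
#' @param pathways,reactions Pathway and reaction registry tables.
#' @param n_resources Number of non-baseline resources (>= 3).
#' @param drop_spec Tibble with columns `reaction_id`, `resource_id`
#'   (resource `"baseline"` or `"res1"`..`"resN"`), or `NULL`.
#' @param spurious_rate Per-gene, per-resource probability of a random
#'   false annotation on a neutral gene.
#' @param seed Integer seed (used when `spurious_rate > 0`).
#' @return Annotation tibble: `gene_id`, `resource_id`, `reaction_id`.
#'   The baseline resource is named `"baseline"`.
#' @export
simulate_annotations <- function(truth, pathways, reactions,
                                 n_resources = 3, drop_spec = NULL,
                                 spurious_rate = 0, seed = 1L) {
  if (n_resources < 3) abort("`n_resources` must be at least 3.")
  if (!is.null(drop_spec)) {
    assert_columns(drop_spec, c("reaction_id", "resource_id"), "`drop_spec`")
    unknown <- setdiff(drop_spec$reaction_id, reactions$reaction_id)
    if (length(unknown) > 0) {
      abort(sprintf("`drop_spec` names unknown reaction(s): %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  resources <- c("baseline", sprintf("res%d", seq_len(n_resources)))
  roles <- truth |>
    filter(!is.na(.data$role)) |>
    select(gene_id = "gene_id", reaction_id = "role")
  ann <- tidyr::expand_grid(resource_id = resources, roles)
  if (!is.null(drop_spec) && nrow(drop_spec) > 0) {
    ann <- anti_join(ann, drop_spec, by = c("resource_id", "reaction_id"))
  }
  if (spurious_rate > 0) {
    neutral <- filter(truth, is.na(.data$role), !.data$essential)$gene_id
    ann <- withr::with_seed(seed, {
      extra <- tidyr::expand_grid(resource_id = resources,
                                  gene_id = neutral) |>
        filter(runif(n()) < spurious_rate) |>
        mutate(reaction_id = sample(reactions$reaction_id, n(),
                                    replace = TRUE))
      bind_rows(ann, extra)
    })
  }
  ann |>
    select("gene_id", "resource_id", "reaction_id") |>
    arrange(.data$gene_id, .data$resource_id, .data$reaction_id)
}
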