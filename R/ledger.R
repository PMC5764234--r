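# Gap classification vocabulary: classification id, ledger group and
# subgroup, and the single-letter code used in classification grids.
CLASSIFICATION_MAP <- tibble::tribble(
  ~classification,     ~group,            ~subgroup,             ~code,
  "clear_multiple",    "Clear candidate", "multiple candidates", "c",
  "clear_auxotrophic", "Clear candidate", "auxotrophic",         "c",
  "clear_essential",   "Clear candidate", "essential",           "c",
  "clear_nodata",      "Clear candidate", "no fitness data",     "c",
  "clear_redundant",   "Clear candidate", "other (redundant)",   "c",
  "clear_other",       "Clear candidate", "other",               "c",
  "gene_model_error",  "Gene model error", "",                   "g",
  "transaminase",      "Transaminase",     "",                   "t",
  "known",             "Known gap",        "",                   "k",
  "genuine_filled",    "Genuine gap",     "filled (this study)", "f",
  "genuine_unfilled",  "Genuine gap",     "unfilled",            "u"
)

#' Summarize classified gaps into a ledger and classification grid
#'
#' Produces (a) a ledger of cases per classification group and subgroup
#' (the counts always sum to the number of gap records) and (b) a grid
#' with one row per organism x amino acid, whose cell concatenates one
#' single-letter code per gap, with repeated codes collapsed to
#' `<code><count>` (e.g., `"c2"` for two clear-candidate gaps).
#'
#' @param gaps Gap records; every record must carry a classification.
#' @return An object of class `gap_ledger`: list with `summary` (tibble
#'   `group`, `subgroup`, `cases`), `grid` (tibble `organism`,
#'   `amino_acid`, `codes`), and `n_gaps`.
#' @export
summarize_ledger <- function(gaps) {
  if (nrow(gaps) > 0) {
    bad <- filter(gaps, is.na(.data$classification) |
                    !.data$classification %in% CLASSIFICATION_MAP$classification)
    if (nrow(bad) > 0) {
      abort(sprintf(
        "Unclassified or unknown gap record(s): %s",
        paste(sprintf("%s/%s/%s", bad$organism, bad$amino_acid,
                      bad$reaction_id), collapse = "; ")
      ))
    }
  }
  summary <- gaps |>
    count(.data$classification, name = "cases") |>
    left_join(CLASSIFICATION_MAP, by = "classification") |>
    mutate(order = match(.data$classification,
                         CLASSIFICATION_MAP$classification)) |>
    arrange(.data$order) |>
    select("group", "subgroup", "cases")
  grid <- gaps |>
    mutate(code = CLASSIFICATION_MAP$code[
      match(.data$classification, CLASSIFICATION_MAP$classification)]) |>
    group_by(.data$organism, .data$amino_acid) |>
    summarise(codes = collapse_codes(.data$code), .groups = "drop")
  structure(
    list(summary = summary, grid = grid, n_gaps = nrow(gaps)),
    class = "gap_ledger"
  )
}

collapse_codes <- function(codes) {
  tab <- table(factor(codes, levels = unique(CLASSIFICATION_MAP$code)))
  tab <- tab[tab > 0]
  paste(ifelse(tab > 1, paste0(names(tab), tab), names(tab)), collapse = "")
}

#' @export
print.gap_ledger <- function(x, ...) {
  cat(sprintf("<gap_ledger> %d gap(s)\n", x$n_gaps))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
autoplot.gap_ledger <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$amino_acid, y = .data$organism)) +
    ggplot2::geom_tile(fill = "grey92", colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$codes), size = 3) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Gap classification by organism and amino acid")
}

#' Packaged gap ledger of 10 heterotrophic bacteria
#'
#' A transcription of the published classification of 173 amino-acid
#' biosynthesis gaps found by an automated annotation pipeline across 10
#' prototrophic bacteria, as group/subgroup case counts. Used by the
#' ledger-integrity checks: expanding it to per-gap records and
#' re-summarizing must reproduce the printed totals exactly.
#'
#' @return Tibble `group`, `subgroup`, `cases`.
#' @export
reference_gap_ledger <- function() {
  path <- system.file("extdata", "gap_ledger_10bacteria.tsv",
                      package = "auxofill")
  readr::read_tsv(
    path, na = character(),
    col_types = readr::cols(
      group = readr::col_character(),
      subgroup = readr::col_character(),
      cases = readr::col_integer()
    )
  )
}

#' Expand a ledger summary into individual gap records
#'
#' Inverse of the summary side of [summarize_ledger()]: emits `cases`
#' gap records per ledger row, with synthetic organism/amino-acid/
#' reaction labels. Round-tripping a ledger through this function and
#' [summarize_ledger()] is lossless in the group/subgroup counts.
#'
#' @param summary Tibble `group`, `subgroup`, `cases`.
#' @param organism Organism label for the synthetic records.
#' @return Gap-record tibble compatible with [summarize_ledger()].
#' @export
expand_ledger <- function(summary, organism = "org1") {
  assert_columns(summary, c("group", "subgroup", "cases"), "`summary`")
  key_map <- paste(CLASSIFICATION_MAP$group, CLASSIFICATION_MAP$subgroup)
  key_in <- paste(summary$group, summary$subgroup)
  unknown <- setdiff(key_in, key_map)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown ledger group/subgroup: %s",
                  paste(unknown, collapse = "; ")))
  }
  cls <- CLASSIFICATION_MAP$classification[match(key_in, key_map)]
  records <- tibble(
    classification = rep(cls, summary$cases)
  )
  n <- nrow(records)
  records |>
    mutate(
      organism = organism,
      amino_acid = AMINO_ACIDS[(dplyr::row_number() - 1L) %% 20L + 1L],
      variant_id = "v1",
      reaction_id = sprintf("reaction_%03d", dplyr::row_number()),
      filled_by = NA_character_
    ) |>
    select("organism", "amino_acid", "variant_id", "reaction_id",
           "classification", "filled_by")
}
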