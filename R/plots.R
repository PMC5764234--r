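# Figure-style views of fitness evidence.

#' Strip plot of one gene's fitness across the compendium
#'
#' Shows each experiment's fitness for a gene, separated by whether
#' most amino acids were available (rich media / replete supplement),
#' only the gene's own amino acid was provided, or neither. The
#' signature of an auxotrophy gene is a cloud of strong defects in the
#' unsupplemented defined media and near-zero fitness everywhere amino
#' acids are supplied.
#'
#' @param gene_fit Normalized long fitness tibble.
#' @param experiments Experiments table.
#' @param gene Gene id.
#' @param amino_acid Optional amino acid whose specific availability is
#'   shown as its own category.
#' @param clip Fitness values below `clip` are drawn at `clip`.
#' @return A ggplot object.
#' @export
plot_gene_fitness <- function(gene_fit, experiments, gene,
                              amino_acid = NULL, clip = -7) {
  parts <- partition_experiments(experiments)
  dat <- gene_fit |>
    filter(.data$gene_id == gene) |>
    inner_join(experiments, by = "exp_id") |>
    mutate(
      category = dplyr::case_when(
        .data$exp_id %in% parts$replete ~ "most amino acids",
        !is.null(amino_acid) &
          amino_acid_available(dplyr::pick(dplyr::everything()),
                               amino_acid %||% "") ~ "this amino acid only",
        TRUE ~ "no amino acids"
      ),
      fitness = pmax(.data$fitness, clip)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fitness, y = .data$category)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(title = gene, x = "gene fitness (log2)", y = NULL)
}

#' Minimal-versus-supplemented fitness scatter
#'
#' Replicate-averaged gene fitness in unsupplemented defined media (x)
#' against defined media with `compound` added (y). Genes far below the
#' diagonal on the x axis but near zero on the y axis are rescued by
#' the compound - biosynthesis candidates.
#'
#' @param gene_fit Normalized long fitness tibble.
#' @param experiments Experiments table.
#' @param compound Supplement name.
#' @param highlight Optional gene ids to label.
#' @return A ggplot object.
#' @export
plot_rescue <- function(gene_fit, experiments, compound, highlight = NULL) {
  scan <- rescue_scan(gene_fit, experiments, compound,
                      f_low = Inf, f_high = -Inf)
  p <- ggplot2::ggplot(
    scan,
    ggplot2::aes(x = .data$fitness_minimal, y = .data$fitness_supplemented)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::labs(
      x = "fitness in minimal media (log2)",
      y = sprintf("fitness in minimal media + %s (log2)", compound)
    )
  if (!is.null(highlight)) {
    hl <- filter(scan, .data$gene_id %in% highlight)
    p <- p +
      ggplot2::geom_point(data = hl, colour = "firebrick") +
      ggplot2::geom_text(
        data = hl, ggplot2::aes(label = .data$gene_id),
        vjust = -0.8, size = 3, colour = "firebrick"
      )
  }
  p
}
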