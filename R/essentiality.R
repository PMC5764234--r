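#' Per-gene insertion statistics for essentiality calling
#'
#' For each gene: its length, GC content (from the genomic sequence),
#' the number of distinct insertion locations in the central 10-90% of
#' the gene, the mapping reads summed over those central insertions, the
#' central insertion-site density `n_central_sites / (0.8 * length)`,
#' and reads per nucleotide. A location is a distinct (scaffold,
#' position, strand) triple - transposon junctions are strand-specific -
#' so two barcodes at one location count once, with their reads summed.
#'
#' @param pool Insertion pool table.
#' @param genes Gene table.
#' @param genome Named character vector of scaffold sequences.
#' @return Tibble `gene_id`, `length`, `gc`, `n_central_sites`,
#'   `central_reads`, `density`, `reads_per_nt`.
#' @export
gene_insertion_stats <- function(pool, genes, genome) {
  bad <- genes |>
    mutate(sc_len = nchar(genome[.data$scaffold_id])) |>
    filter(is.na(.data$sc_len) | .data$end > .data$sc_len | .data$begin < 1)
  if (nrow(bad) > 0) {
    abort(sprintf("Gene(s) outside their scaffold: %s",
                  paste(bad$gene_id, collapse = ", ")))
  }
  pool2 <- if ("central" %in% names(pool)) pool else assign_genes(pool, genes)
  central <- pool2 |>
    filter(.data$central) |>
    group_by(.data$gene_id) |>
    summarise(
      n_central_sites = n_distinct(.data$scaffold_id, .data$pos, .data$strand),
      central_reads = sum(.data$n_reads),
      .groups = "drop"
    )
  genes |>
    mutate(
      length = .data$end - .data$begin + 1L,
      gc = gc_fraction(substr(genome[.data$scaffold_id],
                              .data$begin, .data$end))
    ) |>
    select("gene_id", "length", "gc") |>
    left_join(central, by = "gene_id") |>
    mutate(
      n_central_sites = dplyr::coalesce(.data$n_central_sites, 0L),
      central_reads = dplyr::coalesce(.data$central_reads, 0L),
      density = .data$n_central_sites / (0.8 * .data$length),
      reads_per_nt = .data$central_reads / .data$length
    )
}

#' Fit the expected insertion density as a function of GC content
#'
#' Transposon insertion density varies with local GC; essentiality
#' calls therefore compare each gene to the density expected at its GC
#' rather than to a flat genome average. The model is an ordinary
#' least-squares line of central insertion density on gene GC over genes
#' of at least `min_length` nt, with predictions floored at
#' `floor_frac` of the median density so normalization never divides by
#' a vanishing expectation. Degenerate GC spread (range < 0.01) falls
#' back to a constant model at the median density.
#'
#' @param stats Tibble from [gene_insertion_stats()].
#' @param min_length Genes shorter than this are excluded from the fit.
#' @param floor_frac Prediction floor as a fraction of median density.
#' @return An object of class `gc_density_fit` with [predict()],
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_gc_density_model <- function(stats, min_length = 400, floor_frac = 0.1) {
  dat <- filter(stats, .data$length >= min_length)
  if (nrow(dat) < 50) {
    abort("Need at least 50 genes of qualifying length to fit the GC model.")
  }
  med <- median(dat$density)
  if (diff(range(dat$gc)) < 0.01) {
    fit <- NULL
    type <- "constant"
  } else {
    fit <- lm(density ~ gc, data = dat)
    type <- "linear"
  }
  structure(
    list(model = fit, type = type, median_density = med,
         floor = floor_frac * med, min_length = min_length,
         n = nrow(dat), data = dat),
    class = "gc_density_fit"
  )
}

#' @export
predict.gc_density_fit <- function(object, gc, ...) {
  pred <- if (object$type == "constant") {
    rep(object$median_density, length(gc))
  } else {
    unname(coef(object$model)[1] + coef(object$model)[2] * gc)
  }
  pmax(pred, object$floor)
}

#' @export
print.gc_density_fit <- function(x, ...) {
  cat(sprintf("<gc_density_fit> %s model over %d genes (length >= %d nt)\n",
              x$type, x$n, x$min_length))
  if (x$type == "linear") {
    cat(sprintf("  density = %.4g + %.4g * GC (floor %.4g)\n",
                coef(x$model)[1], coef(x$model)[2], x$floor))
  } else {
    cat(sprintf("  constant density %.4g (floor %.4g)\n",
                x$median_density, x$floor))
  }
  invisible(x)
}

#' @export
tidy.gc_density_fit <- function(x, ...) {
  if (x$type == "constant") {
    return(tibble(term = "(Intercept)", estimate = x$median_density,
                  std.error = NA_real_, statistic = NA_real_,
                  p.value = NA_real_))
  }
  s <- summary(x$model)$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.gc_density_fit <- function(x, ...) {
  tibble(
    type = x$type,
    r.squared = if (x$type == "linear") summary(x$model)$r.squared else NA_real_,
    median_density = x$median_density,
    floor = x$floor,
    n = x$n
  )
}

#' @export
autoplot.gc_density_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$gc, y = .data$density)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "gene GC fraction",
                  y = "central insertion-site density (sites/nt)")
  grid <- tibble(gc = seq(min(object$data$gc), max(object$data$gc),
                          length.out = 50))
  grid$density <- predict(object, grid$gc)
  p + ggplot2::geom_line(data = grid, colour = "firebrick")
}

#' Call putatively essential genes from insertion statistics
#'
#' A gene is called essential when it is long enough to judge (length
#' at least `min_length` nt) and both its GC-normalized central
#' insertion density and its central reads per nucleotide fall below
#' `frac_cutoff` (default 20%) of the typical - median - gene's value,
#' medians taken over genes of qualifying length. When `min_length` is
#' `NULL` it is derived from the pool itself: the smallest length whose
#' expected central insertion count `0.8 * L * density` reaches 4, so
#' that a complete absence of insertions is genuinely surprising.
#'
#' @param stats Tibble from [gene_insertion_stats()].
#' @param model Optional [fit_gc_density_model()] fit; fitted internally
#'   when `NULL`.
#' @param min_length Length floor in nt, or `NULL` for automatic.
#' @param frac_cutoff Fraction of the typical value below which both
#'   statistics must fall.
#' @return `stats` with `expected_density`, `norm_density` and `called`
#'   added; inspect `attr(, "min_length")` for the floor used.
#' @export
call_essential <- function(stats, model = NULL, min_length = NULL,
                           frac_cutoff = 0.2) {
  if (is.null(min_length)) {
    d_hat <- sum(stats$n_central_sites) / sum(0.8 * stats$length)
    min_length <- if (d_hat > 0) ceiling(4 / (0.8 * d_hat)) else Inf
  }
  if (is.null(model)) {
    model <- fit_gc_density_model(stats, min_length = min(min_length, 400))
  }
  out <- stats |>
    mutate(
      expected_density = predict(model, .data$gc),
      norm_density = .data$density / .data$expected_density
    )
  qual <- out$length >= min_length
  med_nd <- median(out$norm_density[qual])
  med_rpn <- median(out$reads_per_nt[qual])
  out <- out |>
    mutate(called = qual &
             .data$norm_density < frac_cutoff * med_nd &
             .data$reads_per_nt < frac_cutoff * med_rpn)
  attr(out, "min_length") <- min_length
  out
}
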