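#' Simulate a randomly barcoded transposon insertion pool
#'
#' Draws insertion locations across the genome with probability
#' proportional to `1 + gc_bias_slope * (localGC - 0.5)` (truncated at a
#' small positive floor), excludes the central 10-90% of essential genes
#' (terminal insertions in essential genes are tolerated and allowed),
#' and gives each strain a unique random 20-nt barcode and a mapping-read
#' support of at least 2.
#'
#' @param genome Named character vector of scaffold sequences.
#' @param genes Gene table (see [simulate_genome()]).
#' @param truth Truth table from [plant_truth()]; only the `essential`
#'   column is used here.
#' @param target_strains Number of insertion strains to draw.
#' @param gc_bias_slope Relative change in insertion density per unit of
#'   local GC (0 = unbiased).
#' @param gc_window Window (nt) for local GC around each position.
#' @param weight_floor Lower truncation of the relative insertion weight.
#' @param mean_extra_reads Mapping reads per strain are
#'   `2 + Poisson(mean_extra_reads)`.
#' @param seed Integer seed.
#' @return Pool tibble: `barcode`, `scaffold_id`, `pos` (1-based),
#'   `strand`, `n_reads`.
#' @export
simulate_pool <- function(genome, genes, truth, target_strains,
                          gc_bias_slope = 0, gc_window = 100,
                          weight_floor = 0.05, mean_extra_reads = 8,
                          seed = 1L) {
  stop_if_not_scalar_count(target_strains, "target_strains")
  withr::with_seed(seed, {
    weights <- lapply(names(genome), function(sc) {
      gc <- local_gc(genome[[sc]], gc_window)
      w <- pmax(1 + gc_bias_slope * (gc - 0.5), weight_floor)
      ess <- genes |>
        inner_join(filter(truth, .data$essential), by = "gene_id") |>
        filter(.data$scaffold_id == sc)
      for (i in seq_len(nrow(ess))) {
        win <- central_window(ess$begin[i], ess$end[i])
        if (win[1] <= win[2]) w[seq(win[1], win[2])] <- 0
      }
      w
    })
    names(weights) <- names(genome)

    lens <- vapply(weights, length, integer(1))
    all_w <- unlist(weights, use.names = FALSE)
    idx <- sample.int(length(all_w), target_strains, replace = TRUE,
                      prob = all_w)
    offsets <- cumsum(c(0L, lens[-length(lens)]))
    sc_i <- findInterval(idx, offsets + 1L)
    tibble(
      barcode = random_barcodes(target_strains),
      scaffold_id = names(genome)[sc_i],
      pos = idx - offsets[sc_i],
      strand = sample(c("+", "-"), target_strains, replace = TRUE),
      n_reads = 2L + rpois(target_strains, mean_extra_reads)
    )
  })
}

# Positions whose central fraction (pos - begin + 0.5) / len lies in
# [0.1, 0.9], as an inclusive [from, to] range.
central_window <- function(begin, end) {
  len <- end - begin + 1L
  from <- ceiling(begin + 0.1 * len - 0.5)
  to <- floor(begin + 0.9 * len - 0.5)
  c(from, to)
}

# Running-mean GC over a centered window, clamped at scaffold edges.
local_gc <- function(seq, window = 100) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  isgc <- as.integer(chars %in% c("G", "C"))
  n <- length(isgc)
  half <- window %/% 2
  cs <- cumsum(c(0L, isgc))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Assign pool insertions to genes
#'
#' Adds the containing gene (if any), the within-gene central fraction
#' `fc = (pos - begin + 0.5) / length`, and whether the insertion is
#' central (`0.1 <= fc <= 0.9`). Insertions in intergenic sequence keep
#' `gene_id = NA`.
#'
#' @param pool Pool tibble (`barcode`, `scaffold_id`, `pos`, `strand`,
#'   `n_reads`).
#' @param genes Gene table with non-overlapping genes.
#' @return The pool with `gene_id`, `central_frac` and `central` added.
#' @export
assign_genes <- function(pool, genes) {
  assert_columns(pool, c("barcode", "scaffold_id", "pos"), "`pool`")
  assert_columns(genes, c("gene_id", "scaffold_id", "begin", "end"), "`genes`")
  if (nrow(pool) == 0) {
    return(mutate(pool, gene_id = character(0), central_frac = numeric(0),
                  central = logical(0)))
  }
  out <- vector("list", length(unique(pool$scaffold_id)))
  for (k in seq_along(out)) {
    sc <- unique(pool$scaffold_id)[k]
    p <- filter(pool, .data$scaffold_id == sc)
    g <- genes |> filter(.data$scaffold_id == sc) |> arrange(.data$begin)
    i <- findInterval(p$pos, g$begin)
    hit <- i >= 1 & p$pos <= g$end[pmax(i, 1)]
    p$gene_id <- if_else(hit, g$gene_id[pmax(i, 1)], NA_character_)
    len <- g$end[pmax(i, 1)] - g$begin[pmax(i, 1)] + 1
    fc <- (p$pos - g$begin[pmax(i, 1)] + 0.5) / len
    p$central_frac <- if_else(hit, fc, NA_real_)
    out[[k]] <- p
  }
  bind_rows(out) |>
    mutate(central = !is.na(.data$central_frac) &
             .data$central_frac >= 0.1 & .data$central_frac <= 0.9)
}
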