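# Readers and writers for the plain-text interchange formats. All
# tables are tab-separated, UTF-8, unquoted; coordinates are 1-based
# inclusive; missing fitness values are empty strings.

#' Write a synthetic world to a directory of interchange files
#'
#' Emits the genome as FASTA, gene models as both a flat TSV and GFF3
#' (when the rtracklayer package is available), and the pool, count,
#' experiment, truth, pathway, reaction and annotation tables as TSV.
#' Output is byte-identical across runs for the same world.
#'
#' @param world An `auxo_world` from [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genome(world$genome, p("genome.fna"))
  write_gene_models(world$genes, p("genes.tsv"),
                    gff3_path = if (requireNamespace("rtracklayer",
                                                    quietly = TRUE))
                      p("genes.gff3") else NULL)
  readr::write_tsv(world$pool, p("pool.tsv"))
  readr::write_tsv(world$counts, p("counts.tsv"))
  readr::write_tsv(world$experiments, p("experiments.tsv"))
  readr::write_tsv(world$truth, p("truth.tsv"), na = "")
  readr::write_tsv(world$pathways, p("pathways.tsv"))
  readr::write_tsv(world$reactions, p("reactions.tsv"))
  readr::write_tsv(world$annotations, p("annotations.tsv"))
  invisible(dir)
}

#' Genome FASTA I/O
#'
#' @param genome Named character vector of scaffold sequences.
#' @param path File path.
#' @return `read_genome()` returns a named character vector.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Gene-model I/O (flat TSV and GFF3)
#'
#' @param genes Gene table (`gene_id`, `scaffold_id`, `begin`, `end`,
#'   `strand`, ...).
#' @param path TSV path.
#' @param gff3_path Optional GFF3 path (requires rtracklayer).
#' @return `read_gene_models()` returns the gene tibble.
#' @export
write_gene_models <- function(genes, path, gff3_path = NULL) {
  readr::write_tsv(genes, path)
  if (!is.null(gff3_path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE) ||
        !requireNamespace("GenomicRanges", quietly = TRUE)) {
      abort("GFF3 export requires the rtracklayer and GenomicRanges packages.")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = genes$scaffold_id,
      ranges = IRanges::IRanges(start = genes$begin, end = genes$end),
      strand = genes$strand
    )
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    rtracklayer::export(gr, gff3_path, format = "GFF3")
  }
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      scaffold_id = readr::col_character(),
      begin = readr::col_integer(),
      end = readr::col_integer(),
      strand = readr::col_character(),
      .default = readr::col_guess()
    )
  )
}

#' Pool, count, experiment and annotation table I/O
#'
#' @param path File path.
#' @return A tibble in the corresponding interchange dialect.
#' @export
read_pool <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      barcode = readr::col_character(),
      scaffold_id = readr::col_character(),
      pos = readr::col_integer(),
      strand = readr::col_character(),
      n_reads = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
}

#' @rdname read_pool
#' @export
read_counts <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      barcode = readr::col_character(),
      .default = readr::col_integer()
    )
  )
}

#' @rdname read_pool
#' @export
read_experiments <- function(path) {
  readr::read_tsv(
    path, na = character(),
    col_types = readr::cols(
      exp_id = readr::col_character(),
      media_class = readr::col_character(),
      supplements = readr::col_character(),
      carbon_source = readr::col_character(),
      nitrogen_source = readr::col_character(),
      replicate_group = readr::col_character(),
      time0_id = readr::col_character(),
      generations = readr::col_double()
    )
  )
}

#' @rdname read_pool
#' @export
read_annotations <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      resource_id = readr::col_character(),
      reaction_id = readr::col_character()
    )
  )
}

#' Fitness matrix I/O (genes x experiments, empty string = missing)
#'
#' @param gene_fit Long fitness tibble.
#' @param path File path.
#' @return `read_fitness()` returns the long fitness tibble.
#' @export
write_fitness <- function(gene_fit, path) {
  readr::write_tsv(fitness_matrix(gene_fit), path, na = "")
  invisible(path)
}

#' @rdname write_fitness
#' @export
read_fitness <- function(path) {
  readr::read_tsv(
    path, na = "",
    col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_double()
    )
  ) |>
    tidyr::pivot_longer(-"gene_id", names_to = "exp_id",
                        values_to = "fitness") |>
    filter(!is.na(.data$fitness))
}
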