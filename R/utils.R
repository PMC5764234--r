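# Internal helpers shared across modules.

NUCLEOTIDES <- c("A", "C", "G", "T")

# The twenty standard amino acids, three-letter lower-case codes.
AMINO_ACIDS <- c(
  "ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his", "ile",
  "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp", "tyr", "val"
)

# Amino-acid-replete supplements: mixtures that supply (nearly) all amino
# acids. Casamino acids lacks tryptophan; see `amino_acid_available()`.
REPLETE_SUPPLEMENTS <- c("casamino_acids", "yeast_extract")

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Split a supplements field like "his:1;casamino_acids:5" into compound names.
supplement_names <- function(supplements) {
  lapply(strsplit(supplements %||% "", ";", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts)]
    sub(":.*$", "", parts)
  })
}

has_supplement <- function(supplements, compound) {
  vapply(supplement_names(supplements), function(x) compound %in% x, logical(1))
}

#' Is an amino acid available to the cells in an experiment?
#'
#' An amino acid counts as available when the medium is rich, when the
#' compound itself is supplemented or serves as the carbon or nitrogen
#' source, or when an amino-acid-replete supplement (casamino acids or
#' yeast extract) is present. Casamino acids lacks tryptophan, so it does
#' not cover `"trp"` unless `casamino_covers_trp = TRUE`.
#'
#' @param experiments Experiment table (see [simulate_experiments()]).
#' @param amino_acid Three-letter lower-case amino acid code.
#' @param casamino_covers_trp Treat casamino acids as supplying tryptophan.
#' @return Logical vector, one element per experiment row.
#' @export
amino_acid_available <- function(experiments, amino_acid,
                                 casamino_covers_trp = FALSE) {
  assert_columns(
    experiments,
    c("media_class", "supplements", "carbon_source", "nitrogen_source"),
    "`experiments`"
  )
  supp <- supplement_names(experiments$supplements)
  vapply(seq_len(nrow(experiments)), function(i) {
    e <- experiments[i, ]
    if (e$media_class == "rich") return(TRUE)
    s <- supp[[i]]
    if (amino_acid %in% s) return(TRUE)
    if ("yeast_extract" %in% s) return(TRUE)
    if ("casamino_acids" %in% s && (amino_acid != "trp" || casamino_covers_trp)) {
      return(TRUE)
    }
    identical(e$carbon_source, amino_acid) ||
      identical(e$nitrogen_source, amino_acid)
  }, logical(1))
}

# Random unique DNA barcodes (collision re-draw).
random_barcodes <- function(n, width = 20) {
  draw <- function(k) {
    m <- matrix(sample(NUCLEOTIDES, k * width, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  bc <- draw(n)
  while (anyDuplicated(bc) > 0) {
    dup <- duplicated(bc)
    bc[dup] <- draw(sum(dup))
  }
  bc
}

# GC fraction of a nucleotide string (vectorized over a character vector).
gc_fraction <- function(seqs) {
  vapply(seqs, function(s) {
    if (nchar(s) == 0) return(NA_real_)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(chars %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}
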