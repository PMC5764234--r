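# Synthetic-data generator: genomes, truth, pools, counts, annotations.

test_that("simulated genes realize their intended GC content", {
  gn <- simulate_genome(1, mean_gene_len = 900, gc_range = c(0.5, 0.5),
                        intergenic_len = 100, seed = 7)
  g <- gn$genes
  seq <- substr(gn$genome[[g$scaffold_id]], g$begin, g$end)
  chars <- strsplit(seq, "")[[1]]
  expect_lt(abs(mean(chars %in% c("G", "C")) - 0.5), 0.02)

  # intended vs realized GC across a spread of genes, recomputed from the
  # emitted FASTA with Biostrings (independent of package internals)
  gn2 <- simulate_genome(200, gc_range = c(0.3, 0.7), seed = 3)
  fa <- withr::local_tempfile(fileext = ".fna")
  write_genome(gn2$genome, fa)
  dna <- Biostrings::readDNAStringSet(fa)
  realized <- vapply(seq_len(nrow(gn2$genes)), function(i) {
    g <- gn2$genes[i, ]
    sub <- Biostrings::subseq(dna[[g$scaffold_id]], g$begin, g$end)
    sum(Biostrings::letterFrequency(sub, c("G", "C"))) / length(sub)
  }, numeric(1))
  expect_gt(cor(gn2$genes$gc_intended, realized), 0.95)
})

test_that("genome simulation is deterministic and validates gc_range", {
  a <- simulate_genome(50, seed = 11)
  b <- simulate_genome(50, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$genome, simulate_genome(50, seed = 12)$genome))
  expect_error(simulate_genome(10, gc_range = c(0.7, 0.3)), "gc_range")
  expect_error(simulate_genome(10, gc_range = c(0, 0.5)), "gc_range")
})

test_that("gene models are non-overlapping, stranded, and in-bounds", {
  gn <- simulate_genome(2050, mean_gene_len = 300, seed = 2)
  expect_identical(length(gn$genome), 3L)  # 1000 genes per scaffold
  for (sc in names(gn$genome)) {
    g <- dplyr::arrange(dplyr::filter(gn$genes, scaffold_id == sc), begin)
    expect_true(all(g$begin <= g$end))
    expect_true(all(g$end <= nchar(gn$genome[[sc]])))
    if (nrow(g) > 1) {
      expect_true(all(g$begin[-1] > g$end[-nrow(g)]))
      expect_true(all(g$strand[-1] != g$strand[-nrow(g)]))
    }
  }
  expect_false(anyDuplicated(gn$genes$gene_id) > 0)
})

test_that("plant_truth assigns exactly the requested roles", {
  gn <- simulate_genome(500, seed = 4)
  pw <- aa_pathways()
  rx <- aa_reactions()

  neutral <- plant_truth(gn$genes, pw, rx, frac_essential = 0,
                         auxotroph_spec = integer(0), seed = 1)
  expect_true(all(!neutral$essential))
  expect_true(all(neutral$effect == 0))
  expect_true(all(is.na(neutral$role)))

  tr <- plant_truth(gn$genes, pw, rx, frac_essential = 0.1,
                    auxotroph_spec = c(his = 3), effect_size = -4, seed = 11)
  expect_identical(sum(tr$essential), 50L)
  his <- dplyr::filter(tr, amino_acid == "his")
  expect_identical(nrow(his), 3L)
  expect_true(all(his$effect == -4))
  # his roles land on non-transaminase steps of the histidine pathway
  his_steps <- pw$reaction_id[pw$amino_acid == "his"]
  trans <- rx$reaction_id[rx$is_transaminase]
  expect_true(all(his$role %in% setdiff(his_steps, trans)))
  # essential genes carry no effect
  expect_true(all(is.na(tr$effect[tr$essential])))

  expect_error(
    plant_truth(gn$genes[1:3, ], pw, rx, frac_essential = 0.5,
                auxotroph_spec = c(his = 3)),
    "exceed"
  )
})

test_that("planted effects vanish wherever the amino acid is available", {
  w <- tiny_world()
  eff <- true_effects(w$truth, w$experiments)
  aux <- dplyr::filter(w$truth, !essential, !is.na(amino_acid), effect < 0)
  for (i in seq_len(nrow(aux))) {
    g <- aux[i, ]
    e <- dplyr::filter(eff, gene_id == g$gene_id)
    avail <- amino_acid_available(w$experiments, g$amino_acid)
    on <- w$experiments$media_class == "defined" & !avail
    expect_true(all(e$effect[match(w$experiments$exp_id[on], e$exp_id)] ==
                      g$effect))
    expect_true(all(e$effect[match(w$experiments$exp_id[!on], e$exp_id)] == 0))
  }
})

test_that("essential genes receive no central insertions", {
  w <- tiny_world()
  pool2 <- assign_genes(w$pool, w$genes)
  ess <- w$truth$gene_id[w$truth$essential]
  hits <- dplyr::filter(pool2, gene_id %in% ess, central)
  expect_identical(nrow(hits), 0L)
})

test_that("distinct insertion locations match an independent recount", {
  gn <- simulate_genome(900, seed = 21)  # ~0.95 Mb
  tr <- plant_truth(gn$genes, aa_pathways(), aa_reactions(),
                    frac_essential = 0, seed = 21)
  pool <- simulate_pool(gn$genome, gn$genes, tr, 50000, seed = 22)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(pool, tsv)
  # brute-force rescan of the emitted file with base R
  raw <- read.delim(tsv, stringsAsFactors = FALSE)
  observed <- length(unique(paste(raw$scaffold_id, raw$pos, raw$strand)))
  # analytic expectation for uniform sampling of N strains over 2P
  # (position, strand) slots
  P <- 2 * sum(nchar(gn$genome))
  expected <- P * (1 - (1 - 1 / P)^nrow(pool))
  expect_lt(abs(observed - expected) / expected, 0.05)
  expect_true(all(raw$n_reads >= 2))
  expect_false(anyDuplicated(raw$barcode) > 0)
})

test_that("unbiased pools show no density-vs-GC trend", {
  w <- cached("flat_world", simulate_world(n_genes = 300, frac_essential = 0,
                                           gc_bias_slope = 0, seed = 9))
  st <- gene_insertion_stats(w$pool, w$genes, w$genome)
  fit <- lm(density ~ gc, data = st)
  ci <- confint(fit)["gc", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("condition counts scale as 2^fitness relative to neutral strains", {
  gn <- simulate_genome(40, seed = 31)
  pw <- aa_pathways(); rx <- aa_reactions()
  tr <- plant_truth(gn$genes, pw, rx, frac_essential = 0,
                    auxotroph_spec = list(his = "histidinol_dehydrogenase"),
                    effect_size = -4, seed = 31)
  exps <- tibble::tibble(
    exp_id = "min_r1", media_class = "defined", supplements = "",
    carbon_source = "glucose", nitrogen_source = "ammonia",
    replicate_group = "min", time0_id = "T0_1", generations = 6
  )
  pool <- simulate_pool(gn$genome, gn$genes, tr, 8000, seed = 32)
  cnt <- simulate_counts(pool, gn$genes, tr, exps,
                         mean_depth_per_strain = 200, seed = 33)
  pool2 <- assign_genes(pool, gn$genes)
  hit_gene <- tr$gene_id[!is.na(tr$role)]
  is_hit <- pool2$central & !is.na(pool2$gene_id) & pool2$gene_id == hit_gene
  is_neutral <- pool2$central & !is.na(pool2$gene_id) &
    pool2$gene_id != hit_gene
  # same time0 abundance model for both groups, so the mean count ratio
  # estimates 2^effect
  ratio <- (mean(cnt$min_r1[is_hit]) / mean(cnt$T0_1[is_hit])) /
    (mean(cnt$min_r1[is_neutral]) / mean(cnt$T0_1[is_neutral]))
  expect_lt(abs(log2(ratio) - (-4)), 0.35)
})

test_that("annotation drops control gap and candidate structure", {
  gn <- simulate_genome(30, seed = 41)
  pw <- tibble::tibble(
    amino_acid = "his", variant_id = "v1", step_index = 1:3,
    reaction_id = c("r1", "r2", "r3")
  )
  rx <- tibble::tibble(reaction_id = c("r1", "r2", "r3"),
                       name = c("a", "b", "c"), is_transaminase = FALSE)
  tr <- plant_truth(gn$genes, pw, rx, frac_essential = 0,
                    auxotroph_spec = list(his = c("r1", "r2", "r3")),
                    seed = 41)

  # no drops: every step annotated by the baseline, no gaps downstream
  ann0 <- simulate_annotations(tr, pw, rx, n_resources = 3)
  expect_identical(nrow(find_gaps(ann0, pw)), 0L)

  # dropped from the baseline only: a gap with a clear 3/3 candidate
  drop1 <- tibble::tibble(reaction_id = "r2", resource_id = "baseline")
  ann1 <- simulate_annotations(tr, pw, rx, n_resources = 3, drop_spec = drop1)
  gaps1 <- find_gaps(ann1, pw)
  expect_identical(gaps1$reaction_id, "r2")
  cand1 <- clear_candidates(gaps1, ann1)
  expect_identical(nrow(dplyr::filter(cand1, clear)), 1L)
  expect_identical(dplyr::filter(cand1, clear)$support, 3L)

  # dropped from the baseline and 2 of 3 resources: gap, no clear candidate
  drop2 <- tibble::tibble(
    reaction_id = "r2", resource_id = c("baseline", "res1", "res2")
  )
  ann2 <- simulate_annotations(tr, pw, rx, n_resources = 3, drop_spec = drop2)
  gaps2 <- find_gaps(ann2, pw)
  cand2 <- clear_candidates(gaps2, ann2)
  expect_identical(nrow(dplyr::filter(cand2, clear)), 0L)
  expect_identical(cand2$support, 1L)

  expect_error(
    simulate_annotations(tr, pw, rx, drop_spec = tibble::tibble(
      reaction_id = "nope", resource_id = "baseline"
    )),
    "unknown reaction"
  )
})

test_that("world simulation and file output are byte-deterministic", {
  w1 <- simulate_world(n_genes = 40, target_strains = 400, seed = 3)
  w2 <- simulate_world(n_genes = 40, target_strains = 400, seed = 3)
  expect_identical(w1[setdiff(names(w1), "params")],
                   w2[setdiff(names(w2), "params")])

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_world(w1, d1)
  write_world(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("every count-table barcode exists in the pool", {
  w <- tiny_world()
  expect_true(all(w$counts$barcode %in% w$pool$barcode))
  expect_true(all(!is.na(match(
    dplyr::filter(w$truth, !is.na(role))$gene_id, w$genes$gene_id
  ))))
})
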