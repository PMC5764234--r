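# Phenotype calls, rescue scans, gap classification, ledger summaries.

test_that("phenotype calls follow the fitness evidence", {
  exps <- toy_experiments()
  fit <- toy_fitness(list(
    aux = c(-5, -4.8, -0.1, 0.1, 0, 0.05),      # sick in minimal, rescued
    flat = c(0.2, -0.3, 0.4, -0.2, 0.1, 0),     # no phenotype anywhere
    sick = c(-4, -4, -4, -4, -3.5, -3.8)        # sick even with amino acids
  ))
  calls <- phenotype_call(fit, exps, essential_ids = "essgene")
  get <- function(g) calls$class[calls$gene_id == g]
  expect_identical(get("aux"), "auxotrophic")
  expect_identical(get("flat"), "no_phenotype")
  expect_identical(get("sick"), "no_phenotype")  # replete median < t_neutral
  # essential set wins even with no fitness rows at all
  expect_identical(get("essgene"), "essential")

  # a gene with data in under half the defined groups is no_data
  sparse <- toy_fitness(list(sp = c(-5)))  # min_r1 only: 1 of 2 groups
  sparse <- dplyr::bind_rows(sparse, toy_fitness(list(full = rep(0, 6))))
  calls2 <- phenotype_call(sparse, exps)
  expect_identical(calls2$class[calls2$gene_id == "sp"], "no_data")

  # defined-minimal experiments are required
  rich_only <- dplyr::filter(exps, media_class == "rich")
  expect_error(phenotype_call(fit, rich_only), "defined")
})

test_that("rescue uses strict inequalities at -2 and -1", {
  exps <- toy_experiments()
  fit <- toy_fitness(list(
    at_low = c(-2, -2, 0, 0, 0, 0),            # exactly -2: not under -2
    below = c(-2.01, -2.01, 0, 0, 0, 0),       # rescued
    at_high = c(-3.5, -3.5, -1, -1, 0, 0),     # exactly -1: not above -1
    partial = c(-3.5, -3.5, -0.99, -0.99, 0, 0),  # just rescued
    not_resc = c(-3.5, -3.5, -2.5, -2.5, 0, 0)
  ))
  scan <- rescue_scan(fit, exps, "his")
  get <- function(g) scan$rescued[scan$gene_id == g]
  expect_false(get("at_low"))
  expect_true(get("below"))
  expect_false(get("at_high"))
  expect_true(get("partial"))
  expect_false(get("not_resc"))
  # strongest rescue first
  expect_identical(scan$gene_id[1], "partial")
  # relaxing f_high never removes a rescued gene
  relaxed <- rescue_scan(fit, exps, "his", f_high = -1.5)
  expect_true(all(scan$gene_id[scan$rescued] %in%
                    relaxed$gene_id[relaxed$rescued]))

  expect_error(rescue_scan(fit, exps, "trp"), "supplemented")
})

test_that("the classification tree resolves each evidence pattern", {
  pw <- tibble::tibble(
    amino_acid = "his", variant_id = "v1", step_index = 1:3,
    reaction_id = c("rA", "rB", "rC")
  )
  gap <- function(rx) tibble::tibble(
    organism = "org", amino_acid = "his", variant_id = "v1",
    reaction_id = rx, classification = NA_character_,
    filled_by = NA_character_
  )
  cand <- function(rx, genes, support = 3L) tibble::tibble(
    organism = "org", amino_acid = "his", reaction_id = rx,
    gene_id = genes, support = support, clear = support >= 2
  )
  phen <- function(genes, classes) tibble::tibble(
    gene_id = genes, class = classes,
    median_defined = NA_real_, median_replete = NA_real_,
    n_defined = 4L, n_replete = 2L
  )
  no_rescue <- tibble::tibble(
    gene_id = character(0), compound = character(0),
    fitness_minimal = numeric(0), fitness_supplemented = numeric(0),
    rescued = logical(0)
  )
  ann <- tibble::tibble(
    gene_id = c("gA", "gB"), resource_id = "res1",
    reaction_id = c("rA", "rB")
  )

  # clear candidate with auxotrophic phenotype
  out <- classify_gaps(gap("rC"), cand("rC", "gX"),
                       phen("gX", "auxotrophic"), no_rescue, ann, pw)
  expect_identical(out$classification, "clear_auxotrophic")

  # clear candidate phenotypes map onto their classes
  for (case in list(c("essential", "clear_essential"),
                    c("no_phenotype", "clear_other"))) {
    out <- classify_gaps(gap("rC"), cand("rC", "gX"),
                         phen("gX", case[1]), no_rescue, ann, pw)
    expect_identical(out$classification, case[2])
  }
  # candidate absent from the phenotype table: no fitness data
  out <- classify_gaps(gap("rC"), cand("rC", "gX"), phen(character(0),
                                                         character(0)),
                       no_rescue, ann, pw)
  expect_identical(out$classification, "clear_nodata")

  # two measured, phenotype-free clear candidates: redundancy
  out <- classify_gaps(gap("rC"), cand("rC", c("gX", "gY")),
                       phen(c("gX", "gY"), rep("no_phenotype", 2)),
                       no_rescue, ann, pw)
  expect_identical(out$classification, "clear_redundant")

  # two clear candidates without data: multiple candidates
  out <- classify_gaps(gap("rC"), cand("rC", c("gX", "gY")),
                       phen(character(0), character(0)), no_rescue, ann, pw)
  expect_identical(out$classification, "clear_multiple")

  # two clear candidates, one auxotrophic: the phenotype carrier decides
  out <- classify_gaps(gap("rC"), cand("rC", c("gX", "gY")),
                       phen(c("gX", "gY"), c("no_phenotype", "auxotrophic")),
                       no_rescue, ann, pw)
  expect_identical(out$classification, "clear_auxotrophic")
  expect_identical(out$best_candidate, "gY")

  # no clear candidate + a rescued unannotated gene: genuine, filled
  rescue <- tibble::tibble(
    gene_id = c("gNew", "gB"), compound = "his",
    fitness_minimal = c(-4, -3.6), fitness_supplemented = c(-0.1, 0),
    rescued = TRUE
  )
  out <- classify_gaps(gap("rC"), cand("rC", character(0))[0, ],
                       phen(character(0), character(0)), rescue, ann, pw)
  expect_identical(out$classification, "genuine_filled")
  # gB is annotated to another step of the same pathway and cannot fill
  expect_identical(out$filled_by, "gNew")

  # no clear candidate, no rescue: genuine, unfilled
  out <- classify_gaps(gap("rC"), cand("rC", character(0))[0, ],
                       phen(character(0), character(0)), no_rescue, ann, pw)
  expect_identical(out$classification, "genuine_unfilled")

  # special flags set earlier are preserved
  g <- gap("rC"); g$classification <- "transaminase"
  out <- classify_gaps(g, cand("rC", "gX"), phen("gX", "auxotrophic"),
                       no_rescue, ann, pw)
  expect_identical(out$classification, "transaminase")
})

test_that("ledger summaries count every record exactly once", {
  gaps <- tibble::tibble(
    organism = "org1",
    amino_acid = c("his", "his", "met", "ser"),
    variant_id = "v1",
    reaction_id = paste0("r", 1:4),
    classification = c("clear_auxotrophic", "clear_essential",
                       "transaminase", "genuine_filled"),
    filled_by = c(NA, NA, NA, "g1")
  )
  led <- summarize_ledger(gaps)
  expect_identical(sum(led$summary$cases), 4L)
  expect_identical(led$n_gaps, 4L)
  # two clear-candidate gaps in one cell collapse to "c2"
  his <- led$grid$codes[led$grid$amino_acid == "his"]
  expect_identical(his, "c2")
  expect_identical(led$grid$codes[led$grid$amino_acid == "ser"], "f")

  # zero gaps: empty but valid
  led0 <- summarize_ledger(gaps[0, ])
  expect_identical(led0$n_gaps, 0L)
  expect_identical(nrow(led0$summary), 0L)

  # unclassified records are an error naming the offenders
  bad <- gaps; bad$classification[2] <- NA
  expect_error(summarize_ledger(bad), "his/r2")
})

test_that("the packaged ten-bacteria ledger round-trips exactly", {
  ref <- reference_gap_ledger()
  expanded <- expand_ledger(ref)
  expect_identical(nrow(expanded), sum(ref$cases))
  led <- summarize_ledger(expanded)
  expect_identical(as.data.frame(led$summary), as.data.frame(ref))
})

test_that("planted worlds classify their gaps as designed", {
  w <- default_world()
  an <- default_analysis()
  gaps <- an$gaps
  cls <- function(rx) gaps$classification[gaps$reaction_id == rx]
  expect_setequal(cls("histidinol_phosphate_transaminase"), "transaminase")
  expect_setequal(cls("phosphoserine_transaminase"), "transaminase")
  expect_identical(cls("cog2122_activation"), "clear_auxotrophic")
  expect_identical(cls("homoserine_kinase"), "clear_auxotrophic")
  expect_identical(cls("aspartate_kinase"), "clear_redundant")
  expect_identical(cls("histidinol_phosphate_phosphatase"), "genuine_filled")
  # the filler is the planted, nowhere-annotated phosphatase gene
  planted <- w$truth$gene_id[!is.na(w$truth$role) &
                               w$truth$role == "histidinol_phosphate_phosphatase"]
  expect_identical(gaps$filled_by[gaps$classification == "genuine_filled"],
                   planted)
  expect_identical(sum(an$ledger$summary$cases), nrow(gaps))
})
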