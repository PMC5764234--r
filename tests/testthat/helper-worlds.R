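# Shared fixtures built in code. Heavier simulated worlds are cached per
# session so several test files can reuse them.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, force(expr), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# The default synthetic study (500 genes, 20 strains/gene, depth 50).
default_world <- function(seed = 1) {
  cached(paste0("world_", seed), simulate_world(seed = seed))
}

default_analysis <- function(seed = 1) {
  cached(paste0("analysis_", seed), analyze_world(default_world(seed)))
}

# A small fast world for structural checks.
tiny_world <- function(seed = 1) {
  cached(paste0("tiny_", seed),
         simulate_world(n_genes = 80, target_strains = 1600, seed = seed))
}

# Planted auxotrophy genes (negative effect, non-essential) of a world.
planted_auxotrophs <- function(world) {
  t <- world$truth
  t$gene_id[!t$essential & !is.na(t$amino_acid) &
              !is.na(t$effect) & t$effect < 0]
}

# Minimal hand-built fitness/experiment fixtures for classifier tests.
toy_experiments <- function() {
  tibble::tibble(
    exp_id = c("min_r1", "min_r2", "plus_his_r1", "plus_his_r2",
               "rich_r1", "rich_r2"),
    media_class = c("defined", "defined", "defined", "defined",
                    "rich", "rich"),
    supplements = c("", "", "his:1", "his:1", "", ""),
    carbon_source = "glucose",
    nitrogen_source = c(rep("ammonia", 4), "rich", "rich"),
    replicate_group = c("min", "min", "plus_his", "plus_his",
                        "rich", "rich"),
    time0_id = rep(c("T0_1", "T0_2"), 3),
    generations = 6
  )
}

toy_fitness <- function(values) {
  # values: named list gene_id -> numeric vector over toy_experiments rows
  exps <- toy_experiments()$exp_id
  purrr::map_dfr(names(values), function(g) {
    v <- values[[g]]
    tibble::tibble(gene_id = g, exp_id = exps[seq_along(v)], fitness = v,
                   n_strains = 3L, t0_reads = 60L)
  })
}
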