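library(data.table)

# tiny genome used across unit tests
tiny_genome <- function(blocklist = NULL) {
  genome_spec(c(chr1 = 1e6, chr2 = 5e5), blocklist)
}

# scaled-down simulation shared by recovery tests (memoised per session)
.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_scale = 0.5, contacts_per_cell = 8000L,
             cg_spacing = 10000, ch_spacing = 20000, ccc_spacing = 50000,
             ...)
}

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- small_sim_config()
    .fixture_env$cfg <- cfg
    .fixture_env$cohort <- simulate_cohort(cfg)
  }
  list(cfg = .fixture_env$cfg, cohort = .fixture_env$cohort)
}

# random contact table on a genome (uniform, for oracle checks)
random_contacts <- function(n, genome, seed = 1) {
  set.seed(seed)
  ch1 <- sample(genome$chroms, n, replace = TRUE)
  ch2 <- sample(genome$chroms, n, replace = TRUE)
  contact_table(data.table(
    chrom1 = ch1, pos1 = floor(runif(n, 0, genome$lengths[ch1])),
    chrom2 = ch2, pos2 = floor(runif(n, 0, genome$lengths[ch2]))), genome)
}
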