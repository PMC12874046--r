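# Pseudobulk 3D-genome analyses: O/E, compartments, insulation, loops.

# dense binned_matrix directly from a count matrix
as_bm <- function(mat, resolution = 25e3, chrom = "chrT") {
  structure(list(mat = mat, resolution = resolution, chrom = chrom,
                 n_contacts = sum(mat[upper.tri(mat, diag = TRUE)]),
                 oe = NULL, expected = NULL),
            class = "binned_matrix")
}

# plaid matrix: within-label pairs enriched by factor c over background
plaid_matrix <- function(n = 40, block = 4, c_enrich = 2, base = 10,
                         noise_sd = 0, seed = 1) {
  set.seed(seed)
  lab <- rep(rep(c("A", "B"), each = block), length.out = n)
  m <- matrix(base, n, n)
  same <- outer(lab, lab, "==")
  m[same] <- base * c_enrich
  if (noise_sd > 0) {
    e <- matrix(rnorm(n * n, 0, noise_sd), n, n)
    e <- (e + t(e)) / 2
    m <- pmax(m + e, 0)
  }
  list(mat = m, labels = lab)
}

test_that("oe_normalize matches brute-force per-diagonal division", {
  set.seed(2)
  n <- 20
  m <- matrix(rpois(n * n, 12), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  bm <- oe_normalize(as_bm(m))
  # brute force
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d); j <- i + d
    e <- mean(m[cbind(i, j)])
    expect_equal(bm$expected[d + 1], e)
    if (e > 0) expect_equal(bm$oe[cbind(i, j)], m[cbind(i, j)] / e)
    # O/E mean along each diagonal is 1 by construction
    if (e > 0) expect_equal(mean(bm$oe[cbind(i, j)]), 1)
  }
  # a matrix equal to its expected profile has O/E identically 1
  flat <- matrix(0, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d); j <- i + d
    flat[cbind(i, j)] <- n - d
    flat[cbind(j, i)] <- n - d
  }
  bf <- oe_normalize(as_bm(flat))
  expect_true(all(abs(bf$oe - 1) < 1e-12, na.rm = TRUE))
  expect_error(oe_normalize(as_bm(matrix(0, 5, 5))), "empty")
})

test_that("compartment PC1 recovers a perfect plaid and obeys the sign rule", {
  pl <- plaid_matrix(n = 40, c_enrich = 2)
  bm <- oe_normalize(as_bm(pl$mat, resolution = 250e3))
  # orientation covariate: B-compartment bins more methylated
  mcg <- ifelse(pl$labels == "B", 0.8, 0.7)
  tr <- compartment_pc1(bm, covariate = mcg)
  called <- ifelse(tr$pc1 > 0, "A", "B")
  expect_equal(called, pl$labels)                 # 100% of bins
  expect_equal(sum(tr$pc1^2), 1)                  # unit norm
  # flipping the covariate reverses every sign deterministically
  tr_flip <- compartment_pc1(bm, covariate = -mcg)
  expect_equal(tr_flip$pc1, -tr$pc1)
  # density orientation points the other way
  dens <- ifelse(pl$labels == "A", 5, 1)
  tr_d <- compartment_pc1(bm, covariate = dens, orient = "density")
  expect_equal(ifelse(tr_d$pc1 > 0, "A", "B"), pl$labels)
  expect_error(compartment_pc1(oe_normalize(as_bm(matrix(1, 12, 12)))),
               "no compartment signal")
})

test_that("compartment PC1 tolerates noise at >= 95% label agreement", {
  pl <- plaid_matrix(n = 60, c_enrich = 2, base = 10, noise_sd = 4, seed = 9)
  bm <- oe_normalize(as_bm(pl$mat, resolution = 250e3))
  mcg <- ifelse(pl$labels == "B", 0.8, 0.7)
  tr <- compartment_pc1(bm, covariate = mcg)
  expect_gte(mean(ifelse(tr$pc1 > 0, "A", "B") == pl$labels), 0.95)
})

test_that("compartment strength is ~1 without structure and monotone in plaid contrast", {
  # label-free random matrix
  set.seed(3)
  n <- 50
  m <- matrix(rpois(n * n, 20), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  bm <- oe_normalize(as_bm(m))
  tr <- compartment_pc1(bm)
  s0 <- compartment_strength(bm, tr)
  expect_lt(abs(s0 - 1), 0.25)
  # monotone in enrichment
  strengths <- vapply(c(1.2, 1.5, 2), function(ce) {
    pl <- plaid_matrix(n = 40, c_enrich = ce)
    bmx <- oe_normalize(as_bm(pl$mat))
    trx <- compartment_pc1(bmx, covariate = ifelse(pl$labels == "B", 1, 0))
    compartment_strength(bmx, trx)
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
  # destroying segregation by label permutation drives strength to ~1
  pl <- plaid_matrix(n = 40, c_enrich = 2)
  set.seed(4)
  perm <- sample(40)
  bmp <- oe_normalize(as_bm(pl$mat[perm, perm]))
  # a random permutation scrambles the plaid; strength on a random track
  trp <- data.table(chrom = "chrT", bin = 0:39, start = 0, end = 0,
                    pc1 = rnorm(40), masked = FALSE)
  expect_lt(abs(compartment_strength(bmp, trp) - 1), 0.3)
})

test_that("compartment switches are detected and merged into runs", {
  tr <- function(v) data.table(chrom = "chrT", bin = seq_along(v) - 1L,
                               start = (seq_along(v) - 1) * 1e6,
                               end = seq_along(v) * 1e6, pc1 = v,
                               masked = FALSE)
  a <- tr(c(0.5, 0.5, -0.5, -0.5, 0.5))
  expect_equal(nrow(compartment_switches(a, a)), 0)
  b <- tr(c(0.5, -0.5, -0.5, -0.5, 0.5))
  sw <- compartment_switches(a, b, min_delta = 0.5)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$direction, "A->B")
  expect_equal(sw$n_bins, 1L)
  # antisymmetry of direction
  sw2 <- compartment_switches(b, a, min_delta = 0.5)
  expect_equal(sw2$direction, "B->A")
  expect_error(compartment_switches(a, tr(rep(0.1, 3))), "identical bins")
})

test_that("variance partitioning resolves toy designs", {
  # one factor, all variance between levels
  scores <- rbind(bin1 = c(1, 1, 5, 5), bin2 = c(2, 2, 8, 8))
  f <- data.frame(age = c("y", "y", "o", "o"))
  vp <- variance_partition(scores, f)
  expect_equal(unname(vp["age"]), 1)
  expect_equal(unname(vp["residual"]), 0)
  # equal-effect balanced two-factor design -> equal fractions
  f2 <- expand.grid(age = c("y", "o"), sub = c("m", "s"))
  y <- 1 * (f2$age == "o") + 1 * (f2$sub == "s")
  scores2 <- rbind(bin1 = y, bin2 = y + 10)
  vp2 <- variance_partition(scores2, f2)
  expect_equal(unname(vp2["age"]), unname(vp2["sub"]), tolerance = 1e-12)
  expect_equal(sum(vp2), 1)
  # dominant factor wins on a noisy design
  set.seed(6)
  f3 <- expand.grid(age = paste0("a", 1:3), sub = c("m", "s"), rep = 1:2)
  eff <- 3 * as.integer(f3$age) + 1 * (f3$sub == "s")
  scores3 <- t(replicate(40, eff + rnorm(nrow(f3), 0, 0.8)))
  vp3 <- variance_partition(scores3, f3[, c("age", "sub")])
  expect_gt(vp3["age"], vp3["sub"])
  expect_warning(variance_partition(scores, data.frame(age = f$age,
                                                       one = "x")),
                 "single-level")
})

test_that("insulation score matches brute force and finds block junctions", {
  # uniform matrix -> score 0 on unmasked bins
  u <- as_bm(matrix(7, 30, 30))
  tu <- insulation_score(u, window = 4 * 25e3)
  expect_true(all(abs(tu$insulation[tu$valid]) < 1e-12))
  expect_equal(sum(!tu$valid), 8)    # w bins masked at each edge
  # two-block toy: global minimum at the junction
  n <- 30
  lab <- rep(1:2, each = 15)
  m <- matrix(2, n, n)
  m[outer(lab, lab, "==")] <- 20
  bm <- as_bm(m)
  tr <- insulation_score(bm, window = 4 * 25e3)
  expect_true(which.min(tr$insulation) %in% 15:16)  # at the junction
  # brute-force diamond oracle
  w <- 4
  for (i in (w + 1):(n - w)) {
    expect_equal(tr$diamond[i], mean(m[(i - w):(i - 1), (i + 1):(i + w)]))
  }
  expect_equal(tr$insulation,
               log2(tr$diamond / mean(tr$diamond, na.rm = TRUE)))
  expect_error(insulation_score(as_bm(matrix(1, 10, 10)), window = 1e5),
               "shorter than 3 windows")
})

test_that("boundary calling requires prominent local minima", {
  mk_track <- function(x) data.table(chrom = "chrT", bin = seq_along(x) - 1L,
                                     start = (seq_along(x) - 1) * 25e3,
                                     end = seq_along(x) * 25e3,
                                     insulation = x, valid = is.finite(x))
  # monotone track: no boundaries
  expect_equal(nrow(call_boundaries(mk_track(seq(0, 2, length.out = 30)))), 0)
  # single sharp minimum of depth 1
  x <- rep(0, 30); x[15] <- -1
  bd <- call_boundaries(mk_track(x), min_depth = 0.5)
  expect_equal(bd$bin, 14L)
  expect_equal(bd$prominence, 1)
  # shallow dip below the prominence threshold is ignored
  x2 <- rep(0, 30); x2[10] <- -0.3
  expect_equal(nrow(call_boundaries(mk_track(x2), min_depth = 0.5)), 0)
  # plateau ties break to the leftmost bin
  x3 <- rep(0, 30); x3[12:13] <- -1
  expect_equal(call_boundaries(mk_track(x3), min_depth = 0.5)$bin, 11L)
})

test_that("planted boundaries are recovered from simulated pseudobulks", {
  cfg <- small_sim_config()
  cells <- lapply(1:80, function(i)
    simulate_contacts_cell(cfg, "MSN", "adult", m = 0.9, seed = 600 + i,
                           n = 20000))
  bulk <- pool_contacts(cells)
  bm <- bin_contacts(bulk, 25e3, "chr3", cfg$genome)
  # at this pseudobulk depth a 200-kb window with light smoothing is the
  # operating point (the methods vignette motivates both)
  tr <- insulation_score(bm, window = 2e5)
  bd <- call_boundaries(tr, min_depth = 0.5, smooth_bins = 3)
  truth_bins <- sort(c(cfg$boundaries[["adult"]]$chr3)) %/% 25e3
  # precision is scored against everything the generator plants that
  # insulates: TAD boundaries plus compartment-plaid block borders (label
  # switches thin cross-border contacts, so borders dip weakly, as
  # compartment transitions do in real insulation tracks)
  plaid_edges <- seq(cfg$plaid_block, cfg$genome$lengths[["chr3"]] - 1,
                     by = cfg$plaid_block) %/% 25e3
  truth_all <- sort(unique(c(truth_bins, plaid_edges)))
  hit <- vapply(truth_bins, function(b) any(abs(bd$bin - b) <= 1), logical(1))
  called_true <- vapply(bd$bin, function(b)
    any(abs(truth_all - b) <= 1), logical(1))
  expect_gte(mean(hit), 0.8)           # recall of planted TAD boundaries
  expect_gte(mean(called_true), 0.8)   # precision vs planted structure
})

test_that("boundary probability is deterministic, order-invariant and calibrated", {
  cfg <- small_sim_config()
  cells <- lapply(1:30, function(i)
    simulate_contacts_cell(cfg, "MSN", "adult", m = 0.9, seed = 700 + i,
                           n = 20000))
  names(cells) <- sprintf("c%02d", seq_along(cells))
  bp1 <- boundary_probability(cells, cfg$genome, "chr3", window = 2e5,
                              smooth_bins = 3, B = 20, seed = 5)
  bp2 <- boundary_probability(cells[sample(30)], cfg$genome, "chr3",
                              window = 2e5, smooth_bins = 3, B = 20, seed = 5)
  expect_identical(bp1$prob, bp2$prob)
  expect_true(all(bp1$prob >= 0 & bp1$prob <= 1))
  # planted boundaries are called far more often than background bins
  truth_bins <- cfg$boundaries[["adult"]]$chr3 %/% 25e3
  smear <- unique(as.vector(outer(truth_bins, -1:1, "+")))
  expect_gt(mean(bp1$prob[truth_bins + 1]), 0.6)
  expect_lt(mean(bp1$prob[setdiff(seq_along(bp1$prob), smear + 1)]), 0.2)
  expect_error(boundary_probability(cells, cfg$genome, "chr3", B = 5),
               ">= 20")
})

test_that("age-differential boundaries detect a stage-specific boundary with sign", {
  cfg <- small_sim_config()
  mk <- function(age, seed0) {
    cells <- lapply(1:30, function(i)
      simulate_contacts_cell(cfg, "MSN", age, m = 0.5, seed = seed0 + i,
                             n = 20000))
    names(cells) <- sprintf("c%02d", seq_along(cells))
    cells
  }
  bp_2t <- boundary_probability(mk("2T", 800), cfg$genome, "chr3",
                                window = 2e5, smooth_bins = 3, B = 20,
                                seed = 6)
  bp_3t <- boundary_probability(mk("3T", 900), cfg$genome, "chr3",
                                window = 2e5, smooth_bins = 3, B = 20,
                                seed = 7)
  db <- differential_boundaries(bp_2t, bp_3t)
  # the boundary planted only from 3T onward (chr3 @ 11 Mb)
  new_bin <- 11.5e6 %/% 25e3
  hit <- db[abs(bin - new_bin) <= 1 & significant == TRUE]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$direction == "gain"))
  # swapping groups flips every gain to loss
  db_rev <- differential_boundaries(bp_3t, bp_2t)
  hit_rev <- db_rev[abs(bin - new_bin) <= 1 & significant == TRUE]
  expect_true(all(hit_rev$direction == "loss"))
})

test_that("loop calling needs local enrichment and scores planted point masses", {
  # uniform matrix: no loops
  u <- as_bm(matrix(6, 40, 40), resolution = 1e4)
  expect_equal(sum(call_loops(u)$significant), 0)
  # single planted point mass at 10x local background
  m <- matrix(3, 40, 40)
  m[10, 25] <- m[25, 10] <- 30
  lp <- call_loops(as_bm(m, resolution = 1e4))
  hit <- lp[bin1 == 9 & bin2 == 24]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$enrich, 10)
  expect_true(hit$significant)
  # differential looping: gains outnumber losses when loops are added later
  m_a <- matrix(3, 40, 40)
  m_b <- m_a
  planted <- data.table(bin1 = c(5L, 12L, 20L), bin2 = c(15L, 22L, 33L))
  m_b[cbind(planted$bin1 + 1, planted$bin2 + 1)] <- 30
  m_b[cbind(planted$bin2 + 1, planted$bin1 + 1)] <- 30
  dl <- differential_loops(as_bm(m_a, 1e4), as_bm(m_b, 1e4), planted)
  expect_equal(sum(dl$significant & dl$direction == "gain"), 3)
  expect_equal(sum(dl$direction == "loss"), 0)
})

test_that("developmental loop gains outnumber losses in simulation", {
  cfg <- small_sim_config()
  mk_bulk <- function(age, seed0, m) {
    cells <- lapply(1:25, function(i)
      simulate_contacts_cell(cfg, "MSN", age, m = m, seed = seed0 + i,
                             n = 12000))
    bin_contacts(pool_contacts(cells), 1e4, "chr3", cfg$genome)
  }
  bm_early <- mk_bulk("2T", 1000, 0.1)
  bm_late <- mk_bulk("adult", 1100, 0.9)
  loops <- unique(rbind(call_loops(bm_early)[significant == TRUE,
                                             .(bin1, bin2)],
                        call_loops(bm_late)[significant == TRUE,
                                            .(bin1, bin2)]))
  dl <- differential_loops(bm_early, bm_late, loops)
  gains <- sum(dl$significant & dl$direction == "gain")
  losses <- sum(dl$significant & dl$direction == "loss")
  expect_gt(gains, losses)
})
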