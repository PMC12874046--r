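# Methylation statistics: global levels, gene matrices, signatures, DMRs.

make_sites <- function(df) meth_site_table(as.data.table(df))

test_that("global_levels pools counts and applies the conversion correction", {
  cell <- make_sites(data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40), strand = "+",
    context = c("CG", "CG", "CH", "CCC"),
    mc = c(3L, 1L, 0L, 0L), cov = c(10L, 10L, 5L, 5L)))
  gl <- global_levels(cell)
  expect_equal(gl$mcg, 4 / 20)        # (3 + 1) / (10 + 10), hand sum
  expect_equal(gl$mch, 0)
  # all-unmethylated cell
  cell0 <- make_sites(data.frame(chrom = "chr1", pos = 1:3, strand = "+",
                                 context = c("CG", "CH", "CCC"),
                                 mc = 0L, cov = 4L))
  expect_equal(unlist(global_levels(cell0)), c(mcg = 0, mch = 0, mccc = 0,
                                               mch_corrected = 0))
  # correction formula oracle: raw 0.05, mCCC 0.01 -> (0.05-0.01)/0.99
  cell2 <- make_sites(data.frame(
    chrom = "chr1", pos = c(1, 2), strand = "+", context = c("CH", "CCC"),
    mc = c(9L, 1L), cov = c(100L, 100L)))
  gl2 <- global_levels(cell2)
  expect_equal(gl2$mch, 0.05)
  expect_equal(gl2$mccc, 0.01)
  expect_equal(gl2$mch_corrected, (0.05 - 0.01) / (1 - 0.01))
  expect_lte(gl2$mch_corrected, gl2$mch)
  # a context with no coverage is NA, not 0
  expect_true(is.na(global_levels(cell2)$mcg))
})

test_that("gene_body_mc pools by membership and leaves uncovered genes NA", {
  genes <- region_set(data.table(chrom = "chr1", start = c(0, 1000),
                                 end = c(100, 1100), name = c("gA", "gB")))
  cell <- make_sites(data.frame(
    chrom = "chr1", pos = c(10L, 50L, 500L), strand = "+", context = "CG",
    mc = c(2L, 2L, 9L), cov = c(4L, 4L, 9L)))
  gm <- gene_body_mc(list(c1 = cell), genes)
  expect_equal(gm$frac["gA", "c1"], 0.5)        # (2+2)/(4+4)
  expect_true(is.na(gm$frac["gB", "c1"]))       # no covered site
  expect_equal(gm$cov["gA", "c1"], 8)
})

test_that("a silenced gene ranks top by methylation in simulation", {
  fx <- small_cohort()
  co <- fx$cohort; cfg <- fx$cfg
  # gain-trajectory genes reach mcg_global + traj_gain in mature neurons;
  # a state-marker gene of another state stays at baseline
  mature <- co$meta$cell_id[co$meta$L2 == "MSN" & co$meta$age_group == "adult"]
  meth <- lapply(co$cells[mature], `[[`, "meth")
  gm <- gene_body_mc(meth, cfg$genes[, .(chrom, start, end, name)])
  mean_f <- rowMeans(gm$frac, na.rm = TRUE)
  top <- names(sort(mean_f, decreasing = TRUE))[1:10]
  gain_genes <- cfg$genes[traj_dir == 1, name]
  expect_gt(length(intersect(top, gain_genes)), 7)
})

test_that("normalization by global level removes per-cell offsets", {
  m <- matrix(c(0.4, 0.8), 1, 2, dimnames = list("g", c("a", "b")))
  out <- normalized_gene_mc(m, c(0.8, 0.8))
  expect_equal(out["g", "a"], 0.5)
  expect_equal(normalized_gene_mc(matrix(0.6), 0.6)[1, 1], 1.0)
  expect_true(is.na(normalized_gene_mc(matrix(0.5), 0)[1, 1]))
  # simulated global offset: cells differ by a scale factor; a neutral
  # gene's between-cell variance collapses after normalization
  set.seed(1)
  scale_f <- runif(30, 0.6, 1)
  gene_frac <- 0.5 * scale_f + rnorm(30, 0, 0.005)
  mat <- rbind(gene = gene_frac)
  norm <- normalized_gene_mc(mat, scale_f)
  expect_gt(stats::var(mat[1, ]) / stats::var(norm[1, ]), 5)
})

test_that("cell distance is the summed absolute change over shared genes", {
  m <- matrix(0.5, 50, 2, dimnames = list(paste0("g", 1:50), c("a", "b")))
  m[, 2] <- m[, 2] + 0.1
  d <- cell_distance_matrix(m)
  expect_equal(d$dist["a", "b"], 5.0)
  expect_equal(d$dist["a", "a"], 0)
  expect_equal(d$n_genes["a", "b"], 50L)
  m[1, 1] <- NA
  d2 <- cell_distance_matrix(m)
  expect_equal(d2$n_genes["a", "b"], 49L)
  expect_equal(d2$dist["a", "b"], 4.9)
})

test_that("within-state distances are below between-state distances", {
  # two states differing by 0.2 at 30 of the genes, binomial noise
  set.seed(4)
  n_genes <- 60; n_cells <- 10
  base <- matrix(rbinom(n_genes * 2 * n_cells, 50, 0.5) / 50, n_genes)
  base[1:30, 1:n_cells] <- rbinom(30 * n_cells, 50, 0.7) / 50
  rownames(base) <- paste0("g", 1:n_genes)
  colnames(base) <- c(paste0("s1_", 1:n_cells), paste0("s2_", 1:n_cells))
  d <- cell_distance_matrix(base)$dist
  grp <- rep(1:2, each = n_cells)
  within <- d[outer(grp, grp, "==") & upper.tri(d)]
  between <- d[outer(grp, grp, "!=") & upper.tri(d)]
  expect_gt(mean(between), mean(within))
})

test_that("group correlation is exact on toys and invariant to scaling", {
  # genes with opposing direction between the two groups -> r = -1
  m <- matrix(c(0.1, 0.9, 0.9, 0.1, 0.3, 0.7), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  cc <- group_correlation(m)
  expect_equal(cc["A", "B"], -1)
  expect_equal(diag(cc), c(A = 1, B = 1))
  # identical pseudobulks correlate at 1 (three-group setting)
  m2 <- cbind(m, C = m[, "A"] + c(0.01, -0.01, 0))
  cc2 <- group_correlation(m2)
  expect_gt(cc2["A", "C"], 0.99)
  # per-gene affine rescaling and row order leave the result unchanged
  m3 <- m2 * 3 + 0.05
  expect_equal(group_correlation(m3[c(2, 3, 1), ]), cc2)
  # constant gene vectors dropped with warning
  m4 <- rbind(m2, g4 = c(0.5, 0.5, 0.5))
  expect_warning(cc4 <- group_correlation(m4), "1 constant")
  expect_equal(cc4, cc2)
})

test_that("sister states correlate more than distant lineages in simulation", {
  fx <- small_cohort()
  co <- fx$cohort; cfg <- fx$cfg
  grp <- fifelse(co$meta$L2 %in% c("eMSN", "MSN"), "MSN",
                 fifelse(co$meta$L2 %in% c("eINT", "INT"), "INT", "glia"))
  # in mature cells the two neuronal lineages share the trajectory-gene
  # program; glia carry none of it
  sel <- co$meta$age_group == "adult"
  meth <- lapply(co$cells[co$meta$cell_id[sel]], `[[`, "meth")
  gm <- gene_body_mc(meth, cfg$genes[, .(chrom, start, end, name)])
  pb <- sapply(c("MSN", "INT", "glia"), function(g)
    rowMeans(gm$frac[, grp[sel] == g, drop = FALSE], na.rm = TRUE))
  cc <- suppressWarnings(group_correlation(pb))
  # the two neuronal lineages share the maturation program; glia do not
  expect_gt(cc["MSN", "INT"], cc["MSN", "glia"])
})

test_that("regional signature reproduces printed-percentage arithmetic", {
  expect_equal(signature_hypo_pct(712, 751), 94.8)
  expect_equal(signature_hypo_pct(1069, 1481), 72.2)
  expect_equal(signature_hypo_pct(1115, 1250), 89.2)
})

test_that("regional_signature detects planted region effects and controls nulls", {
  set.seed(8)
  n_genes <- 200; reps <- 6
  regions <- rep(c("TCx", "DFC", "OCx"), each = reps)
  mat <- matrix(rbinom(n_genes * length(regions), 200, 0.7) / 200, n_genes,
                dimnames = list(paste0("g", 1:n_genes), NULL))
  # plant 40 genes hypomethylated in TCx
  mat[1:40, regions == "TCx"] <- rbinom(40 * reps, 200, 0.45) / 200
  rs <- regional_signature(mat, regions, "TCx")
  sig <- rs$genes[sig == TRUE]
  expect_gt(nrow(sig), 20)
  expect_gt(mean(grepl("^g([1-9]|[1-3][0-9]|40)$", sig$gene)), 0.9)
  expect_equal(rs$pct_target,
               signature_hypo_pct(rs$counts[min_region == "TCx", sum(N)],
                                  sum(rs$counts$N)))
  # null: no region effect -> about FDR-level false positives
  null <- matrix(rbinom(n_genes * length(regions), 200, 0.7) / 200, n_genes,
                 dimnames = list(paste0("n", 1:n_genes), NULL))
  rs0 <- regional_signature(null, regions, "TCx")
  expect_lte(nrow(rs0$genes[sig == TRUE]), 0.05 * n_genes + 2)
  one_rep <- c(1:3, 7, 13:15)  # DFC left with a single replicate
  expect_error(regional_signature(mat[, one_rep], regions[one_rep], "TCx"),
               "2 replicates")
})

test_that("per-site Fisher test matches stats::fisher.test exactly", {
  cases <- expand.grid(mc_a = c(0L, 3L, 20L), cov_a = c(20L, 35L),
                       mc_b = c(0L, 10L, 20L), cov_b = c(20L, 40L))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      p_pkg <- snm3c:::.fisher_p2(mc_a, cov_a - mc_a, mc_b, cov_b - mc_b)
      p_ref <- fisher.test(matrix(c(mc_a, cov_a - mc_a,
                                    mc_b, cov_b - mc_b), 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-12)
    })
  }
  # fully separated case: 20/20 vs 0/20 equals the enumerated value
  p <- snm3c:::.fisher_p2(20, 0, 0, 20)
  expect_equal(p, fisher.test(matrix(c(20, 0, 0, 20), 2))$p.value)
})

test_that("dmr_call_pair finds planted regions, not identical groups", {
  # identical groups -> zero DMRs
  set.seed(12)
  sites <- data.table(chrom = "chr1", pos = seq(0, 5000, by = 100),
                      mc = rbinom(51, 40, 0.7), cov = 40L)
  expect_equal(nrow(dmr_call_pair(sites, sites)), 0)
  # planted hypo window with 12 dense sites
  a <- data.table(chrom = "chr1", pos = c(seq(0, 10000, by = 400),
                                          seq(20000, 21650, by = 150)),
                  cov = 40L)
  a[, mc := rbinom(.N, cov, 0.75)]
  b <- copy(a)
  inside <- b$pos >= 20000 & b$pos < 21800
  b[inside, mc := rbinom(sum(inside), cov, 0.35)]
  dmr <- dmr_call_pair(a, b, label = "early->late")
  expect_equal(nrow(dmr), 1)
  expect_equal(dmr$direction, "hypo")
  expect_gte(dmr$n_sites, 10)
  expect_gte(dmr$start, 19000)
  expect_lte(dmr$end, 22500)
  expect_gte(dmr$q, dmr$p)
  # direction labels always match the pooled fraction difference
  expect_true(all(ifelse(dmr$mc_b / dmr$cov_b < dmr$mc_a / dmr$cov_a,
                         "hypo", "hyper") == dmr$direction))
})

test_that("call_dmrs builds trajectory and branch comparisons", {
  set.seed(13)
  mk <- function(p_window) {
    dt <- data.table(chrom = "chr1", pos = seq(0, 2850, by = 150), cov = 60L)
    dt[, mc := rbinom(.N, cov, ifelse(pos < 1500, 0.75, p_window))]
    dt
  }
  pooled <- list(s1 = mk(0.75), s2 = mk(0.75), s3 = mk(0.30))
  tr <- call_dmrs(pooled, "trajectory")
  expect_true(all(tr$comparison %in% c("s1->s2", "s2->s3")))
  expect_true(any(tr$comparison == "s2->s3" & tr$direction == "hypo"))
  br <- call_dmrs(pooled, "branch", progenitor = "s1")
  expect_true(all(br$comparison %in% c("s1->s2", "s1->s3")))
  expect_error(call_dmrs(pooled, "branch"), "progenitor")
})
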