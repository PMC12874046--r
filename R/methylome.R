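# Per-cell and pseudobulk methylation statistics.

#' Global methylation levels of one cell
#'
#' Pooled fractions per context. The conversion-corrected mCH
#' `max(0, (mCH - mCCC) / (1 - mCCC))` is reported alongside the raw
#' value; mCCC at CCC trinucleotides estimates bisulfite non-conversion.
#' mCH pools all non-CpG sites (the CCC subset included); a context with
#' zero total coverage yields `NA`.
#'
#' @param cell methylation site table.
#' @return one-row `data.table` with mcg, mch, mccc, mch_corrected.
#' @export
global_levels <- function(cell) {
  dt <- as.data.table(cell)
  lv <- function(sel) {
    cv <- sum(dt$cov[sel])
    if (cv == 0) NA_real_ else sum(dt$mc[sel]) / cv
  }
  mcg <- lv(dt$context == "CG")
  mch <- lv(dt$context %chin% c("CH", "CCC"))
  mccc <- lv(dt$context == "CCC")
  corrected <- if (is.na(mch) || is.na(mccc) || mccc >= 1) NA_real_ else
    max(0, (mch - mccc) / (1 - mccc))
  data.table(mcg = mcg, mch = mch, mccc = mccc, mch_corrected = corrected)
}

#' Gene-body methylation matrix
#'
#' Pooled fraction `sum(mc)/sum(cov)` over each gene body per cell, for
#' one context. Genes with zero covered sites in a cell are `NA` (never
#' 0); the matching coverage matrix is returned so callers can mask.
#'
#' @param cells named list of methylation site tables.
#' @param genes region set of gene bodies.
#' @param context context class to pool (default "CG").
#' @return list with `frac` and `cov` matrices (genes x cells).
#' @export
gene_body_mc <- function(cells, genes, context = "CG") {
  genes <- region_set(genes)
  gv <- copy(genes)[, gid := .I]
  setkey(gv, chrom, start, end)
  ids <- names(cells)
  if (is.null(ids)) ids <- paste0("cell_", seq_along(cells))
  frac <- matrix(NA_real_, nrow(genes), length(cells),
                 dimnames = list(genes$name, ids))
  covm <- matrix(0, nrow(genes), length(cells),
                 dimnames = list(genes$name, ids))
  for (k in seq_along(cells)) {
    ctx <- context
    dt <- as.data.table(cells[[k]])[context == ctx]
    if (!nrow(dt)) next
    pts <- dt[, .(chrom, start = as.numeric(pos), end = as.numeric(pos) + 0.5,
                  mc, cov)]
    ov <- foverlaps(pts, gv[, .(chrom, start, end, gid)], nomatch = NULL)
    if (!nrow(ov)) next
    agg <- ov[, .(mc = sum(mc), cov = sum(cov)), by = gid]
    frac[agg$gid, k] <- agg$mc / agg$cov
    covm[agg$gid, k] <- agg$cov
  }
  list(frac = frac, cov = covm)
}

#' Normalize a gene methylation matrix by per-cell global levels
#'
#' Divides each cell's column by that cell's global methylation level in
#' the same context, removing per-cell global offsets; cells with a zero
#' or undefined global level become `NA`.
#'
#' @param mat genes x cells fraction matrix.
#' @param global_per_cell numeric vector of per-cell global levels,
#'   aligned with the matrix columns.
#' @return normalized matrix.
#' @export
normalized_gene_mc <- function(mat, global_per_cell) {
  if (length(global_per_cell) != ncol(mat))
    stop("one global level per cell column is required")
  g <- as.numeric(global_per_cell)
  g[!is.finite(g) | g == 0] <- NA_real_
  sweep(mat, 2, g, "/")
}

#' Cell-to-cell methylation distance
#'
#' `D(a, b) = sum(|f_a - f_b|)` over genes defined in both cells — the
#' total mCG change summed across genes. The number of shared defined
#' genes per pair is returned so distances are comparable; pairs with no
#' shared genes are `NA`.
#'
#' @param mat genes x cells fraction matrix.
#' @return list with `dist` (cells x cells) and `n_genes` matrices.
#' @export
cell_distance_matrix <- function(mat) {
  if (ncol(mat) < 2) stop("need at least 2 cells")
  nc <- ncol(mat)
  D <- matrix(0, nc, nc, dimnames = list(colnames(mat), colnames(mat)))
  N <- matrix(0L, nc, nc, dimnames = dimnames(D))
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    if (b < a) next
    ok <- !is.na(mat[, a]) & !is.na(mat[, b])
    N[a, b] <- N[b, a] <- sum(ok)
    D[a, b] <- D[b, a] <- if (any(ok)) sum(abs(mat[ok, a] - mat[ok, b])) else NA_real_
  }
  list(dist = D, n_genes = N)
}

#' Correlation between pseudobulk groups on scaled gene methylation
#'
#' Each gene (row) is z-scaled across groups; group pairs are then
#' Pearson-correlated. Constant gene vectors carry no information and are
#' dropped (their count is reported in a warning). The result is
#' invariant to gene order and per-gene affine rescaling.
#'
#' @param mat genes x groups matrix (complete rows used).
#' @return groups x groups correlation matrix (diagonal 1).
#' @export
group_correlation <- function(mat) {
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3) stop("need >= 3 genes defined across all groups")
  sds <- apply(mat, 1, sd)
  n_const <- sum(sds == 0)
  if (n_const > 0) {
    warning(n_const, " constant gene vector(s) dropped")
    mat <- mat[sds > 0, , drop = FALSE]
  }
  z <- t(scale(t(mat)))
  cor(z)
}

#' Percentage of signature genes hypomethylated in a region
#'
#' The headline percentage of a regional methylation signature, reported
#' to one decimal (e.g. 712 of 751 -> 94.8).
#'
#' @param n_hypo genes whose minimum methylation falls in the region.
#' @param n_total all signature genes.
#' @return percentage rounded to one decimal.
#' @export
signature_hypo_pct <- function(n_hypo, n_total) {
  round(100 * n_hypo / n_total, 1)
}

#' Regional methylation signature of a cell group
#'
#' Per-gene Kruskal-Wallis test of a region effect across pseudobulk
#' replicates (e.g. donors), BH-corrected. Significant genes are labeled
#' by the region of minimal methylation; the percentage of signature
#' genes hypomethylated in `target_region` is reported to one decimal.
#'
#' @param mat genes x replicates methylation matrix.
#' @param regions region label per replicate column.
#' @param target_region region whose hypomethylated share is headline.
#' @param fdr BH-FDR threshold (default 0.05).
#' @return list with `genes` (per-gene table), `counts` (signature genes
#'   per minimal region) and `pct_target`.
#' @export
regional_signature <- function(mat, regions, target_region, fdr = 0.05) {
  regions <- as.character(regions)
  if (length(regions) != ncol(mat))
    stop("one region label per replicate column is required")
  if (length(unique(regions)) < 2) stop("need >= 2 regions")
  if (any(table(regions) < 2))
    stop("need >= 2 replicates per region for a test")
  pvals <- apply(mat, 1, function(v) {
    ok <- !is.na(v)
    if (length(unique(regions[ok])) < 2 || sum(ok) < 3) return(NA_real_)
    suppressWarnings(kruskal.test(v[ok], factor(regions[ok]))$p.value)
  })
  qvals <- p.adjust(pvals, "BH")
  min_reg <- apply(mat, 1, function(v) {
    mns <- tapply(v, regions, mean, na.rm = TRUE)
    names(mns)[which.min(mns)]
  })
  genes <- data.table(gene = rownames(mat), p = pvals, q = qvals,
                      min_region = min_reg, sig = !is.na(qvals) & qvals < fdr)
  cnt <- genes[sig == TRUE, .N, by = min_region]
  n_total <- sum(cnt$N)
  n_hypo <- cnt[min_region == target_region, sum(N)]
  list(genes = genes[], counts = cnt[],
       pct_target = if (n_total > 0) signature_hypo_pct(n_hypo, n_total)
                    else NA_real_)
}

# vectorized two-sided Fisher exact p for 2x2 tables (a b / c d),
# matching stats::fisher.test's "probabilities <= observed" rule
.fisher_p2 <- function(a, b, c_, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + c_[i]          # first-group total (white balls)
    nn <- b[i] + d[i]          # second-group total
    k <- a[i] + b[i]           # methylated margin
    lo <- max(0L, k - nn); hi <- min(k, m)
    xs <- lo:hi
    probs <- dhyper(xs, m, nn, k)
    pobs <- dhyper(a[i], m, nn, k)
    out[i] <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }
  out
}

#' Call differentially methylated regions between two pooled groups
#'
#' Per-site two-sided Fisher exact test on (mc, cov - mc) between groups;
#' sites with `q < q_thresh` and `|delta fraction| >= min_delta` are
#' merged into regions when within `merge_gap` bp of each other with the
#' same direction and at least `min_sites` sites. Each region is then
#' re-scored by a Fisher test on its pooled counts and regions are
#' BH-corrected. Direction is the sign of the fraction change in group B
#' (the later stage or derived branch): "hypo" if B is lower.
#'
#' @param sites_a,sites_b pooled site tables (chrom, pos, mc, cov) for
#'   groups A (earlier/progenitor) and B (later/derived), aligned or not;
#'   sites are matched by (chrom, pos), unmatched sites are ignored.
#' @param label comparison label stored with each call.
#' @param q_thresh,min_delta,merge_gap,min_sites caller thresholds.
#' @return `data.table` of DMRecords (chrom, start, end, comparison,
#'   direction, n_sites, per-group pooled counts, p, q).
#' @export
dmr_call_pair <- function(sites_a, sites_b, label = "A_vs_B",
                          q_thresh = 0.05, min_delta = 0.1,
                          merge_gap = 250, min_sites = 2) {
  a <- as.data.table(sites_a)[, .(chrom, pos, mc_a = mc, cov_a = cov)]
  b <- as.data.table(sites_b)[, .(chrom, pos, mc_b = mc, cov_b = cov)]
  if (sum(a$cov_a) == 0 || sum(b$cov_b) == 0)
    stop("a group has zero coverage at all sites")
  m <- merge(a, b, by = c("chrom", "pos"))
  m <- m[cov_a > 0 & cov_b > 0]
  empty <- data.table(chrom = character(), start = numeric(), end = numeric(),
                      comparison = character(), direction = character(),
                      n_sites = integer(), mc_a = integer(), cov_a = integer(),
                      mc_b = integer(), cov_b = integer(),
                      p = numeric(), q = numeric())
  if (!nrow(m)) return(empty)
  setorder(m, chrom, pos)
  m[, p := .fisher_p2(mc_a, cov_a - mc_a, mc_b, cov_b - mc_b)]
  m[, q := p.adjust(p, "BH")]
  m[, delta := mc_b / cov_b - mc_a / cov_a]
  m[, sig := q < q_thresh & abs(delta) >= min_delta]
  s <- m[sig == TRUE]
  if (!nrow(s)) return(empty)
  setorder(s, chrom, pos)
  dirn <- ifelse(s$delta < 0, "hypo", "hyper")
  new_run <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                 diff(s$pos) > merge_gap |
                 dirn[-1] != dirn[-nrow(s)])
  s[, run_id := cumsum(new_run)]
  reg <- s[, .(chrom = chrom[1], start = as.numeric(min(pos)),
               end = as.numeric(max(pos)) + 1, n_sites = .N,
               mc_a = sum(mc_a), cov_a = sum(cov_a),
               mc_b = sum(mc_b), cov_b = sum(cov_b)),
           by = run_id]
  reg <- reg[n_sites >= min_sites]
  if (!nrow(reg)) return(empty)
  reg[, direction := ifelse(mc_b / cov_b < mc_a / cov_a, "hypo", "hyper")]
  reg[, p := .fisher_p2(mc_a, cov_a - mc_a, mc_b, cov_b - mc_b)]
  reg[, q := pmax(p, p.adjust(p, "BH"))]
  reg[, comparison := label]
  reg[, run_id := NULL]
  setcolorder(reg, c("chrom", "start", "end", "comparison", "direction",
                     "n_sites", "mc_a", "cov_a", "mc_b", "cov_b", "p", "q"))
  reg[]
}

#' Pool per-cell site counts into group pseudobulks
#'
#' @param cells named list of methylation site tables.
#' @param groups group label per cell (aligned with `cells`).
#' @param context context class to pool (default "CG").
#' @return named list of pooled site tables (chrom, pos, mc, cov).
#' @export
pool_sites <- function(cells, groups, context = "CG") {
  groups <- as.character(groups)
  stopifnot(length(groups) == length(cells))
  out <- list()
  for (g in unique(groups)) {
    ctx <- context
    dt <- rbindlist(lapply(cells[groups == g], function(x)
      as.data.table(x)[context == ctx, .(chrom, pos, mc, cov)]))
    out[[g]] <- dt[, .(mc = sum(mc), cov = sum(cov)), by = .(chrom, pos)]
  }
  out
}

#' Call trajectory- or branch-DMRs across a group structure
#'
#' Trajectory mode tests each pair of succeeding stages; branch mode
#' tests each derived group against the shared progenitor.
#'
#' @param pooled named list of pooled site tables (see [pool_sites()]).
#' @param mode "trajectory" (names in stage order) or "branch".
#' @param progenitor for branch mode, the progenitor group name.
#' @param ... thresholds passed to [dmr_call_pair()].
#' @return combined DMRecord table.
#' @export
call_dmrs <- function(pooled, mode = c("trajectory", "branch"),
                      progenitor = NULL, ...) {
  mode <- match.arg(mode)
  nms <- names(pooled)
  if (mode == "trajectory") {
    if (length(nms) < 2) stop("trajectory mode needs >= 2 stages")
    cmp <- data.table(a = nms[-length(nms)], b = nms[-1])
  } else {
    if (is.null(progenitor) || !progenitor %in% nms)
      stop("branch mode needs a progenitor group present in `pooled`")
    cmp <- data.table(a = progenitor, b = setdiff(nms, progenitor))
  }
  rbindlist(lapply(seq_len(nrow(cmp)), function(i)
    dmr_call_pair(pooled[[cmp$a[i]]], pooled[[cmp$b[i]]],
                  label = paste0(cmp$a[i], "->", cmp$b[i]), ...)))
}

#' Write DMR calls as BED plus a statistics sidecar TSV
#' @param dmrs DMRecord table.
#' @param prefix output path prefix (writes `<prefix>.bed`, `<prefix>.tsv`).
#' @export
write_dmrs <- function(dmrs, prefix) {
  dt <- as.data.table(dmrs)
  fwrite(dt[, .(chrom, start, end,
                name = paste0(comparison, "_", direction, "_", seq_len(.N)))],
         paste0(prefix, ".bed"), sep = "\t", col.names = FALSE)
  fwrite(dt, paste0(prefix, ".tsv"), sep = "\t")
  invisible(prefix)
}
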