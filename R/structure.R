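# Pseudobulk 3D-genome analyses on binned cis contact matrices.

#' Observed/expected distance normalization
#'
#' Expected counts at bin-distance d are the mean observed counts over
#' all unmasked bin pairs at that distance (masked bins are those with
#' zero marginal counts); O/E is observed divided by expected, `NA` where
#' expected is zero. Each O/E diagonal has mean 1 by construction.
#'
#' @param bm `binned_matrix` from [bin_contacts()].
#' @return the `binned_matrix` with `oe`, `expected` and `mask` filled.
#' @export
oe_normalize <- function(bm) {
  mat <- bm$mat
  n <- nrow(mat)
  if (n == 0 || sum(mat) == 0) stop("empty contact matrix")
  mask <- rowSums(mat) == 0
  keep <- which(!mask)
  expected <- rep(NA_real_, n)
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- !mask[i] & !mask[j]
    if (!any(ok)) next
    e <- mean(mat[cbind(i[ok], j[ok])])
    expected[d + 1] <- e
    if (e > 0) {
      v <- mat[cbind(i[ok], j[ok])] / e
      oe[cbind(i[ok], j[ok])] <- v
      oe[cbind(j[ok], i[ok])] <- v
    }
  }
  bm$oe <- oe
  bm$expected <- expected
  bm$mask <- mask
  bm
}

#' A/B compartment track from the leading eigenvector
#'
#' Pearson correlation matrix of the O/E columns over unmasked bins, then
#' the leading eigenvector, scaled to unit norm. The sign is oriented so
#' that positive values (the A compartment) have the lower mean
#' methylation covariate — or, with `orient = "density"`, the higher gene
#' density — since eigenvector sign is otherwise arbitrary.
#'
#' @param bm `binned_matrix` with O/E computed (see [oe_normalize()]).
#' @param covariate per-bin orientation covariate (mean pseudobulk mCG by
#'   default semantics, or gene density).
#' @param orient "mcg" (A = lower covariate) or "density" (A = higher).
#' @return `data.table` track: chrom, bin (0-based), start, end, pc1,
#'   masked.
#' @export
compartment_pc1 <- function(bm, covariate = NULL,
                            orient = c("mcg", "density")) {
  orient <- match.arg(orient)
  if (is.null(bm$oe)) bm <- oe_normalize(bm)
  keep <- which(!bm$mask)
  if (length(keep) < 10) stop("need >= 10 unmasked bins")
  sub <- bm$oe[keep, keep, drop = FALSE]
  suppressWarnings(C <- cor(sub, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  if (all(abs(C[upper.tri(C)]) < 1e-12))
    stop("no compartment signal (degenerate correlation matrix)")
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  if (!is.null(covariate)) {
    cv <- covariate[keep]
    ok <- is.finite(cv)
    if (sum(ok) >= 3 && sd(cv[ok]) > 0 && sd(v[ok]) > 0) {
      r <- cor(v[ok], cv[ok])
      flip <- if (orient == "mcg") r > 0 else r < 0
      if (isTRUE(flip)) v <- -v
    }
  }
  n <- nrow(bm$mat)
  pc1 <- rep(NA_real_, n)
  pc1[keep] <- v
  data.table(chrom = bm$chrom, bin = seq_len(n) - 1L,
             start = (seq_len(n) - 1) * bm$resolution,
             end = seq_len(n) * bm$resolution,
             pc1 = pc1, masked = bm$mask)
}

#' Compartment strength (saddle corner ratio)
#'
#' Bins are ranked by PC1 into `n_quantiles` quantiles; strength is the
#' mean O/E of same-compartment corner pairs (top-quantile AA plus
#' bottom-quantile BB) over twice the mean O/E of the AB corner, with
#' bin pairs closer than `min_sep` bins excluded. A label-free matrix
#' gives a strength near 1; stronger segregation gives larger values.
#'
#' @param bm `binned_matrix` with O/E.
#' @param track compartment track from [compartment_pc1()].
#' @param n_quantiles number of PC1 quantile bins (default 5).
#' @param min_sep minimum bin separation included (default 2).
#' @return scalar strength (`NA` when any saddle corner is empty).
#' @export
compartment_strength <- function(bm, track, n_quantiles = 5, min_sep = 2) {
  if (is.null(bm$oe)) bm <- oe_normalize(bm)
  tr <- as.data.table(track)
  ok <- which(!tr$masked & is.finite(tr$pc1))
  qs <- cut(rank(tr$pc1[ok], ties.method = "first"),
            breaks = n_quantiles, labels = FALSE)
  top <- ok[qs == n_quantiles]
  bot <- ok[qs == 1]
  corner_mean <- function(rows, cols) {
    idx <- expand.grid(i = rows, j = cols)
    idx <- idx[abs(idx$i - idx$j) >= min_sep, ]
    if (!nrow(idx)) return(NA_real_)
    mean(bm$oe[cbind(idx$i, idx$j)], na.rm = TRUE)
  }
  aa <- corner_mean(top, top)
  bb <- corner_mean(bot, bot)
  ab <- corner_mean(top, bot)
  if (!is.finite(aa) || !is.finite(bb) || !is.finite(ab) || ab == 0)
    return(NA_real_)
  (aa + bb) / (2 * ab)
}

#' Detect compartment switches between two tracks
#'
#' Bins with opposite PC1 signs and `|delta PC1| >= min_delta`, merged
#' into runs of consecutive bins.
#'
#' @param track_a,track_b compartment tracks on identical bins.
#' @param min_delta minimum |PC1 difference| (default 0.05).
#' @return `data.table` of switch runs: chrom, start, end, n_bins,
#'   direction ("A->B" means A-compartment in track_a, B in track_b).
#' @export
compartment_switches <- function(track_a, track_b, min_delta = 0.05) {
  a <- as.data.table(track_a)
  b <- as.data.table(track_b)
  if (nrow(a) != nrow(b) || any(a$bin != b$bin) || a$chrom[1] != b$chrom[1])
    stop("tracks must cover identical bins")
  sw <- which(is.finite(a$pc1) & is.finite(b$pc1) &
                sign(a$pc1) != sign(b$pc1) & sign(a$pc1) != 0 &
                abs(a$pc1 - b$pc1) >= min_delta)
  if (!length(sw))
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), direction = character()))
  runs <- cumsum(c(TRUE, diff(sw) != 1))
  rbindlist(lapply(split(sw, runs), function(ii) {
    data.table(chrom = a$chrom[1], start = a$start[ii[1]],
               end = a$end[ii[length(ii)]], n_bins = length(ii),
               direction = if (a$pc1[ii[1]] > 0) "A->B" else "B->A")
  }))
}

#' Variance partitioning of compartment scores across design factors
#'
#' Per-bin sequential (type I) sum-of-squares decomposition of the
#' compartment score over the factor means, averaged genome-wide; the
#' reported fractions (one per factor plus residual) sum to 1.
#' Single-level factors are dropped with a warning.
#'
#' @param scores bins x groups matrix of compartment scores.
#' @param factors data.frame of design factors, one row per group column.
#' @return named numeric vector of average variance fractions.
#' @export
variance_partition <- function(scores, factors) {
  factors <- as.data.frame(factors)
  if (nrow(factors) != ncol(scores))
    stop("one factor row per score column is required")
  keep <- vapply(factors, function(f) length(unique(f)) > 1, logical(1))
  if (any(!keep))
    warning("dropping single-level factor(s): ",
            paste(names(factors)[!keep], collapse = ", "))
  factors <- factors[, keep, drop = FALSE]
  if (!ncol(factors)) stop("no factor with >= 2 levels")
  factors[] <- lapply(factors, factor)
  fml <- as.formula(paste("y ~", paste(names(factors), collapse = " + ")))
  terms_out <- c(names(factors), "Residuals")
  acc <- setNames(numeric(length(terms_out)), terms_out)
  n_used <- 0L
  for (i in seq_len(nrow(scores))) {
    y <- scores[i, ]
    if (anyNA(y) || sd(y) == 0) next
    # only the sums of squares are used; the F-tests (unreliable on
    # near-perfect fits) are discarded
    av <- suppressWarnings(anova(lm(fml, data = cbind(y = y, factors))))
    ss <- av$`Sum Sq`
    names(ss) <- rownames(av)
    tot <- sum(ss)
    if (tot == 0) next
    acc[names(ss)] <- acc[names(ss)] + ss / tot
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no informative bins")
  fr <- acc / n_used
  names(fr)[names(fr) == "Residuals"] <- "residual"
  fr
}

#' Insulation score track (diamond convention)
#'
#' For each bin, the mean contact count in the w x w diamond spanning the
#' bin (upstream rows x downstream columns); the score is
#' `log2(diamond mean / chromosome-wide mean of diamond means)`. Bins
#' within `w` of either edge are masked. Local minima of this track mark
#' domain boundaries.
#'
#' @param bm `binned_matrix` (25-kb resolution by convention).
#' @param window diamond window in bp (default 100 kb).
#' @return `data.table` track: chrom, bin, start, end, diamond,
#'   insulation, valid.
#' @export
insulation_score <- function(bm, window = 1e5) {
  w <- as.integer(round(window / bm$resolution))
  n <- nrow(bm$mat)
  if (n < 3 * w) stop("chromosome shorter than 3 windows at this resolution")
  diamond <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    diamond[i] <- mean(bm$mat[(i - w):(i - 1), (i + 1):(i + w)])
  }
  valid <- is.finite(diamond)
  gm <- mean(diamond[valid])
  ins <- rep(NA_real_, n)
  if (gm > 0) ins[valid] <- log2(pmax(diamond[valid], 1e-9) / gm)
  data.table(chrom = bm$chrom, bin = seq_len(n) - 1L,
             start = (seq_len(n) - 1) * bm$resolution,
             end = seq_len(n) * bm$resolution,
             diamond = diamond, insulation = ins, valid = valid & gm > 0)
}

# topographic prominence of a local minimum at index i
.min_prominence <- function(x, i) {
  left_max <- -Inf
  j <- i - 1
  while (j >= 1 && x[j] >= x[i]) {
    left_max <- max(left_max, x[j]); j <- j - 1
  }
  right_max <- -Inf
  j <- i + 1
  while (j <= length(x) && x[j] >= x[i]) {
    right_max <- max(right_max, x[j]); j <- j + 1
  }
  min(left_max, right_max) - x[i]
}

#' Call domain boundaries from an insulation track
#'
#' Boundaries are local insulation minima with topographic prominence at
#' least `min_depth` (log2 units); plateau ties break to the leftmost
#' bin. For sparse pseudobulks the track can be smoothed with a running
#' mean over `smooth_bins` bins before minima detection, which suppresses
#' shot-noise minima; `smooth_bins = 1` (the default) leaves the track
#' untouched.
#'
#' @param track insulation track from [insulation_score()].
#' @param min_depth minimum prominence (default 0.5).
#' @param smooth_bins odd width of the running-mean smoother (default 1,
#'   i.e. no smoothing).
#' @return `data.table`: chrom, bin, start, end, insulation, prominence.
#' @export
call_boundaries <- function(track, min_depth = 0.5, smooth_bins = 1) {
  tr <- as.data.table(track)
  x <- tr$insulation
  x[!tr$valid] <- NA_real_
  if (smooth_bins > 1) {
    h <- (smooth_bins - 1) %/% 2
    x <- vapply(seq_along(x), function(i) {
      win <- x[max(1, i - h):min(length(x), i + h)]
      if (all(!is.finite(win))) NA_real_ else mean(win, na.rm = TRUE)
    }, numeric(1))
    x[!tr$valid] <- NA_real_
  }
  idx <- which(vapply(seq_along(x), function(i) {
    if (!is.finite(x[i]) || i == 1 || i == length(x)) return(FALSE)
    if (!is.finite(x[i - 1]) || !is.finite(x[i + 1])) return(FALSE)
    x[i] < x[i - 1] && x[i] <= x[i + 1]
  }, logical(1)))
  if (!length(idx))
    return(tr[0, .(chrom, bin, start, end, insulation)][, prominence := numeric(0)][])
  xs <- x
  xs[!is.finite(xs)] <- Inf  # masked edges act as walls
  prom <- vapply(idx, function(i) .min_prominence(xs, i), numeric(1))
  keep <- prom >= min_depth
  out <- tr[idx[keep], .(chrom, bin, start, end, insulation)]
  out[, prominence := prom[keep]]
  out[]
}

#' Bootstrap boundary probability per bin
#'
#' Cells are resampled with replacement within the group `B` times; each
#' bootstrap pseudobulk is binned, its insulation computed and boundaries
#' called. A bin's probability is the fraction of replicates in which a
#' boundary is called within one bin of it. Fixed seed; cells are
#' processed in name order so the result is invariant to input order.
#'
#' @param cells named list of contact tables (one group).
#' @param genome `genome_spec`.
#' @param chrom chromosome analysed.
#' @param resolution bin size (default 25 kb).
#' @param window insulation window in bp.
#' @param min_depth boundary prominence threshold.
#' @param smooth_bins smoothing width passed to [call_boundaries()].
#' @param B bootstrap replicates (default 50; at least 20 required).
#' @param min_cells minimum cells in the group (default 5).
#' @param seed RNG seed.
#' @return list with `prob` (per-bin probability), `calls` (B x bins
#'   logical matrix of smeared calls), `track` template, `B`.
#' @export
boundary_probability <- function(cells, genome, chrom, resolution = 25e3,
                                 window = 1e5, min_depth = 0.5,
                                 smooth_bins = 1, B = 50,
                                 min_cells = 5, seed = 1) {
  if (B < 20) stop("need >= 20 bootstrap replicates")
  if (length(cells) < min_cells)
    stop("group has fewer than ", min_cells, " cells")
  if (!is.null(names(cells))) cells <- cells[order(names(cells))]
  set.seed(seed)
  n_bins <- as.integer(ceiling(genome$lengths[[chrom]] / resolution))
  calls <- matrix(FALSE, B, n_bins)
  for (b in seq_len(B)) {
    take <- sample(length(cells), length(cells), replace = TRUE)
    bulk <- pool_contacts(cells[take])
    bm <- bin_contacts(bulk, resolution, chrom, genome)
    tr <- insulation_score(bm, window)
    bd <- call_boundaries(tr, min_depth, smooth_bins)
    if (nrow(bd)) {
      hit <- unique(pmin(pmax(rep(bd$bin + 1L, each = 3) + (-1:1), 1L), n_bins))
      calls[b, hit] <- TRUE
    }
  }
  list(prob = colMeans(calls), calls = calls, chrom = chrom,
       resolution = resolution, B = B)
}

#' Age-differential domain boundaries
#'
#' For each candidate bin (called in at least one replicate of either
#' group), a two-sided Fisher exact test compares boundary-call counts
#' across the two groups' bootstrap replicates; BH-FDR across candidates.
#' The sign of the probability change labels each hit "gain" (higher in
#' group B) or "loss". Swapping the groups flips every label.
#'
#' @param bp_a,bp_b results of [boundary_probability()] with equal `B`.
#' @param fdr BH-FDR threshold (default 0.05).
#' @return `data.table`: bin, start, prob_a, prob_b, p, q, direction,
#'   significant.
#' @export
differential_boundaries <- function(bp_a, bp_b, fdr = 0.05) {
  if (bp_a$B != bp_b$B) stop("groups must use equal bootstrap replicates")
  if (ncol(bp_a$calls) != ncol(bp_b$calls)) stop("bin grids differ")
  B <- bp_a$B
  k_a <- colSums(bp_a$calls)
  k_b <- colSums(bp_b$calls)
  cand <- which(k_a + k_b > 0)
  if (!length(cand))
    return(data.table(bin = integer(), start = numeric(), prob_a = numeric(),
                      prob_b = numeric(), p = numeric(), q = numeric(),
                      direction = character(), significant = logical()))
  p <- .fisher_p2(k_a[cand], B - k_a[cand], k_b[cand], B - k_b[cand])
  out <- data.table(bin = cand - 1L,
                    start = (cand - 1) * bp_a$resolution,
                    prob_a = k_a[cand] / B, prob_b = k_b[cand] / B,
                    p = p, q = p.adjust(p, "BH"))
  out[, direction := ifelse(prob_b > prob_a, "gain",
                            ifelse(prob_b < prob_a, "loss", "none"))]
  out[, significant := q < fdr & direction != "none"]
  out[]
}

#' Call chromatin loops with a donut local background
#'
#' Candidate pixels (anchors at least `min_sep` bins apart, observed
#' count at least `min_obs`) are tested against a local expected count:
#' the median of the donut annulus around the pixel (offsets with
#' Chebyshev radius in (inner, outer], anchor row/column excluded).
#' Poisson upper-tail p-value, BH-FDR.
#'
#' @param bm `binned_matrix` (10-kb resolution by convention).
#' @param min_obs minimum observed count for a candidate (default 5).
#' @param inner,outer donut radii in bins (defaults 2 and 5).
#' @param min_sep minimum anchor separation in bins (default 2).
#' @param fdr BH-FDR threshold.
#' @return `data.table`: bin1, bin2, obs, expected, enrich, p, q,
#'   significant.
#' @export
call_loops <- function(bm, min_obs = 5, inner = 2, outer = 5, min_sep = 2,
                       fdr = 0.05) {
  mat <- bm$mat
  n <- nrow(mat)
  cand <- which(upper.tri(mat) & mat >= min_obs, arr.ind = TRUE)
  cand <- cand[cand[, 2] - cand[, 1] >= min_sep, , drop = FALSE]
  empty <- data.table(bin1 = integer(), bin2 = integer(), obs = numeric(),
                      expected = numeric(), enrich = numeric(),
                      p = numeric(), q = numeric(), significant = logical())
  if (!nrow(cand)) return(empty)
  off <- expand.grid(di = -outer:outer, dj = -outer:outer)
  cheb <- pmax(abs(off$di), abs(off$dj))
  off <- off[cheb > inner & cheb <= outer & off$di != 0 & off$dj != 0, ]
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    ii <- i + off$di; jj <- j + off$dj
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & jj - ii >= 1
    if (!any(ok)) return(NULL)
    e <- median(mat[cbind(ii[ok], jj[ok])])
    data.table(bin1 = i - 1L, bin2 = j - 1L, obs = mat[i, j], expected = e)
  })
  out <- rbindlist(rows)
  if (!nrow(out)) return(empty)
  out[, p := ppois(obs - 1, expected, lower.tail = FALSE)]
  out[, enrich := ifelse(expected > 0, obs / expected, Inf)]
  out[, q := p.adjust(p, "BH")]
  out[, significant := q < fdr & enrich > 1]
  setcolorder(out, c("bin1", "bin2", "obs", "expected", "enrich", "p", "q",
                     "significant"))
  out[]
}

#' Differential looping between two pseudobulk groups
#'
#' For each loop, a Fisher exact test on (loop count, remaining cis
#' count) between the groups; BH-FDR; direction "gain" when the loop's
#' cis-normalized count is higher in group B.
#'
#' @param bm_a,bm_b `binned_matrix` pseudobulks of the two groups.
#' @param loops table with bin1, bin2 (0-based) of loops to test,
#'   typically a union of [call_loops()] calls.
#' @param fdr BH-FDR threshold.
#' @return `data.table` with counts, p, q, direction, significant.
#' @export
differential_loops <- function(bm_a, bm_b, loops, fdr = 0.05) {
  lp <- as.data.table(loops)
  tot_a <- bm_a$n_contacts
  tot_b <- bm_b$n_contacts
  ka <- bm_a$mat[cbind(lp$bin1 + 1L, lp$bin2 + 1L)]
  kb <- bm_b$mat[cbind(lp$bin1 + 1L, lp$bin2 + 1L)]
  p <- .fisher_p2(ka, tot_a - ka, kb, tot_b - kb)
  out <- data.table(bin1 = lp$bin1, bin2 = lp$bin2,
                    obs_a = ka, total_a = tot_a, obs_b = kb, total_b = tot_b,
                    p = p, q = p.adjust(p, "BH"))
  out[, direction := ifelse(kb / tot_b > ka / tot_a, "gain",
                            ifelse(kb / tot_b < ka / tot_a, "loss", "none"))]
  out[, significant := q < fdr & direction != "none"]
  out[]
}

#' Write a per-bin track as bedGraph
#' @param track table with chrom, start, end and a value column.
#' @param value name of the value column.
#' @param path output path.
#' @export
write_bedgraph <- function(track, value, path) {
  dt <- as.data.table(track)
  out <- dt[is.finite(dt[[value]]), .(chrom, start, end)]
  out[, value := dt[[value]][is.finite(dt[[value]])]]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
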