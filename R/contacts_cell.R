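# Per-cell contact statistics: distance decay, SE/LE state, QC ratios,
# and the 3C gene score.

.cis_separations <- function(contacts) {
  dt <- as.data.table(contacts)[chrom1 == chrom2]
  abs(dt$pos2 - dt$pos1)
}

#' Shared log-spaced distance bin edges
#'
#' @param min_bp,max_bp range of cis separations covered.
#' @param n_bins number of bins.
#' @return numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
decay_bins <- function(min_bp = 1e3, max_bp = 1e8, n_bins = 30) {
  exp(seq(log(min_bp), log(max_bp), length.out = n_bins + 1))
}

#' Per-cell contact distance-decay profile
#'
#' Cis separations histogrammed over shared log-spaced bins and
#' normalized by the cell's total cis contacts across bins, so profiles
#' are comparable between cells of different depth.
#'
#' @param cell contact table.
#' @param bins bin edges (strictly increasing), e.g. [decay_bins()].
#' @return list with `fraction` (sums to 1), `count` per bin, and
#'   `defined` (FALSE when the cell has no cis contact in range).
#' @export
decay_profile <- function(cell, bins = decay_bins()) {
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
  s <- .cis_separations(cell)
  s <- s[s >= bins[1] & s < bins[length(bins)]]
  counts <- if (length(s))
    tabulate(findInterval(s, bins), nbins = length(bins) - 1)
  else rep(0L, length(bins) - 1)
  tot <- sum(counts)
  list(fraction = if (tot > 0) counts / tot else rep(NA_real_, length(counts)),
       count = counts, defined = tot > 0)
}

#' Per-cell short/long-range contact ratio
#'
#' `r = log2(n_short / n_long)` with `n_short` the cis contacts at
#' separations in the short-range band [200 kb, 2 Mb) and `n_long` in the
#' long-range band [20 Mb, 100 Mb), both half-open on raw bp separations.
#' The ratio is flagged undefined when either band holds fewer than
#' `min_count` contacts (shallow cells give unstable log ratios).
#'
#' @param cell contact table (blocklist-filtered).
#' @param short_band,long_band band edges in bp.
#' @param min_count minimum contacts per band (default 50).
#' @return one-row `data.table`: n_short, n_long, ratio, defined.
#' @export
sle_ratio <- function(cell, short_band = c(2e5, 2e6),
                      long_band = c(2e7, 1e8), min_count = 50) {
  s <- .cis_separations(cell)
  n_short <- sum(s >= short_band[1] & s < short_band[2])
  n_long <- sum(s >= long_band[1] & s < long_band[2])
  defined <- n_short >= min_count && n_long >= min_count
  data.table(n_short = n_short, n_long = n_long,
             ratio = if (defined) log2(n_short / n_long) else NA_real_,
             defined = defined)
}

# two-component 1-D Gaussian mixture via EM, k-means initialized
.em_gmm2 <- function(x, max_iter = 200, tol = 1e-8, seed = 1) {
  set.seed(seed)
  km <- kmeans(x, centers = 2, nstart = 5)
  mu <- as.numeric(km$centers)
  pi1 <- mean(km$cluster == 1)
  sg <- rep(max(sd(x) / 2, 1e-3), 2)
  w <- c(pi1, 1 - pi1)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sg <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                 sum((1 - g1) * (x - mu[2])^2) / n2))
    if (any(sg < 1e-6)) return(NULL)  # degenerate component
    w <- c(n1, n2) / length(x)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sg, w = w, gamma1 = g1)
}

#' Classify cells into SE / LE conformation states
#'
#' Fits a two-component Gaussian mixture to the cohort's per-cell
#' log2(short/long) ratios (EM, k-means initialization, fixed seed); the
#' component with the larger mean is SE. States are assigned by maximum
#' posterior, so assignments agree with the Bayes rule under the fitted
#' mixture by construction. Bimodality is summarized as the separation
#' `|mu_SE - mu_LE| / pooled sd`; values below `bimodal_min` flag an
#' effectively unimodal cohort. EM degeneracy (a vanishing variance)
#' falls back to a median split with a warning.
#'
#' @param ratios numeric vector of per-cell ratios (NAs allowed; those
#'   cells stay unclassified).
#' @param min_cells minimum defined ratios required (default 50).
#' @param bimodal_min separation below which bimodality is not claimed.
#' @param seed RNG seed for initialization.
#' @return list with `states` ("SE"/"LE"/NA per cell), `posterior_se`,
#'   `mu`, `sigma`, `weights`, `separation`, `bimodal`, `method`.
#' @export
classify_sle <- function(ratios, min_cells = 50, bimodal_min = 2, seed = 1) {
  ok <- which(is.finite(ratios))
  if (length(ok) < min_cells)
    stop("need >= ", min_cells, " cells with a defined ratio")
  x <- ratios[ok]
  fit <- .em_gmm2(x, seed = seed)
  states <- rep(NA_character_, length(ratios))
  post <- rep(NA_real_, length(ratios))
  if (is.null(fit)) {
    warning("EM degenerated; falling back to median split")
    med <- median(x)
    states[ok] <- ifelse(x > med, "SE", "LE")
    post[ok] <- as.numeric(x > med)
    return(list(states = states, posterior_se = post,
                mu = c(SE = NA, LE = NA), sigma = c(NA, NA),
                weights = c(NA, NA), separation = NA_real_,
                bimodal = FALSE, method = "median_split"))
  }
  se_comp <- which.max(fit$mu)
  p_se <- if (se_comp == 1) fit$gamma1 else 1 - fit$gamma1
  pooled_sd <- sqrt(sum(fit$w * fit$sigma^2))
  separation <- abs(diff(fit$mu)) / pooled_sd
  states[ok] <- ifelse(p_se >= 0.5, "SE", "LE")
  post[ok] <- p_se
  list(states = states, posterior_se = post,
       mu = c(SE = fit$mu[se_comp], LE = fit$mu[3 - se_comp]),
       sigma = c(SE = fit$sigma[se_comp], LE = fit$sigma[3 - se_comp]),
       weights = c(SE = fit$w[se_comp], LE = fit$w[3 - se_comp]),
       separation = separation, bimodal = separation >= bimodal_min,
       method = "gmm")
}

#' Per-cell intra/inter-chromosomal contact ratio
#'
#' @param cell contact table.
#' @return one-row `data.table`: n_intra, n_inter, ratio (`NA` when the
#'   cell has no interchromosomal contact — never infinity).
#' @export
intra_inter_ratio <- function(cell) {
  dt <- as.data.table(cell)
  n_intra <- sum(dt$chrom1 == dt$chrom2)
  n_inter <- nrow(dt) - n_intra
  data.table(n_intra = n_intra, n_inter = n_inter,
             ratio = if (n_inter > 0) n_intra / n_inter else NA_real_)
}

#' Cohort summary of the intra/inter ratio
#'
#' Reports both the ratio of means (mean intra / mean inter across cells)
#' and the mean of per-cell ratios; the two differ for heterogeneous
#' cohorts, so both are stated.
#'
#' @param n_intra,n_inter per-cell counts.
#' @return one-row `data.table` with ratio_of_means, mean_of_ratios.
#' @export
intra_inter_summary <- function(n_intra, n_inter) {
  ok <- n_inter > 0
  data.table(ratio_of_means = mean(n_intra) / mean(n_inter),
             mean_of_ratios = mean(n_intra[ok] / n_inter[ok]))
}

#' 3C gene score: chromatin interaction within gene bodies
#'
#' For each gene, the raw score counts cis contacts with both endpoints
#' inside the gene body (half-open; an `endpoint_rule = "any"` switch
#' counts contacts with at least one endpoint inside). Scores are
#' depth-normalized per cell to contacts per 100,000 cis contacts, and a
#' per-kb length normalization is emitted alongside since either
#' convention is in use.
#'
#' @param cell contact table.
#' @param genes region set of gene bodies.
#' @param endpoint_rule "both" (default, stricter) or "any".
#' @return `data.table` per gene: raw, per100k, per100k_kb.
#' @export
gene_3cgs <- function(cell, genes, endpoint_rule = c("both", "any")) {
  endpoint_rule <- match.arg(endpoint_rule)
  genes <- region_set(genes)
  dt <- as.data.table(cell)[chrom1 == chrom2]
  n_cis <- nrow(dt)
  gv <- copy(genes)[, gid := .I]
  setkey(gv, chrom, start, end)
  count_in <- function(chrom, pos) {
    # gene index per endpoint (NA when outside every gene)
    pts <- data.table(chrom = chrom, start = as.numeric(pos),
                      end = as.numeric(pos) + 0.5)
    ov <- foverlaps(pts, gv[, .(chrom, start, end, gid)], which = TRUE,
                    nomatch = NA, mult = "first")
    gv$gid[ov]
  }
  raw <- integer(nrow(genes))
  if (n_cis > 0) {
    g1 <- count_in(dt$chrom1, dt$pos1)
    g2 <- count_in(dt$chrom2, dt$pos2)
    hits <- if (endpoint_rule == "both") {
      ok <- !is.na(g1) & !is.na(g2) & g1 == g2
      g1[ok]
    } else {
      c(g1[!is.na(g1)], g2[!is.na(g2) & (is.na(g1) | g1 != g2)])
    }
    if (length(hits)) {
      tab <- tabulate(hits, nbins = nrow(genes))
      raw <- tab
    }
  }
  kb <- (genes$end - genes$start) / 1e3
  data.table(gene = genes$name, raw = raw,
             per100k = if (n_cis > 0) raw * 1e5 / n_cis else NA_real_,
             per100k_kb = if (n_cis > 0) raw * 1e5 / n_cis / kb else NA_real_)
}
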