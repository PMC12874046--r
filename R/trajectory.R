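# Modality feature spaces, diffusion pseudotime, maturation-lag and
# composition statistics.

#' Build a per-modality feature space
#'
#' mCG: 100-kb-bin CpG methylation fractions per cell, undefined bins
#' imputed by the feature mean (the imputation count is reported). 3C:
#' the cell's distance-decay profile concatenated with per-chromosome-arm
#' endpoint fractions. Joint: the z-scaled concatenation of both. Cells
#' with fewer than `min_defined` of features defined are dropped with a
#' log entry.
#'
#' @param cells named list of per-cell records with `$meth` and/or
#'   `$contacts` (as produced by [simulate_cohort()]).
#' @param modality "mcg", "3c" or "joint".
#' @param genome `genome_spec`.
#' @param bin_size methylation feature bin in bp (default 100 kb).
#' @param bins decay bin edges for the 3C modality.
#' @param min_defined minimum fraction of defined features per cell.
#' @return list with `X` (cells x features), `imputed` (count),
#'   `dropped` (cell ids), `modality`.
#' @export
build_features <- function(cells, modality = c("mcg", "3c", "joint"),
                           genome, bin_size = 1e5, bins = decay_bins(),
                           min_defined = 0.2) {
  modality <- match.arg(modality)
  if (modality == "joint") {
    a <- build_features(cells, "mcg", genome, bin_size, bins, min_defined)
    b <- build_features(cells, "3c", genome, bin_size, bins, min_defined)
    keep <- intersect(rownames(a$X), rownames(b$X))
    zs <- function(m) {
      m <- scale(m)
      m[, apply(is.finite(m), 2, all), drop = FALSE]
    }
    return(list(X = cbind(zs(a$X[keep, , drop = FALSE]),
                          zs(b$X[keep, , drop = FALSE])),
                imputed = a$imputed + b$imputed,
                dropped = union(a$dropped, b$dropped), modality = "joint"))
  }
  ids <- names(cells)
  if (modality == "mcg") {
    offs <- c(0, cumsum(ceiling(genome$lengths / bin_size)))
    names(offs) <- c(genome$chroms, "..total")
    n_feat <- offs[["..total"]]
    X <- matrix(NA_real_, length(cells), n_feat,
                dimnames = list(ids, paste0("bin", seq_len(n_feat))))
    for (k in seq_along(cells)) {
      dt <- as.data.table(cells[[k]]$meth)[context == "CG"]
      if (!nrow(dt)) next
      fi <- offs[dt$chrom] + dt$pos %/% bin_size + 1
      agg <- data.table(fi = fi, mc = dt$mc, cov = dt$cov)[
        , .(frac = sum(mc) / sum(cov)), by = fi]
      X[k, agg$fi] <- agg$frac
    }
  } else {
    n_dec <- length(bins) - 1
    arm_names <- as.vector(outer(c("p", "q"), genome$chroms,
                                 function(a, b) paste0(b, "_", a)))
    X <- matrix(NA_real_, length(cells), n_dec + length(arm_names),
                dimnames = list(ids, c(paste0("decay", seq_len(n_dec)),
                                       arm_names)))
    for (k in seq_along(cells)) {
      ct <- cells[[k]]$contacts
      dp <- decay_profile(ct, bins)
      if (dp$defined) X[k, seq_len(n_dec)] <- dp$fraction
      dt <- as.data.table(ct)
      ep <- data.table(chrom = c(dt$chrom1, dt$chrom2),
                       pos = c(dt$pos1, dt$pos2))
      if (nrow(ep)) {
        half <- genome$lengths[ep$chrom] / 2
        arm <- paste0(ep$chrom, "_", ifelse(ep$pos < half, "p", "q"))
        tab <- table(factor(arm, levels = arm_names))
        X[k, arm_names] <- as.numeric(tab) / sum(tab)
      }
    }
  }
  defined <- rowMeans(!is.na(X))
  dropped <- ids[defined < min_defined]
  if (length(dropped))
    message(length(dropped), " cell(s) dropped (<",
            round(100 * min_defined), "% features defined)")
  X <- X[defined >= min_defined, , drop = FALSE]
  n_imp <- sum(is.na(X))
  if (n_imp > 0) {
    mns <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0))
      X[is.na(X[, j]), j] <- mns[j]
  }
  X <- X[, apply(X, 2, function(v) all(is.finite(v))), drop = FALSE]
  list(X = X, imputed = n_imp, dropped = dropped, modality = modality)
}

#' Pseudotime from a root group
#'
#' PCA to at most `n_pc` components, then a kNN graph on the (optionally
#' kNN-denoised) PC scores. The default `"geodesic"` score is the graph
#' shortest-path (arc-length) distance from the root group's medoid —
#' approximately linear in progression along the trajectory, which makes
#' scores comparable between modalities (the property [modality_lag()]
#' relies on). The `"diffusion"` alternative is classical diffusion
#' pseudotime (local Gaussian kernel, spectral decomposition of the
#' normalized transition operator, components weighted by
#' lambda/(1-lambda)); it orders cells equally well but its distances
#' compress across stage bottlenecks, so it is kept for exploration
#' rather than cross-modality comparison. Scores are min-max scaled to
#' [0, 1]; the root medoid scores 0. A disconnected kNN graph is an
#' error naming the component sizes, never silently bridged.
#'
#' @param X cells x features matrix (see [build_features()]).
#' @param root_ids cell ids (rownames of `X`) of the root group.
#' @param n_pc number of PCA components (default 20).
#' @param k kNN neighborhood size (default 15).
#' @param method "geodesic" (default) or "diffusion".
#' @param denoise_k neighbors averaged to denoise PC coordinates before
#'   the graph is built (default 8; 1 disables). Shot noise in sparse
#'   single-cell features otherwise inflates early path lengths.
#' @param n_dc diffusion components used when `method = "diffusion"`.
#' @param seed RNG seed (the procedure is deterministic; the seed guards
#'   any downstream stochastic consumer).
#' @return `data.table`: cell_id, score; attribute `root_medoid`.
#' @export
pseudotime <- function(X, root_ids, n_pc = 20, k = 15,
                       method = c("geodesic", "diffusion"),
                       denoise_k = 8, n_dc = 10, seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  root_ids <- intersect(root_ids, rownames(X))
  if (length(root_ids) < 5) stop("root group needs >= 5 cells present")
  n <- nrow(X)
  k <- min(k, n - 1)
  pc <- prcomp(X, rank. = min(n_pc, ncol(X), n - 1), center = TRUE,
               scale. = FALSE)$x
  if (denoise_k > 1) {
    dk <- min(denoise_k, n)
    D0 <- as.matrix(dist(pc))
    nn0 <- t(apply(D0, 1, function(d) order(d)[seq_len(dk)]))
    pc <- t(vapply(seq_len(n), function(i)
      colMeans(pc[nn0[i, ], , drop = FALSE]), numeric(ncol(pc))))
    rownames(pc) <- rownames(X)
  }
  D <- as.matrix(dist(pc))
  nn <- t(apply(D, 1, function(d) order(d)[2:(k + 1)]))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) A[i, nn[i, ]] <- TRUE
  A <- A | t(A)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    A, mode = "undirected"))
  if (comp$no > 1)
    stop("kNN graph is disconnected: ", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "))
  ri <- match(root_ids, rownames(X))
  med <- ri[which.min(rowSums(as.matrix(dist(pc[ri, , drop = FALSE]))))]
  if (method == "geodesic") {
    g <- igraph::graph_from_adjacency_matrix(D * A, mode = "undirected",
                                             weighted = TRUE)
    sc <- as.numeric(igraph::distances(g, v = med))
  } else {
    sigma <- D[cbind(seq_len(n), nn[, k])]
    sigma[sigma <= 0] <- min(D[D > 0])
    W <- matrix(0, n, n)
    W[A] <- exp(-D[A]^2 / (sigma[row(A)[A]] * sigma[col(A)[A]]))
    dg <- rowSums(W)
    S <- W / sqrt(dg %o% dg)
    eg <- eigen(S, symmetric = TRUE)
    n_dc <- min(n_dc, n - 1)
    lam <- pmin(eg$values[2:(n_dc + 1)], 1 - 1e-9)
    psi <- eg$vectors[, 2:(n_dc + 1), drop = FALSE] / sqrt(dg)
    coords <- sweep(psi, 2, lam / (1 - lam), "*")
    sc <- sqrt(rowSums(sweep(coords, 2, coords[med, ], "-")^2))
  }
  sc <- (sc - min(sc)) / max(sc - min(sc))
  out <- data.table(cell_id = rownames(X), score = sc)
  setattr(out, "root_medoid", rownames(X)[med])
  out[]
}

#' Maturation lag between 3C and mCG pseudotime
#'
#' Per age group, the median pseudotime of each modality. Each modality's
#' median-vs-age curve is anchored so its first-age median maps to 0 and
#' its last-age median to 1 (a pseudotime score carries no absolute
#' scale; anchoring removes per-modality offsets while preserving
#' mid-course ordering). The lag statistic is the signed area between the
#' anchored curves (3C minus mCG summed over age groups at unit spacing),
#' positive when the chromatin conformation landscape matures ahead of
#' the methylome. Age groups with fewer than `min_cells` cells are
#' excluded.
#'
#' @param scores table with cell_id, age_group (ordered factor or
#'   character in chronological order), pt_mcg, pt_3c.
#' @param ages age-group ordering (defaults to factor levels or order of
#'   appearance).
#' @param min_cells minimum cells per age group (default 10).
#' @return list with `by_age` (raw and anchored medians per age), `lag`
#'   (anchored signed area) and `lag_raw` (unanchored).
#' @export
modality_lag <- function(scores, ages = NULL, min_cells = 10) {
  dt <- as.data.table(scores)
  if (is.null(ages))
    ages <- if (is.factor(dt$age_group)) levels(dt$age_group)
            else unique(dt$age_group)
  dt <- dt[age_group %in% ages]
  by_age <- dt[, .(n = .N, med_mcg = median(pt_mcg), med_3c = median(pt_3c)),
               by = age_group]
  by_age <- by_age[n >= min_cells]
  by_age[, age_group := factor(age_group, levels = ages)]
  setorder(by_age, age_group)
  anchor <- function(v) {
    span <- v[length(v)] - v[1]
    if (length(v) < 2 || span == 0) return(v - v[1])
    (v - v[1]) / span
  }
  by_age[, `:=`(anch_mcg = anchor(med_mcg), anch_3c = anchor(med_3c))]
  list(by_age = by_age[],
       lag = sum(by_age$anch_3c - by_age$anch_mcg),
       lag_raw = sum(by_age$med_3c - by_age$med_mcg))
}

#' Fraction of immature neurons per lineage and age
#'
#' @param meta cell metadata with lineage, age_group and state columns.
#' @param immature_states state labels counted as immature.
#' @param lineage_col,age_col,state_col column names.
#' @return `data.table`: lineage, age_group, n, n_immature, fraction
#'   (`NA` on a zero denominator).
#' @export
immature_fraction <- function(meta, immature_states, lineage_col = "lineage",
                              age_col = "age_group", state_col = "state") {
  dt <- as.data.table(meta)
  out <- dt[, .(n = .N,
                n_immature = sum(get(state_col) %in% immature_states)),
            by = c(lineage_col, age_col)]
  out[, fraction := ifelse(n > 0, n_immature / n, NA_real_)]
  out[]
}

#' Composition enrichment of a state across strata
#'
#' Per stratum, a two-sided Fisher exact test on the 2x2 table of
#' (target state vs rest) x (stratum vs rest), with the sample odds
#' ratio, BH-corrected across strata. Strata with an empty margin are
#' skipped with a note.
#'
#' @param meta cell metadata.
#' @param state_col column holding the state labels.
#' @param target_state state tested for enrichment.
#' @param strat_col stratifying column (e.g. region).
#' @param fdr BH-FDR threshold.
#' @return `data.table`: stratum, counts, odds_ratio, p, q, significant.
#' @export
composition_enrichment <- function(meta, state_col, target_state, strat_col,
                                   fdr = 0.05) {
  dt <- as.data.table(meta)
  in_state <- dt[[state_col]] == target_state
  strata <- sort(unique(as.character(dt[[strat_col]])))
  rows <- lapply(strata, function(s) {
    in_s <- dt[[strat_col]] == s
    a <- sum(in_state & in_s); b <- sum(in_state & !in_s)
    c_ <- sum(!in_state & in_s); d <- sum(!in_state & !in_s)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
      message("stratum ", s, " skipped (empty margin)")
      return(NULL)
    }
    data.table(stratum = s, n_state_in = a, n_state_out = b,
               n_other_in = c_, n_other_out = d,
               odds_ratio = (a * d) / (b * c_),
               p = .fisher_p2(a, b, c_, d))
  })
  out <- rbindlist(rows)
  if (!nrow(out)) return(out)
  out[, q := p.adjust(p, "BH")]
  out[, significant := q < fdr]
  out[]
}
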