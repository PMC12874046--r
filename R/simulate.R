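# Synthetic joint methylome + 3C cohort generator.
#
# Every sampled quantity is driven by a per-cell maturation score m in
# [0, 1]: global mCH (neurons only), the short-range mixture weight of the
# contact decay, and the methylation of planted trajectory genes all
# interpolate between stage endpoints as m advances, so the cohort forms a
# continuous trajectory with a known ordering.

.SIM_AGES <- c("2T", "3T", "1mo", "4-7mo", "adult")

#' Default simulated genome
#'
#' Three chromosomes of 60, 40 and 20 Mb. The largest two are long enough
#' to carry contacts in the 20-100 Mb long-range band.
#' @return a `genome_spec`.
#' @export
sim_genome <- function() {
  genome_spec(c(chr1 = 60e6, chr2 = 40e6, chr3 = 20e6))
}

.sim_state <- function(name, lineage, neuronal, immature, root, ages, n,
                       w_se = c(0.25, 0.55), lag_3c = 0,
                       region_str = 0.5) {
  list(name = name, lineage = lineage, neuronal = neuronal,
       immature = immature, root = root, ages = ages, n = n,
       w_se = w_se, lag_3c = lag_3c, region_str = region_str)
}

.default_states <- function() {
  list(
    .sim_state("eMSN", "MSN", TRUE,  TRUE,  TRUE,  "2T", 20,
               w_se = c(0.25, 0.55), region_str = 0.9),
    .sim_state("MSN",  "MSN", TRUE,  FALSE, FALSE, .SIM_AGES, 12,
               w_se = c(0.25, 0.55), region_str = 0.9),
    .sim_state("eINT", "INT", TRUE,  TRUE,  TRUE,  "2T", 20,
               w_se = c(0.25, 0.55), lag_3c = 0.25, region_str = 0.2),
    .sim_state("INT",  "INT", TRUE,  FALSE, FALSE, .SIM_AGES, 12,
               w_se = c(0.25, 0.55), lag_3c = 0.25, region_str = 0.2),
    .sim_state("OPC",  "ODC", FALSE, FALSE, TRUE,  .SIM_AGES, 10,
               w_se = c(0.15, 0.15), region_str = 0.5),
    .sim_state("ODC",  "ODC", FALSE, FALSE, FALSE, .SIM_AGES, 10,
               w_se = c(0.15, 0.15), region_str = 0.5),
    .sim_state("tOPC", "ODC", FALSE, FALSE, FALSE, "1mo", 20,
               w_se = c(0.55, 0.55), region_str = 0.5),
    .sim_state("tODC", "ODC", FALSE, FALSE, FALSE, "1mo", 20,
               w_se = c(0.55, 0.55), region_str = 0.8)
  )
}

# evenly spaced 100-kb gene bodies; chr1 genes carry the maturation
# gradient, chr2 genes are state-specific markers
.sim_genes <- function(genome, n_per_chrom = 30, gene_len = 1e5,
                       states = .default_states()) {
  gs <- rbindlist(lapply(genome$chroms, function(ch) {
    L <- genome$lengths[[ch]]
    spacing <- floor(L / n_per_chrom)
    data.table(chrom = ch,
               start = as.numeric((seq_len(n_per_chrom) - 1L) * spacing),
               end = as.numeric((seq_len(n_per_chrom) - 1L) * spacing + gene_len),
               name = sprintf("%s_g%02d", ch, seq_len(n_per_chrom)))
  }))
  gs[, `:=`(traj_dir = 0, traj_scale = 0, active_state = NA_character_)]
  # the neuronal maturation program: most genes outside the marker
  # chromosome remodel with maturation, half losing and half gaining
  # mCG, with graded effect sizes (as in real developing neurons, where
  # gene-body remodeling is pervasive rather than confined to a few loci)
  for (ch in c("chr1", "chr3")) {
    idx <- which(gs$chrom == ch)
    half <- length(idx) %/% 2
    gs$traj_dir[idx[seq_len(half)]] <- -1
    gs$traj_dir[idx[(half + 1):length(idx)]] <- 1
    gs$traj_scale[idx] <- rep_len(seq(0.4, 1, length.out = 5), length(idx))
  }
  # state markers: 3 chr2 genes per state, demethylated + contact-boosted
  idx2 <- which(gs$chrom == "chr2")
  nm <- vapply(states, `[[`, "", "name")
  for (k in seq_along(nm)) {
    take <- idx2[((k - 1) * 3 + 1):((k - 1) * 3 + 3)]
    take <- take[!is.na(take)]
    gs$active_state[take] <- nm[k]
  }
  gs[]
}

# planted DMRs live in chr1 intergenic space (genes occupy the first
# 100 kb of each 2-Mb slot there)
.sim_dmrs <- function(dmr_len = 1800) {
  traj <- data.table(chrom = "chr1",
                     start = seq(1e6, by = 2e6, length.out = 12),
                     kind = "trajectory", lineage = "MSN", from_age = "3T",
                     state = NA_character_,
                     delta = rep(c(-0.4, 0.2), c(8, 4)))
  branch <- data.table(chrom = "chr1",
                       start = seq(27e6, by = 2e6, length.out = 6),
                       kind = "branch", lineage = "INT", from_age = NA_character_,
                       state = "INT", delta = -0.4)
  dmrs <- rbind(traj, branch)
  dmrs[, end := start + dmr_len]
  dmrs[, name := sprintf("dmr_%02d", seq_len(.N))]
  dmrs[]
}

# stage-specific TAD boundaries: a base set every 2 Mb plus extras that
# appear from 3T onward (the age-DB truth)
.sim_boundaries <- function(genome, ages = .SIM_AGES) {
  base <- lapply(genome$chroms, function(ch) {
    L <- genome$lengths[[ch]]
    seq(2e6, L - 1.5e6, by = 2e6)
  })
  names(base) <- genome$chroms
  # age-specific boundaries sit mid-way through a plaid block so they are
  # not confounded with the (weakly insulating) compartment block edges
  extra <- list(chr1 = 31.5e6, chr3 = 11.5e6)
  out <- lapply(ages, function(a) {
    b <- base
    if (match(a, ages) >= 2) {
      for (ch in names(extra)) b[[ch]] <- sort(c(b[[ch]], extra[[ch]]))
    }
    b
  })
  names(out) <- ages
  out
}

# chromatin loops: 5 early anchor pairs, 10 more gained from 1mo onward
.sim_loops <- function(ages = .SIM_AGES) {
  a <- 1e6 + (0:14) * 1.2e6
  all_loops <- data.table(chrom = "chr3", pos1 = a, pos2 = a + 5e5)
  out <- lapply(ages, function(ag) {
    if (match(ag, ages) >= 3) all_loops else all_loops[1:5]
  })
  names(out) <- ages
  out
}

#' Build a simulation configuration
#'
#' Defaults describe the emulated study conditions: ~300 cells across five
#' age groups (2T < 3T < 1mo < 4-7mo < adult), 50,000 contacts per cell
#' with an interchromosomal fraction of 1/3 (intra/inter ratio 2), a
#' two-component cis-distance mixture (log-uniform short-range band
#' 200 kb-2 Mb vs power law), a 1-Mb compartment plaid, stage-specific TAD
#' boundaries and loops, neuronal mCH accumulating with maturation, and
#' planted trajectory/branch DMRs. All sizes and effect magnitudes are
#' overridable for scaled-down experiments.
#'
#' @param seed integer master seed; per-cell substreams are derived from
#'   it by counter so outputs are reproducible and order-independent.
#' @param genome `genome_spec` (default [sim_genome()]).
#' @param states list of state descriptors (default emulates MSN and
#'   interneuron neuronal lineages plus an OPC/ODC glial lineage with
#'   transitional SE states).
#' @param n_scale multiplier on per-state cell counts (for small runs).
#' @param contacts_per_cell contacts drawn per cell.
#' @param f_inter interchromosomal contact fraction.
#' @param alpha power-law decay exponent of the long-range cis component.
#' @param se_band,le_band short-/long-range bands in bp (half-open).
#' @param plaid_block compartment block size in bp.
#' @param comp_c_neuron,comp_c_glia per-age within-compartment enrichment
#'   factors (plaid contrast) for neuronal and glial lineages.
#' @param tad_penalty multiplicative acceptance penalty for cis contacts
#'   crossing a TAD boundary at separations below `tad_range`.
#' @param tad_range separation below which the TAD penalty applies (bp).
#' @param p_loop,p_active per-contact probability of re-assignment to a
#'   planted loop / an active-gene body.
#' @param mcg_global baseline CpG methylation fraction.
#' @param mch_range neuronal global mCH at maturation 0 and 1.
#' @param mch_glia flat glial mCH level.
#' @param conversion_error bisulfite non-conversion rate (CCC sites).
#' @param comp_mcg_delta extra CpG methylation in B-compartment blocks
#'   (anchors compartment orientation to the methylome).
#' @param cov_lambda mean of the shifted-Poisson site coverage (>= 1).
#' @param cg_spacing,ch_spacing,ccc_spacing background site grid spacing
#'   in bp per context.
#' @param dmr_site_spacing CG site spacing inside planted DMR intervals.
#' @param active_delta methylation offset of a state's marker genes.
#' @param traj_loss,traj_gain methylation slopes (per unit maturation) of
#'   the losing/gaining trajectory genes.
#' @param m_noise s.d. of per-cell maturation noise around the stage mean.
#' @param dmrs planted DMR table (chrom, start, end, kind, lineage,
#'   from_age, state, delta); `NULL` for the default set, a zero-row
#'   table to plant none (e.g. for experiments that need a purely
#'   continuous methylome trajectory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = sim_genome(),
                       states = .default_states(),
                       dmrs = NULL,
                       n_scale = 1,
                       contacts_per_cell = 50000L,
                       f_inter = 1 / 3,
                       alpha = 1.0,
                       se_band = c(2e5, 2e6),
                       le_band = c(2e7, 1e8),
                       plaid_block = 1e6,
                       comp_c_neuron = c(2.0, 1.5, 1.4, 1.3, 1.3),
                       comp_c_glia = c(1.2, 1.35, 1.5, 1.65, 1.8),
                       tad_penalty = 0.4,
                       tad_range = 3e6,
                       p_loop = 0.01,
                       p_active = 0.02,
                       mcg_global = 0.75,
                       mch_range = c(0.01, 0.06),
                       mch_glia = 0.01,
                       conversion_error = 0.005,
                       comp_mcg_delta = 0.04,
                       cov_lambda = 2,
                       cg_spacing = 2000,
                       ch_spacing = 4000,
                       ccc_spacing = 20000,
                       dmr_site_spacing = 150,
                       active_delta = -0.35,
                       traj_loss = -0.45,
                       traj_gain = 0.20,
                       m_noise = 0.06) {
  ages <- .SIM_AGES
  genes <- .sim_genes(genome, states = states)
  if (is.null(dmrs)) dmrs <- .sim_dmrs()
  dmrs <- as.data.table(dmrs)
  cfg <- structure(list(
    seed = as.integer(seed), genome = genome, ages = ages, states = states,
    n_scale = n_scale, contacts_per_cell = as.integer(contacts_per_cell),
    f_inter = f_inter, alpha = alpha, se_band = se_band, le_band = le_band,
    plaid_block = plaid_block,
    comp_c_neuron = setNames(comp_c_neuron, ages),
    comp_c_glia = setNames(comp_c_glia, ages),
    tad_penalty = tad_penalty, tad_range = tad_range,
    p_loop = p_loop, p_active = p_active,
    mcg_global = mcg_global, mch_range = mch_range, mch_glia = mch_glia,
    conversion_error = conversion_error, comp_mcg_delta = comp_mcg_delta,
    cov_lambda = cov_lambda,
    cg_spacing = cg_spacing, ch_spacing = ch_spacing,
    ccc_spacing = ccc_spacing, dmr_site_spacing = dmr_site_spacing,
    active_delta = active_delta, traj_loss = traj_loss,
    traj_gain = traj_gain, m_noise = m_noise,
    genes = genes, dmrs = dmrs,
    boundaries = .sim_boundaries(genome, ages),
    loops = .sim_loops(ages),
    switch_region = list(chrom = "chr2", blocks = 10:13, from_age = "1mo")
  ), class = "sim_config")
  cfg$sites <- .site_grid(cfg)
  validate_sim_config(cfg)
  cfg
}

# background site grid + dense CG sites inside planted DMRs, annotated
# with gene / DMR / compartment-block membership
.site_grid <- function(cfg) {
  g <- cfg$genome
  grid_one <- function(ch) {
    L <- g$lengths[[ch]]
    cg <- seq(500, L - 1, by = cfg$cg_spacing)
    ch_ <- seq(1500, L - 1, by = cfg$ch_spacing)
    ccc <- seq(2500, L - 1, by = cfg$ccc_spacing)
    data.table(chrom = ch,
               pos = c(cg, ch_, ccc),
               context = rep(c("CG", "CH", "CCC"),
                             c(length(cg), length(ch_), length(ccc))))
  }
  sites <- rbindlist(lapply(g$chroms, grid_one))
  if (nrow(cfg$dmrs)) {
    dmr_sites <- cfg$dmrs[, .(pos = seq(start[1], end[1] - 1,
                                        by = cfg$dmr_site_spacing),
                              context = "CG"),
                          by = .(name, chrom)][, .(chrom, pos, context)]
    sites <- rbind(sites, dmr_sites)
  }
  sites <- unique(sites, by = c("chrom", "pos", "context"))
  setorder(sites, chrom, pos)
  sites[, strand := "+"]
  # gene membership
  sites[, gene_id := NA_integer_]
  gv <- copy(cfg$genes)[, gid := .I]
  setkey(gv, chrom, start, end)
  pts <- sites[, .(chrom, start = as.numeric(pos), end = as.numeric(pos) + 0.5)]
  ov <- foverlaps(pts, gv[, .(chrom, start, end, gid)], which = TRUE, nomatch = NA)
  ok <- !is.na(ov$yid)
  sites$gene_id[ov$xid[ok]] <- gv$gid[ov$yid[ok]]
  # DMR membership
  sites[, dmr_id := NA_integer_]
  dv <- copy(cfg$dmrs)[, did := .I]
  setkey(dv, chrom, start, end)
  ov <- foverlaps(pts, dv[, .(chrom, start, end, did)], which = TRUE, nomatch = NA)
  ok <- !is.na(ov$yid)
  sites$dmr_id[ov$xid[ok]] <- dv$did[ov$yid[ok]]
  sites[, block := as.integer(pos %/% cfg$plaid_block)]
  sites[]
}

#' Compartment plaid labels for one chromosome at one age
#'
#' Blocks alternate A/B; the planted switch region flips label from its
#' onset age onward.
#'
#' @param cfg `sim_config`.
#' @param chrom chromosome name.
#' @param age age-group name.
#' @return character vector of "A"/"B" per plaid block.
#' @export
plaid_labels <- function(cfg, chrom, age) {
  n_blocks <- as.integer(ceiling(cfg$genome$lengths[[chrom]] / cfg$plaid_block))
  lab <- rep(c("A", "B"), length.out = n_blocks)
  sw <- cfg$switch_region
  if (!is.null(sw) && chrom == sw$chrom &&
      match(age, cfg$ages) >= match(sw$from_age, cfg$ages)) {
    i <- sw$blocks + 1L
    lab[i] <- ifelse(lab[i] == "A", "B", "A")
  }
  lab
}

.state_lookup <- function(cfg, state) {
  nm <- vapply(cfg$states, `[[`, "", "name")
  i <- match(state, nm)
  if (is.na(i)) stop("unknown simulated state: ", state)
  cfg$states[[i]]
}

# per-site success probability for one cell; errors here are caught at
# config validation by probing the extremes
.site_probs <- function(cfg, state, age, m_mcg) {
  st <- .state_lookup(cfg, state)
  s <- cfg$sites
  p <- numeric(nrow(s))
  is_cg <- s$context == "CG"
  p[is_cg] <- cfg$mcg_global
  mch <- if (st$neuronal)
    cfg$mch_range[1] + diff(cfg$mch_range) * m_mcg else cfg$mch_glia
  p[s$context == "CH"] <- mch
  p[s$context == "CCC"] <- cfg$conversion_error
  # B-compartment offset (CG only)
  for (ch in cfg$genome$chroms) {
    lab <- plaid_labels(cfg, ch, age)
    sel <- is_cg & s$chrom == ch
    p[sel] <- p[sel] + cfg$comp_mcg_delta * (lab[s$block[sel] + 1L] == "B")
  }
  # gene offsets: trajectory slope by maturation (the neuronal
  # maturation program; glia do not share it) + state-marker delta
  goff <- numeric(nrow(cfg$genes))
  if (st$neuronal) {
    loss <- cfg$genes$traj_dir == -1
    gain <- cfg$genes$traj_dir == 1
    goff[loss] <- cfg$traj_loss * cfg$genes$traj_scale[loss] * m_mcg
    goff[gain] <- cfg$traj_gain * cfg$genes$traj_scale[gain] * m_mcg
  }
  act_gene <- !is.na(cfg$genes$active_state) & cfg$genes$active_state == state
  goff[act_gene] <- goff[act_gene] + cfg$active_delta
  hasg <- is_cg & !is.na(s$gene_id)
  p[hasg] <- p[hasg] + goff[s$gene_id[hasg]]
  # planted DMR deltas for cells in the DMR's target group
  act <- .dmr_active(cfg, state, age)
  hasd <- which(is_cg & !is.na(s$dmr_id))
  hasd <- hasd[act[s$dmr_id[hasd]]]
  p[hasd] <- p[hasd] + cfg$dmrs$delta[s$dmr_id[hasd]]
  p
}

# which planted DMRs are "on" for a cell of this state/age
.dmr_active <- function(cfg, state, age) {
  st <- .state_lookup(cfg, state)
  d <- cfg$dmrs
  traj <- d$kind == "trajectory" & d$lineage == st$lineage &
    !is.na(d$from_age) &
    match(age, cfg$ages) >= match(d$from_age, cfg$ages)
  branch <- d$kind == "branch" & !is.na(d$state) & d$state == state
  traj | branch
}

#' Validate a simulation configuration
#'
#' Checks probability bounds at the maturation extremes of every state and
#' age, and that every planted object lies within the genome.
#'
#' @param cfg `sim_config`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$f_inter >= 0, cfg$f_inter <= 1,
            cfg$conversion_error >= 0, cfg$conversion_error <= 1,
            cfg$contacts_per_cell > 0, cfg$cov_lambda >= 1)
  for (st in cfg$states) {
    if (any(st$w_se < 0 | st$w_se > 1))
      stop("w_se out of [0,1] for state ", st$name)
    for (age in intersect(st$ages, cfg$ages)) {
      for (m in c(0, 1)) {
        p <- .site_probs(cfg, st$name, age, m)
        if (any(p < 0 | p > 1))
          stop("site probability outside [0,1] for state ", st$name,
               ", age ", age, ", m = ", m,
               " (check planted deltas and offsets)")
      }
    }
  }
  planted <- rbind(cfg$dmrs[, .(chrom, start, end)],
                   cfg$genes[, .(chrom, start, end)])
  if (any(planted$start < 0) ||
      any(planted$end > cfg$genome$lengths[planted$chrom]))
    stop("planted interval outside genome bounds")
  invisible(TRUE)
}

.cell_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1000003 + counter * 7919) %% 2147483647)
}

#' Simulate one cell's methylome
#'
#' Site-level counts on the cohort site grid: `mc ~ Binomial(cov, p)` with
#' p set by context (global mCG, maturation-interpolated mCH for neurons,
#' the conversion error for CCC) and modified by compartment, gene-body
#' and planted-DMR effects; `cov` is shifted Poisson (>= 1).
#'
#' @param cfg `sim_config`.
#' @param state simulated state name.
#' @param age age-group name.
#' @param m maturation score in [0,1]; defaults to the stage midpoint.
#' @param seed optional integer substream seed.
#' @return a methylation site table.
#' @export
simulate_methylome_cell <- function(cfg, state, age, m = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m)) m <- (match(age, cfg$ages) - 1) / (length(cfg$ages) - 1)
  p <- .site_probs(cfg, state, age, m)
  n <- length(p)
  cov <- 1L + rpois(n, cfg$cov_lambda - 1)
  mc <- rbinom(n, cov, p)
  meth_site_table(data.table(chrom = cfg$sites$chrom, pos = cfg$sites$pos,
                             strand = cfg$sites$strand,
                             context = cfg$sites$context,
                             mc = mc, cov = cov))
}

.rpower <- function(n, alpha, a, b) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-9) return(exp(log(a) + u * (log(b) - log(a))))
  e <- 1 - alpha
  (u * (b^e - a^e) + a^e)^(1 / e)
}

.crosses_boundary <- function(chrom, posA, posB, bnds) {
  out <- rep(FALSE, length(posA))
  for (ch in unique(chrom)) {
    b <- bnds[[ch]]
    if (is.null(b) || !length(b)) next
    sel <- chrom == ch
    out[sel] <- findInterval(posB[sel], b) > findInterval(posA[sel], b)
  }
  out
}

#' Simulate one cell's chromatin contacts
#'
#' Contacts are interchromosomal with probability `f_inter` (uniform
#' endpoints on two distinct chromosomes, length-weighted); otherwise the
#' cis separation comes from a two-component mixture (log-uniform
#' short-range band with weight `w_se`, else power law). Endpoint placement
#' respects the compartment plaid (cross-label contacts thinned by the
#' age-specific contrast), TAD boundaries (cross-boundary short contacts
#' thinned by `tad_penalty`), planted loops and active-gene bodies.
#'
#' @inheritParams simulate_methylome_cell
#' @param n number of contacts; defaults to `cfg$contacts_per_cell`.
#' @return a contact table.
#' @export
simulate_contacts_cell <- function(cfg, state, age, m = NULL, seed = NULL,
                                   n = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m)) m <- (match(age, cfg$ages) - 1) / (length(cfg$ages) - 1)
  if (is.null(n)) n <- cfg$contacts_per_cell
  if (n <= 0) stop("number of contacts must be positive")
  st <- .state_lookup(cfg, state)
  w_se <- st$w_se[1] + diff(st$w_se) * min(max(m, 0), 1)
  g <- cfg$genome
  lens <- g$lengths
  comp_c <- if (st$neuronal) cfg$comp_c_neuron[[age]] else cfg$comp_c_glia[[age]]
  bnds <- cfg$boundaries[[age]]

  n_inter <- rbinom(1, n, cfg$f_inter)
  n_cis <- n - n_inter

  # interchromosomal: endpoints uniform on two distinct chroms
  inter <- NULL
  if (n_inter > 0) {
    c1 <- sample(g$chroms, n_inter, replace = TRUE, prob = lens)
    c2 <- sample(g$chroms, n_inter, replace = TRUE, prob = lens)
    while (any(same <- c1 == c2))
      c2[same] <- sample(g$chroms, sum(same), replace = TRUE, prob = lens)
    inter <- data.table(chrom1 = c1, pos1 = floor(runif(n_inter, 0, lens[c1])),
                        chrom2 = c2, pos2 = floor(runif(n_inter, 0, lens[c2])))
  }

  # cis: rejection sampling against plaid + TAD acceptance weights
  acc <- vector("list", 0)
  got <- 0L
  plaid_cache <- lapply(g$chroms, function(ch) plaid_labels(cfg, ch, age))
  names(plaid_cache) <- g$chroms
  while (got < n_cis) {
    mdraw <- as.integer(ceiling((n_cis - got) * 2.2) + 64L)
    ch <- sample(g$chroms, mdraw, replace = TRUE, prob = lens)
    L <- lens[ch]
    se <- runif(mdraw) < w_se
    s <- numeric(mdraw)
    if (any(se))
      s[se] <- exp(runif(sum(se), log(cfg$se_band[1]), log(cfg$se_band[2])))
    if (any(!se))
      s[!se] <- .rpower(sum(!se), cfg$alpha, 1e3, L[!se])
    posA <- floor(runif(mdraw, 0, L - s))
    posB <- posA + floor(s)
    w <- rep(1, mdraw)
    bA <- as.integer(posA %/% cfg$plaid_block) + 1L
    bB <- as.integer(posB %/% cfg$plaid_block) + 1L
    lab_same <- logical(mdraw)
    for (cc in unique(ch)) {
      sel <- ch == cc
      labs <- plaid_cache[[cc]]
      lab_same[sel] <- labs[bA[sel]] == labs[bB[sel]]
    }
    w[!lab_same] <- w[!lab_same] / comp_c
    cross <- s < cfg$tad_range & .crosses_boundary(ch, posA, posB, bnds)
    w[cross] <- w[cross] * cfg$tad_penalty
    keep <- runif(mdraw) < w
    kept <- data.table(chrom1 = ch[keep], pos1 = posA[keep],
                       chrom2 = ch[keep], pos2 = posB[keep])
    acc[[length(acc) + 1L]] <- kept
    got <- got + nrow(kept)
  }
  cis <- if (n_cis > 0) rbindlist(acc)[seq_len(n_cis)] else
    data.table(chrom1 = character(), pos1 = numeric(),
               chrom2 = character(), pos2 = numeric())

  # re-assign a slice of cis contacts to planted loops / active genes
  u <- runif(n_cis)
  loops <- cfg$loops[[age]]
  li <- which(u < cfg$p_loop)
  if (length(li) && nrow(loops)) {
    pick <- sample(nrow(loops), length(li), replace = TRUE)
    cis[li, `:=`(chrom1 = loops$chrom[pick],
                 pos1 = floor(loops$pos1[pick] + runif(length(li), 0, 1e4)),
                 chrom2 = loops$chrom[pick],
                 pos2 = floor(loops$pos2[pick] + runif(length(li), 0, 1e4)))]
  }
  agenes <- cfg$genes[!is.na(active_state) & active_state == state]
  gi <- which(u >= cfg$p_loop & u < cfg$p_loop + cfg$p_active)
  if (length(gi) && nrow(agenes)) {
    pick <- sample(nrow(agenes), length(gi), replace = TRUE)
    p1 <- floor(runif(length(gi), agenes$start[pick], agenes$end[pick]))
    p2 <- floor(runif(length(gi), agenes$start[pick], agenes$end[pick]))
    cis[gi, `:=`(chrom1 = agenes$chrom[pick], pos1 = p1,
                 chrom2 = agenes$chrom[pick], pos2 = p2)]
  }
  contact_table(rbind(cis, inter), g)
}

#' Simulate a full cohort with ground truth
#'
#' @param cfg `sim_config`.
#' @param modalities which per-cell modalities to generate (both by
#'   default; generating only one halves the cost of targeted tests).
#' @return list with `cells` (named list; each element has `$meth` and/or
#'   `$contacts`), `meta` (cell metadata table with donor, age group,
#'   region and L1/L2/L3 labels) and `truth` (per-cell maturation scores
#'   and contact parameters plus the planted DMR/boundary/loop objects).
#' @export
simulate_cohort <- function(cfg, modalities = c("meth", "contacts")) {
  modalities <- match.arg(modalities, c("meth", "contacts"), several.ok = TRUE)
  set.seed(cfg$seed)
  rows <- list()
  for (st in cfg$states) {
    for (age in intersect(cfg$ages, st$ages)) {
      n <- max(1L, as.integer(round(st$n * cfg$n_scale)))
      rows[[length(rows) + 1L]] <-
        data.table(state = st$name, lineage = st$lineage, age_group = age,
                   neuronal = st$neuronal, immature = st$immature,
                   root = st$root, n = n, lag_3c = st$lag_3c,
                   region_str = st$region_str)
    }
  }
  plan <- rbindlist(rows)
  meta <- plan[rep(seq_len(.N), n)]
  meta[, cell_id := sprintf("cell_%04d", seq_len(.N))]
  meta[, donor_id := rep_len(c("donor1", "donor2"), .N)]
  age_idx <- match(meta$age_group, cfg$ages)
  m_base <- (age_idx - 1) / (length(cfg$ages) - 1)
  m <- pmin(pmax(m_base + rnorm(nrow(meta), 0, cfg$m_noise), 0), 1)
  meta[, region := ifelse(runif(.N) < region_str, "STR", "CTX")]
  truth_cells <- data.table(cell_id = meta$cell_id, state = meta$state,
                            m = m,
                            m_mcg = m,
                            m_3c = pmin(pmax(m + meta$lag_3c, 0), 1))
  st_by_cell <- meta$state
  cells <- vector("list", nrow(meta))
  names(cells) <- meta$cell_id
  for (i in seq_len(nrow(meta))) {
    cell <- list()
    if ("meth" %in% modalities)
      cell$meth <- simulate_methylome_cell(
        cfg, st_by_cell[i], meta$age_group[i], m = truth_cells$m_mcg[i],
        seed = .cell_seed(cfg$seed, 2L * i))
    if ("contacts" %in% modalities)
      cell$contacts <- simulate_contacts_cell(
        cfg, st_by_cell[i], meta$age_group[i], m = truth_cells$m_3c[i],
        seed = .cell_seed(cfg$seed, 2L * i + 1L))
    cells[[i]] <- cell
  }
  st_w <- lapply(cfg$states, function(s) s$w_se)
  names(st_w) <- vapply(cfg$states, `[[`, "", "name")
  truth_cells[, w_se := vapply(seq_len(.N), function(i) {
    w <- st_w[[state[i]]]
    w[1] + diff(w) * m_3c[i]
  }, numeric(1))]
  meta_out <- meta[, .(cell_id, donor_id, age_group, region,
                       L1 = ifelse(neuronal, "Inh", "Glial"),
                       L2 = state, L3 = paste0(state, ":", age_group),
                       lineage, state, immature)]
  list(cells = cells, meta = meta_out,
       truth = list(cells = truth_cells, dmrs = copy(cfg$dmrs),
                    boundaries = cfg$boundaries, loops = cfg$loops,
                    switch_region = cfg$switch_region))
}

#' Write a simulated cohort to disk
#'
#' Emits `meta.tsv`, per-cell allc and pairs files under `allc/` and
#' `pairs/`, the genome as `chrom.sizes`, gene bodies as `genes.bed`, and
#' the truth tables as a `truth_*.tsv` set.
#'
#' @param cohort result of [simulate_cohort()].
#' @param cfg the `sim_config` used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, cfg, dir) {
  dir.create(file.path(dir, "allc"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pairs"), recursive = TRUE, showWarnings = FALSE)
  fwrite(cohort$meta, file.path(dir, "meta.tsv"), sep = "\t")
  write_chrom_sizes(cfg$genome, file.path(dir, "chrom.sizes"))
  write_bed(cfg$genes[, .(chrom, start, end, name)], file.path(dir, "genes.bed"))
  for (id in names(cohort$cells)) {
    cell <- cohort$cells[[id]]
    if (!is.null(cell$meth))
      write_allc(cell$meth, file.path(dir, "allc", paste0(id, ".tsv")))
    if (!is.null(cell$contacts))
      write_pairs(cell$contacts, file.path(dir, "pairs", paste0(id, ".tsv")))
  }
  fwrite(cohort$truth$cells, file.path(dir, "truth_cells.tsv"), sep = "\t")
  fwrite(cohort$truth$dmrs, file.path(dir, "truth_dmrs.tsv"), sep = "\t")
  invisible(dir)
}
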