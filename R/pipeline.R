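# Pipeline driver: one command per stage, a resolved-config snapshot and
# a plain log per stage, deterministic outputs under a fixed seed.

.default_run_config <- function() {
  list(
    seed = 1L,
    sim = list(n_scale = 1, contacts_per_cell = 50000L,
               cg_spacing = 2000, ch_spacing = 4000, ccc_spacing = 20000),
    stages = list(qc = TRUE, methylome = TRUE, contacts = TRUE,
                  structure = TRUE, trajectory = TRUE),
    methylome = list(dmr_lineage = "MSN", dmr_q = 0.05, dmr_min_delta = 0.1,
                     dmr_merge_gap = 250, dmr_min_sites = 2),
    contacts = list(min_band_count = 50),
    structure = list(chrom = "chr3", lineage = "MSN",
                     compartment_resolution = 250e3,
                     insulation_resolution = 25e3,
                     loop_resolution = 10e3,
                     boundary_B = 20, boundary_min_depth = 0.5,
                     ages = c("2T", "3T")),
    trajectory = list(lineage = "INT", root_state = "eINT",
                      target_state = "tODC", strat_col = "region")
  )
}

.merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) stop("config key ", full, " must be a section")
      base[[key]] <- .merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Resolve a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), overlays it on the package
#' defaults, and rejects unknown keys; every seed and threshold is
#' explicit in the resolved result, which each stage persists next to its
#' outputs for auditability.
#'
#' @param config path to a YAML config, a list, or `NULL` for defaults.
#' @param seed optional seed overriding the config's.
#' @return resolved config list.
#' @export
run_config <- function(config = NULL, seed = NULL) {
  base <- .default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) base <- .merge_config(base, config)
  if (!is.null(seed)) base$seed <- as.integer(seed)
  base
}

.stage_init <- function(out, stage, config) {
  dir <- file.path(out, stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(dir, "config_resolved.yaml"))
  log <- file.path(dir, "log.txt")
  cat("stage:", stage, "\n", file = log)
  list(dir = dir, log = log)
}

.log <- function(ctx, ...) {
  cat(..., "\n", file = ctx$log, append = TRUE)
}

.need_upstream <- function(out, stage, producer) {
  dir <- file.path(out, stage)
  if (!dir.exists(dir))
    stop("missing upstream output '", stage, "'; run `", producer, "` first")
  dir
}

#' Load a simulated dataset from disk
#'
#' @param dir dataset directory written by [cmd_simulate()].
#' @param modalities which per-cell modalities to load.
#' @return list with `cells`, `meta`, `genome`, `genes`.
#' @export
read_cohort <- function(dir, modalities = c("meth", "contacts")) {
  genome <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  meta <- fread(file.path(dir, "meta.tsv"))
  genes <- read_bed(file.path(dir, "genes.bed"))
  cells <- lapply(meta$cell_id, function(id) {
    cell <- list()
    if ("meth" %in% modalities)
      cell$meth <- read_allc(file.path(dir, "allc", paste0(id, ".tsv")), genome)
    if ("contacts" %in% modalities)
      cell$contacts <- read_pairs(file.path(dir, "pairs", paste0(id, ".tsv")),
                                  genome)
    cell
  })
  names(cells) <- meta$cell_id
  list(cells = cells, meta = meta, genome = genome, genes = genes)
}

#' Pipeline stage: simulate a dataset
#'
#' @param config resolved config (see [run_config()]).
#' @param out output directory root.
#' @return the dataset directory, invisibly.
#' @export
cmd_simulate <- function(config, out) {
  ctx <- .stage_init(out, "dataset", config)
  cfg <- sim_config(seed = config$seed,
                    n_scale = config$sim$n_scale,
                    contacts_per_cell = config$sim$contacts_per_cell,
                    cg_spacing = config$sim$cg_spacing,
                    ch_spacing = config$sim$ch_spacing,
                    ccc_spacing = config$sim$ccc_spacing)
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, cfg, ctx$dir)
  .log(ctx, "cells:", nrow(cohort$meta))
  invisible(ctx$dir)
}

#' Pipeline stage: per-cell QC
#'
#' Writes per-cell global mCG/mCH/mCCC (raw and conversion-corrected),
#' contact counts, the intra/inter ratio and the short/long-range ratio.
#'
#' @inheritParams cmd_simulate
#' @export
cmd_qc <- function(config, out) {
  ds <- .need_upstream(out, "dataset", "simulate")
  ctx <- .stage_init(out, "qc", config)
  co <- read_cohort(ds)
  rows <- lapply(names(co$cells), function(id) {
    cell <- co$cells[[id]]
    gl <- global_levels(cell$meth)
    ii <- intra_inter_ratio(cell$contacts)
    sl <- sle_ratio(cell$contacts, min_count = config$contacts$min_band_count)
    cbind(data.table(cell_id = id), gl, ii,
          sl[, .(n_short, n_long, sle = ratio)])
  })
  qc <- rbindlist(rows)
  fwrite(qc, file.path(ctx$dir, "qc.tsv"), sep = "\t")
  summ <- intra_inter_summary(qc$n_intra, qc$n_inter)
  fwrite(summ, file.path(ctx$dir, "intra_inter_summary.tsv"), sep = "\t")
  .log(ctx, "cells:", nrow(qc))
  invisible(ctx$dir)
}

#' Pipeline stage: methylome matrices and DMRs
#' @inheritParams cmd_simulate
#' @export
cmd_methylome <- function(config, out) {
  ds <- .need_upstream(out, "dataset", "simulate")
  ctx <- .stage_init(out, "methylome", config)
  co <- read_cohort(ds, "meth")
  meth <- lapply(co$cells, `[[`, "meth")
  gm <- gene_body_mc(meth, co$genes)
  glb <- vapply(meth, function(m) global_levels(m)$mcg, numeric(1))
  norm <- normalized_gene_mc(gm$frac, glb)
  fwrite(data.table(gene = rownames(gm$frac), gm$frac),
         file.path(ctx$dir, "gene_mcg.tsv"), sep = "\t")
  fwrite(data.table(gene = rownames(norm), norm),
         file.path(ctx$dir, "gene_mcg_normalized.tsv"), sep = "\t")
  # pseudobulk correlation across (state, age) groups
  grp <- paste0(co$meta$L2, "|", co$meta$age_group)
  pb <- sapply(sort(unique(grp)), function(g)
    rowMeans(gm$frac[, grp == g, drop = FALSE], na.rm = TRUE))
  cc <- suppressWarnings(group_correlation(pb))
  fwrite(data.table(group = rownames(cc), cc),
         file.path(ctx$dir, "group_correlation.tsv"), sep = "\t")
  # trajectory-DMRs along the configured lineage
  lin <- config$methylome$dmr_lineage
  sel <- co$meta$lineage == lin
  pooled <- pool_sites(meth[sel],
                       factor(co$meta$age_group[sel], levels = .SIM_AGES))
  pooled <- pooled[intersect(.SIM_AGES, names(pooled))]
  dmrs <- call_dmrs(pooled, "trajectory",
                    q_thresh = config$methylome$dmr_q,
                    min_delta = config$methylome$dmr_min_delta,
                    merge_gap = config$methylome$dmr_merge_gap,
                    min_sites = config$methylome$dmr_min_sites)
  write_dmrs(dmrs, file.path(ctx$dir, "trajectory_dmrs"))
  .log(ctx, "dmrs:", nrow(dmrs))
  invisible(ctx$dir)
}

#' Pipeline stage: per-cell contact statistics
#' @inheritParams cmd_simulate
#' @export
cmd_contacts <- function(config, out) {
  ds <- .need_upstream(out, "dataset", "simulate")
  ctx <- .stage_init(out, "contacts", config)
  co <- read_cohort(ds, "contacts")
  bins <- decay_bins()
  prof <- t(vapply(co$cells, function(cell)
    decay_profile(cell$contacts, bins)$fraction, numeric(length(bins) - 1)))
  fwrite(data.table(cell_id = rownames(prof), prof),
         file.path(ctx$dir, "decay_profiles.tsv"), sep = "\t")
  sle <- rbindlist(lapply(co$cells, function(cell)
    sle_ratio(cell$contacts, min_count = config$contacts$min_band_count)))
  sle[, cell_id := names(co$cells)]
  cls <- tryCatch(classify_sle(sle$ratio, seed = config$seed),
                  error = function(e) NULL)
  sle[, state := if (is.null(cls)) NA_character_ else cls$states]
  fwrite(sle, file.path(ctx$dir, "sle.tsv"), sep = "\t")
  g3 <- sapply(co$cells, function(cell)
    gene_3cgs(cell$contacts, co$genes)$per100k)
  fwrite(data.table(gene = co$genes$name, g3),
         file.path(ctx$dir, "gene_3cgs.tsv"), sep = "\t")
  .log(ctx, "cells:", nrow(sle), "; sle bimodal:",
       if (is.null(cls)) NA else cls$bimodal)
  invisible(ctx$dir)
}

#' Pipeline stage: pseudobulk 3D-genome structure
#' @inheritParams cmd_simulate
#' @export
cmd_structure <- function(config, out) {
  ds <- .need_upstream(out, "dataset", "simulate")
  ctx <- .stage_init(out, "structure", config)
  sc <- config$structure
  co <- read_cohort(ds, "contacts")
  sel <- co$meta$lineage == sc$lineage
  ages <- intersect(.SIM_AGES, unique(co$meta$age_group[sel]))
  strengths <- list()
  for (age in ages) {
    idx <- which(sel & co$meta$age_group == age)
    bulk <- pool_contacts(lapply(co$cells[idx], `[[`, "contacts"))
    bm <- oe_normalize(bin_contacts(bulk, sc$compartment_resolution,
                                    sc$chrom, co$genome))
    tr <- compartment_pc1(bm)
    write_bedgraph(tr, "pc1", file.path(ctx$dir, paste0("pc1_", age, ".bedgraph")))
    strengths[[age]] <- data.table(age_group = age,
                                   strength = compartment_strength(bm, tr))
    ins <- insulation_score(bin_contacts(bulk, sc$insulation_resolution,
                                         sc$chrom, co$genome))
    write_bedgraph(ins, "insulation",
                   file.path(ctx$dir, paste0("insulation_", age, ".bedgraph")))
  }
  fwrite(rbindlist(strengths), file.path(ctx$dir, "compartment_strength.tsv"),
         sep = "\t")
  # age-differential boundaries between the two configured ages
  a1 <- sc$ages[1]; a2 <- sc$ages[2]
  grab <- function(a) lapply(co$cells[which(sel & co$meta$age_group == a)],
                             `[[`, "contacts")
  bp1 <- boundary_probability(grab(a1), co$genome, sc$chrom,
                              sc$insulation_resolution, B = sc$boundary_B,
                              min_depth = sc$boundary_min_depth,
                              seed = config$seed)
  bp2 <- boundary_probability(grab(a2), co$genome, sc$chrom,
                              sc$insulation_resolution, B = sc$boundary_B,
                              min_depth = sc$boundary_min_depth,
                              seed = config$seed + 1L)
  db <- differential_boundaries(bp1, bp2)
  fwrite(db, file.path(ctx$dir, "age_dbs.tsv"), sep = "\t")
  # loops on the union of age pseudobulks
  bulk_all <- pool_contacts(lapply(co$cells[which(sel)], `[[`, "contacts"))
  bml <- bin_contacts(bulk_all, sc$loop_resolution, sc$chrom, co$genome)
  loops <- call_loops(bml)
  fwrite(loops, file.path(ctx$dir, "loops.tsv"), sep = "\t")
  .log(ctx, "ages:", paste(ages, collapse = ","), "; age-DBs:",
       sum(db$significant), "; loops:", sum(loops$significant))
  invisible(ctx$dir)
}

#' Pipeline stage: pseudotime and composition
#' @inheritParams cmd_simulate
#' @export
cmd_trajectory <- function(config, out) {
  ds <- .need_upstream(out, "dataset", "simulate")
  ctx <- .stage_init(out, "trajectory", config)
  tc <- config$trajectory
  co <- read_cohort(ds)
  sel <- which(co$meta$lineage == tc$lineage)
  cells <- co$cells[sel]
  meta <- co$meta[sel]
  roots <- meta$cell_id[meta$L2 == tc$root_state]
  pt <- lapply(c(mcg = "mcg", `3c` = "3c", joint = "joint"), function(mod) {
    fs <- build_features(cells, mod, co$genome)
    pseudotime(fs$X, roots, seed = config$seed)
  })
  tab <- merge(merge(pt$mcg[, .(cell_id, pt_mcg = score)],
                     pt$`3c`[, .(cell_id, pt_3c = score)], by = "cell_id"),
               pt$joint[, .(cell_id, pt_joint = score)], by = "cell_id")
  tab <- merge(tab, meta[, .(cell_id, age_group)], by = "cell_id")
  fwrite(tab, file.path(ctx$dir, "pseudotime.tsv"), sep = "\t")
  lag <- modality_lag(tab, ages = .SIM_AGES, min_cells = 5)
  fwrite(lag$by_age, file.path(ctx$dir, "modality_lag_by_age.tsv"), sep = "\t")
  imm <- immature_fraction(co$meta,
                           unique(co$meta$state[co$meta$immature == TRUE]))
  fwrite(imm, file.path(ctx$dir, "immature_fraction.tsv"), sep = "\t")
  ce <- composition_enrichment(co$meta, "state", tc$target_state, tc$strat_col)
  fwrite(ce, file.path(ctx$dir, "composition_enrichment.tsv"), sep = "\t")
  .log(ctx, "lag:", lag$lag)
  invisible(ctx$dir)
}

#' Pipeline stage: aggregate report tables
#'
#' Collects per-cell QC and the headline statistics of every stage into
#' `report/`; stages toggled off (or not yet run) are marked absent.
#'
#' @inheritParams cmd_simulate
#' @export
cmd_report <- function(config, out) {
  ctx <- .stage_init(out, "report", config)
  status <- list()
  for (stage in names(config$stages)) {
    present <- config$stages[[stage]] && dir.exists(file.path(out, stage))
    status[[stage]] <- data.table(stage = stage,
                                  status = if (present) "present" else "absent")
  }
  fwrite(rbindlist(status), file.path(ctx$dir, "stage_status.tsv"), sep = "\t")
  if (dir.exists(file.path(out, "qc"))) {
    qc <- fread(file.path(out, "qc", "qc.tsv"))
    summ <- data.table(
      n_cells = nrow(qc),
      mean_mcg = mean(qc$mcg, na.rm = TRUE),
      mean_mch = mean(qc$mch, na.rm = TRUE),
      mean_mccc = mean(qc$mccc, na.rm = TRUE),
      intra_inter_ratio_of_means = mean(qc$n_intra) / mean(qc$n_inter))
    fwrite(summ, file.path(ctx$dir, "qc_summary.tsv"), sep = "\t")
  }
  invisible(ctx$dir)
}

#' Run the full pipeline
#'
#' Executes simulate, then every enabled stage, then the report. Outputs
#' are reproduced byte-identically from the same config and seed.
#'
#' @param config config path, list or `NULL` (see [run_config()]).
#' @param out output directory root.
#' @param seed optional seed override.
#' @return `out`, invisibly.
#' @export
run_pipeline <- function(config = NULL, out, seed = NULL) {
  config <- run_config(config, seed)
  cmd_simulate(config, out)
  if (config$stages$qc) cmd_qc(config, out)
  if (config$stages$methylome) cmd_methylome(config, out)
  if (config$stages$contacts) cmd_contacts(config, out)
  if (config$stages$structure) cmd_structure(config, out)
  if (config$stages$trajectory) cmd_trajectory(config, out)
  cmd_report(config, out)
  invisible(out)
}
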