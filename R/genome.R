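#' @importFrom data.table data.table as.data.table setkey setkeyv foverlaps
#'   fread fwrite rbindlist setorder setnames setattr setcolorder copy := .N .SD %chin%
#' @importFrom stats rbinom rpois runif rnorm median quantile sd cor
#'   p.adjust kruskal.test prcomp dhyper ppois kmeans dist setNames
#'   fisher.test wilcox.test aggregate anova lm as.formula complete.cases
#' @importFrom utils head tail
NULL

utils::globalVariables(c(
  ".", "chrom", "chrom1", "chrom2", "pos", "pos1", "pos2", "start", "end",
  "name", "mc", "cov", "context", "strand", "sep_bp", "cell_id", "i.start",
  "i.end", "i.name", "gene", "frac", "q", "p", "direction", "region_id",
  "n_sites", "delta", "age_group", "state", "lineage", "L1", "L2", "L3",
  "donor_id", "region", "score", "modality", "x", "y", "keep", "bin",
  "label", "V1", "V2", "V3", "V4", "V5", "V6", "obs", "enrich",
  "gene_id", "dmr_id", "block", "gid", "did", "active_state", "n",
  "neuronal", "immature", "root", "lag_3c", "region_str", "m_3c", "w_se",
  "traj_dir", "kind", "from_age", "i.gid", "i.did", "frac_a", "frac_b",
  "mc_a", "mc_b", "cov_a", "cov_b", "site_q", "grp", "n_short", "n_long",
  "ratio", "posterior_se", "value", "stratum", "odds_ratio", "pct",
  "n_intra", "n_inter", "mcg", "mch", "mccc", "mch_corrected", "pc1",
  "boundary", "prob_a", "prob_b", "k_a", "k_b", "d", "bin1", "bin2",
  "raw", "per100k", "per100k_kb", "run_id", "sig", "min_region",
  "fraction", "n_immature", "pt_mcg", "pt_3c", "pt_joint", "med_mcg",
  "med_3c", "significant", "prominence", "insulation", "valid", "diamond",
  "masked", "sle", "strength", "fi", "group", "n_bins",
  "anch_mcg", "anch_3c", "med_mcg", "med_3c", "traj_scale"
))

# Internal: 0-based, half-open intervals everywhere; allc input is 1-based.

#' Genome specification
#'
#' Ordered chromosome names and lengths plus an optional blocklist of
#' excluded regions (half-open intervals, 0-based). The chromosome order
#' given here defines the canonical endpoint order used for contact
#' tables.
#'
#' @param lengths named numeric vector of chromosome lengths in bp; names
#'   are chromosome names in canonical order.
#' @param blocklist optional `data.table`/`data.frame` with columns
#'   `chrom`, `start`, `end` (0-based, half-open) of regions to exclude.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(lengths, blocklist = NULL) {
  if (is.null(names(lengths)) || anyNA(names(lengths)) || any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names: ",
         paste(unique(names(lengths)[duplicated(names(lengths))]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")
  if (!is.null(blocklist)) {
    blocklist <- as.data.table(blocklist)[, .(chrom, start = as.numeric(start),
                                              end = as.numeric(end))]
    bad <- !blocklist$chrom %chin% names(lengths)
    if (any(bad))
      stop("blocklist chromosomes not in genome: ",
           paste(unique(blocklist$chrom[bad]), collapse = ", "))
    if (any(blocklist$start < 0) ||
        any(blocklist$end > lengths[blocklist$chrom]) ||
        any(blocklist$start >= blocklist$end))
      stop("blocklist intervals must satisfy 0 <= start < end <= chrom length")
  } else {
    blocklist <- data.table(chrom = character(), start = numeric(), end = numeric())
  }
  structure(list(chroms = names(lengths),
                 lengths = setNames(as.numeric(lengths), names(lengths)),
                 blocklist = blocklist),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chroms), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp;",
      nrow(x$blocklist), "blocklist intervals\n")
  invisible(x)
}

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns chrom, length.
#' @param blocklist optional blocklist table (see [genome_spec()]).
#' @return a `genome_spec`.
#' @export
read_chrom_sizes <- function(path, blocklist = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2) stop("chrom sizes file needs two columns: ", path)
  genome_spec(setNames(as.numeric(dt[[2]]), as.character(dt[[1]])), blocklist)
}

#' Read a BED file as a region set
#'
#' Regions are half-open `[start, end)` in 0-based coordinates, the BED
#' convention. A fourth column supplies names; unnamed rows are named
#' `region_<i>`.
#'
#' @param path BED path (3+ columns, tab-separated, no header).
#' @return `data.table` with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0)
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric(), name = character()))
  if (ncol(dt) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- data.table(chrom = as.character(dt[[1]]),
                    start = as.numeric(dt[[2]]),
                    end = as.numeric(dt[[3]]),
                    name = if (ncol(dt) >= 4) as.character(dt[[4]])
                           else paste0("region_", seq_len(nrow(dt))))
  region_set(out)
}

#' Construct a validated region set
#'
#' @param regions data.frame-like with chrom, start, end and optional name.
#' @return `data.table` region set.
#' @export
region_set <- function(regions) {
  dt <- as.data.table(regions)
  if (!"name" %in% names(dt)) dt[, name := paste0("region_", seq_len(.N))]
  dt <- dt[, .(chrom = as.character(chrom), start = as.numeric(start),
               end = as.numeric(end), name = as.character(name))]
  if (any(dt$start >= dt$end)) stop("region set requires start < end")
  if (anyDuplicated(dt$name))
    stop("duplicate region names: ",
         paste(head(unique(dt$name[duplicated(dt$name)]), 5), collapse = ", "))
  dt[]
}

#' Write a region set as BED
#' @param regions region set table.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  fwrite(as.data.table(regions)[, .(chrom, start, end, name)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a genome's chromosome sizes
#' @param genome `genome_spec`.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  fwrite(data.table(chrom = genome$chroms, length = genome$lengths[genome$chroms]),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# point-in-interval membership (half-open), vectorized over points
.in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0 || length(pos) == 0)
    return(rep(FALSE, length(pos)))
  pts <- data.table(chrom = chrom, start = as.numeric(pos), end = as.numeric(pos))
  iv <- copy(as.data.table(intervals))[, .(chrom, start, end = end - 1)]
  setkey(iv, chrom, start, end)
  ov <- foverlaps(pts, iv, type = "any", which = TRUE, nomatch = NA)
  found <- rep(FALSE, length(pos))
  found[ov$xid[!is.na(ov$yid)]] <- TRUE
  found
}
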