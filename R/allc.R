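#' Construct a validated per-cell methylation site table
#'
#' Site-level basecall counts with context collapsed to CG / CH / CCC.
#' Positions are 0-based. CCC rows are the CH-context subset used to
#' estimate bisulfite non-conversion and are tracked as their own class.
#'
#' @param sites data.frame-like with columns chrom, pos, strand, context,
#'   mc, cov.
#' @param genome optional `genome_spec` for bounds checking.
#' @return `data.table` of class columns (chrom, pos, strand, context, mc, cov).
#' @export
meth_site_table <- function(sites, genome = NULL) {
  dt <- as.data.table(sites)[, .(chrom = as.character(chrom),
                                 pos = as.integer(pos),
                                 strand = as.character(strand),
                                 context = as.character(context),
                                 mc = as.integer(mc), cov = as.integer(cov))]
  if (nrow(dt)) {
    if (!all(dt$context %chin% c("CG", "CH", "CCC")))
      stop("context must be one of CG, CH, CCC")
    bad <- which(dt$mc > dt$cov | dt$mc < 0 | dt$cov < 1)
    if (length(bad))
      stop("invalid methylation counts (mc > cov, mc < 0 or cov < 1) at row(s) ",
           paste(head(bad, 5), collapse = ", "))
    if (!is.null(genome)) {
      if (!all(dt$chrom %chin% genome$chroms))
        stop("unknown chromosome(s): ",
             paste(setdiff(unique(dt$chrom), genome$chroms), collapse = ", "))
      oob <- dt$pos < 0 | dt$pos >= genome$lengths[dt$chrom]
      if (any(oob)) stop(sum(oob), " site(s) outside chromosome bounds")
    }
  }
  dt[]
}

#' Collapse trinucleotide contexts to CG / CH / CCC
#'
#' Any context whose second base is G is a CpG site (CG); `CCC` is kept as
#' its own class (non-conversion proxy); everything else is CH.
#'
#' @param tri character vector of trinucleotide contexts (e.g. "CGG").
#' @return character vector in {CG, CH, CCC}.
#' @export
collapse_context <- function(tri) {
  out <- rep("CH", length(tri))
  out[substr(tri, 2, 2) == "G"] <- "CG"
  out[tri == "CCC"] <- "CCC"
  out
}

#' Read an allc-style methylation table
#'
#' The allc dialect is a TSV with columns chrom, position (1-based by
#' default), strand, trinucleotide context, methylated count, total count
#' (a 7th 0/1 column may be present and is ignored). Positions are
#' converted to the package's 0-based convention.
#'
#' @param path file path.
#' @param genome optional `genome_spec` for bounds checking.
#' @param one_based logical; set `FALSE` if the file is already 0-based.
#' @return a methylation site table (see [meth_site_table()]).
#' @export
read_allc <- function(path, genome = NULL, one_based = TRUE) {
  dt <- suppressWarnings(fread(path, header = FALSE, sep = "\t", fill = TRUE))
  if (nrow(dt) == 0)
    return(meth_site_table(data.table(chrom = character(), pos = integer(),
                                      strand = character(), context = character(),
                                      mc = integer(), cov = integer())))
  if (ncol(dt) < 6) stop("allc file needs at least 6 columns: ", path)
  pos <- suppressWarnings(as.integer(dt[[2]]))
  mc <- suppressWarnings(as.integer(dt[[5]]))
  cov <- suppressWarnings(as.integer(dt[[6]]))
  bad <- which(is.na(pos) | is.na(mc) | is.na(cov))
  if (length(bad))
    stop("malformed allc row(s) at line(s) ", paste(head(bad, 5), collapse = ", "),
         " in ", path)
  bad <- which(mc > cov)
  if (length(bad))
    stop("mc > cov at line(s) ", paste(head(bad, 5), collapse = ", "), " in ", path)
  meth_site_table(data.table(chrom = as.character(dt[[1]]),
                             pos = pos - as.integer(one_based),
                             strand = as.character(dt[[3]]),
                             context = collapse_context(as.character(dt[[4]])),
                             mc = mc, cov = cov),
                  genome)
}

#' Write a methylation site table in allc layout
#'
#' Emits 1-based positions (the allc convention); contexts are written as
#' stored (already collapsed). Deterministic column order, newline
#' terminated.
#'
#' @param sites methylation site table.
#' @param path output path.
#' @export
write_allc <- function(sites, path) {
  dt <- as.data.table(sites)[, .(chrom, pos = pos + 1L, strand, context, mc, cov)]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
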