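#' Construct a canonicalized contact table
#'
#' Each row is one chromatin contact with unordered endpoints stored in
#' canonical order: endpoint A precedes endpoint B by chromosome order
#' (as declared in the genome) then by position.
#'
#' @param contacts data.frame-like with chrom1, pos1, chrom2, pos2.
#' @param genome `genome_spec` providing chromosome order and bounds.
#' @param drop_out_of_bounds if TRUE, rows with an endpoint outside its
#'   chromosome are dropped and their count attached as attribute
#'   `n_rejected`; if FALSE they are an error.
#' @return `data.table` (chrom1, pos1, chrom2, pos2), canonical order.
#' @export
contact_table <- function(contacts, genome, drop_out_of_bounds = FALSE) {
  dt <- as.data.table(contacts)[, .(chrom1 = as.character(chrom1),
                                    pos1 = as.numeric(pos1),
                                    chrom2 = as.character(chrom2),
                                    pos2 = as.numeric(pos2))]
  unknown <- setdiff(unique(c(dt$chrom1, dt$chrom2)), genome$chroms)
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  n_rejected <- 0L
  if (nrow(dt)) {
    oob <- dt$pos1 < 0 | dt$pos1 >= genome$lengths[dt$chrom1] |
           dt$pos2 < 0 | dt$pos2 >= genome$lengths[dt$chrom2]
    if (any(oob)) {
      if (!drop_out_of_bounds)
        stop(sum(oob), " contact(s) outside chromosome bounds")
      n_rejected <- sum(oob)
      dt <- dt[!oob]
    }
  }
  ord <- match(dt$chrom1, genome$chroms)
  ord2 <- match(dt$chrom2, genome$chroms)
  flip <- ord2 < ord | (ord2 == ord & dt$pos2 < dt$pos1)
  if (any(flip)) {
    tmp_c <- dt$chrom1[flip]; tmp_p <- dt$pos1[flip]
    dt[flip, `:=`(chrom1 = chrom2, pos1 = pos2)]
    dt[flip, `:=`(chrom2 = tmp_c, pos2 = tmp_p)]
  }
  setattr(dt, "n_rejected", n_rejected)
  dt[]
}

#' Read a pairs-style contact list
#'
#' Accepts 4-column (chromA posA chromB posB) or 5-column (readID first)
#' TSVs; comment lines starting with `#` are skipped. Endpoints are
#' canonicalized; out-of-bound rows are dropped with their count reported
#' in attribute `n_rejected` and a message.
#'
#' @param path file path.
#' @param genome `genome_spec`.
#' @return canonical contact table.
#' @export
read_pairs <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(contact_table(data.table(chrom1 = character(), pos1 = numeric(),
                                    chrom2 = character(), pos2 = numeric()),
                         genome))
  dt <- fread(text = lines, header = FALSE, sep = "\t",
              colClasses = "character")
  if (ncol(dt) >= 5 && anyNA(suppressWarnings(as.numeric(dt[[2]])))) {
    # readID in column 1: endpoint columns are 2-5
    dt <- dt[, .(V1 = as.character(V2), V2 = as.numeric(V3),
                 V3 = as.character(V4), V4 = as.numeric(V5))]
  } else if (ncol(dt) < 4) {
    stop("pairs file needs at least 4 columns: ", path)
  }
  out <- contact_table(data.table(chrom1 = as.character(dt[[1]]),
                                  pos1 = as.numeric(dt[[2]]),
                                  chrom2 = as.character(dt[[3]]),
                                  pos2 = as.numeric(dt[[4]])),
                       genome, drop_out_of_bounds = TRUE)
  if (attr(out, "n_rejected") > 0)
    message(attr(out, "n_rejected"), " out-of-bounds contact(s) rejected from ", path)
  out
}

#' Write a contact table in 4-column pairs layout
#' @param contacts contact table.
#' @param path output path.
#' @export
write_pairs <- function(contacts, path) {
  fwrite(as.data.table(contacts)[, .(chrom1, pos1, chrom2, pos2)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Remove contacts overlapping excluded regions
#'
#' Retains exactly the contacts for which neither endpoint falls inside
#' any blocklist interval (half-open membership test). Idempotent.
#'
#' @param contacts contact table.
#' @param genome `genome_spec` carrying the blocklist.
#' @return filtered contact table.
#' @export
filter_blocklist <- function(contacts, genome) {
  dt <- as.data.table(contacts)
  if (nrow(dt) == 0 || nrow(genome$blocklist) == 0) return(dt)
  hit <- .in_intervals(dt$chrom1, dt$pos1, genome$blocklist) |
         .in_intervals(dt$chrom2, dt$pos2, genome$blocklist)
  dt[!hit]
}

#' Bin cis contacts of one chromosome into a symmetric matrix
#'
#' Bin index is `floor(pos / resolution)` (0-based bins); the count in
#' bin pair (i, j) is the number of contacts whose endpoints fall in bins
#' i and j. The matrix is stored dense and symmetric; its upper triangle
#' (including diagonal) sums to the number of cis contacts binned.
#'
#' @param contacts contact table.
#' @param resolution bin size in bp (> 0).
#' @param chrom chromosome to bin.
#' @param genome `genome_spec`.
#' @return object of class `binned_matrix` with fields `mat`,
#'   `resolution`, `chrom`, `n_contacts`, and (after [oe_normalize()])
#'   `oe` and `expected`.
#' @export
bin_contacts <- function(contacts, resolution, chrom, genome) {
  if (!is.numeric(resolution) || resolution <= 0) stop("resolution must be > 0")
  if (!chrom %chin% genome$chroms) stop("unknown chromosome: ", chrom)
  n_bins <- as.integer(ceiling(genome$lengths[[chrom]] / resolution))
  dt <- as.data.table(contacts)[chrom1 == chrom & chrom2 == chrom]
  mat <- matrix(0, n_bins, n_bins)
  if (nrow(dt)) {
    i <- as.integer(dt$pos1 %/% resolution) + 1L
    j <- as.integer(dt$pos2 %/% resolution) + 1L
    tab <- data.table(i = pmin(i, j), j = pmax(i, j))[, .N, by = .(i, j)]
    mat[cbind(tab$i, tab$j)] <- tab$N
    lower <- tab[i != j]
    mat[cbind(lower$j, lower$i)] <- lower$N
  }
  structure(list(mat = mat, resolution = resolution, chrom = chrom,
                 n_contacts = nrow(dt), oe = NULL, expected = NULL),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat("binned_matrix:", x$chrom, "@", format(x$resolution, big.mark = ","),
      "bp;", nrow(x$mat), "bins;", x$n_contacts, "cis contacts;",
      if (is.null(x$oe)) "raw" else "O/E computed", "\n")
  invisible(x)
}

#' Pool per-cell contact tables into one pseudobulk table
#' @param cells list of contact tables.
#' @return single contact table (row-bound; already canonical).
#' @export
pool_contacts <- function(cells) {
  rbindlist(lapply(cells, as.data.table), use.names = TRUE)
}
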