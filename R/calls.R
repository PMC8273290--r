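## Per-read methylation calls: read-by-CpG matrices per candidate region.
##
## A region call set is a list(region_id, calls, n_conflicts) where `calls`
## is an integer matrix (rows = reads, cols = CpG index within the region,
## entries 0 = unmethylated, 1 = methylated, NA = site not covered by that
## read). Both strands' evidence for a CpG is merged into one site: a call at
## the reverse-strand G (coordinate p + 1) reports to the forward unit at p.

new_read_call_set <- function(region_id, calls, n_conflicts = 0L) {
  structure(list(region_id = region_id, calls = calls,
                 n_conflicts = n_conflicts),
            class = "read_call_set")
}

#' @export
print.read_call_set <- function(x, ...) {
  cat("<read_call_set> region ", x$region_id, ": ", nrow(x$calls),
      " reads x ", ncol(x$calls), " CpGs (", x$n_conflicts,
      " mate conflicts)\n", sep = "")
  invisible(x)
}

## Build one region's call matrix from long-format calls.
## df: read_id, cpg_index (1-based within region), status. The first call a
## read makes at a site wins (mate-overlap policy); later disagreeing calls
## are counted as conflicts, not depth.
calls_matrix_from_long <- function(df, n_cpg, region_id) {
  if (nrow(df) == 0) {
    return(new_read_call_set(region_id,
                             matrix(integer(), 0, n_cpg)))
  }
  key <- paste(df$read_id, df$cpg_index)
  dup <- duplicated(key)
  first_status <- df$status[match(key, key)]
  n_conflicts <- sum(dup & df$status != first_status)
  df <- df[!dup, , drop = FALSE]
  reads <- unique(df$read_id)
  m <- matrix(NA_integer_, length(reads), n_cpg,
              dimnames = list(reads, NULL))
  m[cbind(match(df$read_id, reads), df$cpg_index)] <- as.integer(df$status)
  new_read_call_set(region_id, m, as.integer(n_conflicts))
}

#' Read per-read methylation calls from the TSV dialect
#'
#' The TSV has a header and columns `read_id`, `chrom`, `cpg_position`
#' (0-based forward-strand C coordinate) and `status` (0 unmethylated /
#' 1 methylated). Calls are assigned to candidate regions by coordinate;
#' calls outside any region CpG are dropped.
#'
#' @param path TSV path.
#' @param regions A `candidate_regions` data frame.
#' @return Named list of region call sets (one per region, in region order).
#' @export
read_calls_tsv <- function(path, regions) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "cpg_position", "status")
  if (!all(need %in% names(df))) {
    stop("calls TSV must have header columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$status %in% c(0L, 1L))) stop("status must be 0 or 1")
  split_calls_by_region(df$read_id, df$chrom, df$cpg_position, df$status,
                        regions)
}

split_calls_by_region <- function(read_id, chrom, position, status, regions) {
  out <- vector("list", nrow(regions))
  names(out) <- regions$region_id
  for (i in seq_len(nrow(regions))) {
    pos <- regions$cpg_positions[[i]]
    sel <- which(chrom == regions$chrom[i] & position %in% pos)
    df <- data.frame(read_id = read_id[sel],
                     cpg_index = match(position[sel], pos),
                     status = status[sel], stringsAsFactors = FALSE)
    out[[i]] <- calls_matrix_from_long(df, length(pos),
                                       regions$region_id[i])
  }
  out
}

#' Write region call sets to the TSV dialect
#'
#' @param call_sets Named list of region call sets.
#' @param regions Matching `candidate_regions` data frame (provides the
#'   genomic coordinates of each CpG index).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(call_sets, regions, path) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    cs <- call_sets[[regions$region_id[i]]]
    if (is.null(cs) || nrow(cs$calls) == 0) return(NULL)
    idx <- which(!is.na(cs$calls), arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(read_id = rownames(cs$calls)[idx[, 1]],
               chrom = regions$chrom[i],
               cpg_position = regions$cpg_positions[[i]][idx[, 2]],
               status = cs$calls[idx], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) {
    df <- data.frame(read_id = character(), chrom = character(),
                     cpg_position = integer(), status = integer())
  }
  df <- df[order(df$chrom, df$cpg_position, df$read_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Map each query base of an aligned read to a 0-based reference coordinate.
## pos0: 0-based leftmost reference position. Returns an integer vector with
## one entry per query base (NA for insertions / soft clips). Rejects
## malformed CIGARs.
cigar_query_to_ref <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0 || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  refpos <- pos0
  out <- integer(0)
  for (i in seq_along(ops)) {
    k <- kinds[i]; l <- lens[i]
    if (k %in% c("M", "=", "X")) {
      out <- c(out, refpos + seq_len(l) - 1L)
      refpos <- refpos + l
    } else if (k %in% c("I", "S")) {
      out <- c(out, rep(NA_integer_, l))
    } else if (k %in% c("D", "N")) {
      refpos <- refpos + l
    }
    ## H and P consume neither query nor reference
  }
  out
}

#' Parse Bismark-style methylation calls from SAM/BAM alignments
#'
#' Reads alignments whose `XM` tag carries per-base methylation calls
#' (Bismark convention: `Z` methylated CpG, `z` unmethylated CpG; other
#' contexts ignored), maps each CpG-context call through the CIGAR to
#' reference coordinates, and assembles read-by-CpG call matrices per
#' candidate region. Reverse-strand CpG calls (at coordinate p + 1) are
#' merged into the forward CpG unit at p. Unmapped, secondary and
#' duplicate-flagged records are skipped; records without an `XM` tag are
#' skipped and counted.
#'
#' @param path SAM or BAM file (SAM files are converted on the fly).
#' @param regions A `candidate_regions` data frame.
#' @param min_mapq Minimum mapping quality (default 0, i.e. permissive).
#' @return Named list of region call sets; attribute `n_missing_tag` counts
#'   skipped records without an XM tag.
#' @export
parse_alignment_calls <- function(path, regions, min_mapq = 0L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "mapq"),
    tag = "XM", flag = flag)
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  xm <- rec$tag$XM
  keep <- !is.na(rec$pos) & (is.na(rec$mapq) | rec$mapq >= min_mapq)
  n_missing <- sum(keep & is.na(xm))
  keep <- keep & !is.na(xm)
  read_id <- character(0); chrom <- character(0)
  position <- integer(0); status <- integer(0)
  for (i in which(keep)) {
    s <- xm[i]
    hits <- gregexpr("[Zz]", s)[[1]]
    if (hits[1] == -1L) next
    q2r <- cigar_query_to_ref(rec$cigar[i], rec$pos[i] - 1L)
    refpos <- q2r[hits]
    ok <- !is.na(refpos)
    if (!any(ok)) next
    read_id <- c(read_id, rep(rec$qname[i], sum(ok)))
    chrom <- c(chrom, rep(as.character(rec$rname[i]), sum(ok)))
    position <- c(position, refpos[ok])
    status <- c(status, as.integer(substring(s, hits, hits)[ok] == "Z"))
  }
  ## reverse-strand CpG calls sit on the G: shift to the forward C unit when
  ## the coordinate itself is not a catalogued C
  all_pos <- unlist(regions$cpg_positions, use.names = FALSE)
  on_g <- !(position %in% all_pos) & ((position - 1L) %in% all_pos)
  position[on_g] <- position[on_g] - 1L
  out <- split_calls_by_region(read_id, chrom, position, status, regions)
  attr(out, "n_missing_tag") <- n_missing
  out
}

#' Per-site pileup of methylation calls
#'
#' @param call_set A region call set (from [read_calls_tsv()],
#'   [parse_alignment_calls()] or [emit_reads()]), or a bare call matrix.
#' @return Data frame with one row per CpG index: `cpg_index`, `n_meth`,
#'   `n_unmeth`, `depth`.
#' @export
pileup <- function(call_set) {
  calls <- if (is.matrix(call_set)) call_set else call_set$calls
  n_meth <- as.integer(colSums(calls == 1L, na.rm = TRUE))
  n_unmeth <- as.integer(colSums(calls == 0L, na.rm = TRUE))
  data.frame(cpg_index = seq_len(ncol(calls)), n_meth = n_meth,
             n_unmeth = n_unmeth, depth = n_meth + n_unmeth)
}
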