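## Candidate-region generation: CpG catalog -> island splitting + dense-CpG
## clustering. All coordinates are 0-based, half-open (BED convention); a CpG
## position is the coordinate of the C on the forward strand.

#' Extract forward-strand CpG coordinates from genome sequence
#'
#' Scans each chromosome for \code{CG} dinucleotides and returns their
#' 0-based start coordinates. Dinucleotides containing \code{N} are excluded;
#' letters other than A/C/G/T/N are rejected.
#'
#' @param genome A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @return A named list (one element per chromosome) of strictly increasing
#'   integer vectors of CpG coordinates.
#' @examples
#' extract_cpg_catalog(c(chr1 = "ACGTCGN"))
#' @export
extract_cpg_catalog <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("seq", seq_along(genome))
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  bad <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  extra <- rowSums(bad[, setdiff(colnames(bad), allowed), drop = FALSE])
  if (any(extra > 0)) {
    stop("genome contains non-nucleotide characters other than N in: ",
         paste(names(genome)[extra > 0], collapse = ", "))
  }
  out <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern("CG", genome[[i]], fixed = TRUE)
    as.integer(Biostrings::start(m) - 1L)
  })
  names(out) <- names(genome)
  out
}

## sizes of k consecutive blocks over n items, differing by at most 1
balanced_block_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  as.integer(sizes)
}

region_row <- function(chrom, positions, source) {
  data.frame(chrom = chrom,
             start = positions[1L],
             end = positions[length(positions)] + 2L,
             cpg_count = length(positions),
             source = source,
             cpg_positions = I(list(as.integer(positions))),
             stringsAsFactors = FALSE)
}

#' Split one CpG island into candidate regions
#'
#' An island holding `n >= min_cpg` CpGs is partitioned into
#' `floor(n / min_cpg)` consecutive blocks of near-equal size (sizes differ by
#' at most one, each at least `min_cpg`), so local methylation signal is not
#' averaged away over a long island. Islands with fewer than `min_cpg` CpGs
#' yield nothing.
#'
#' @param island_start,island_end 0-based half-open island interval.
#' @param positions Sorted CpG coordinates of the island's chromosome.
#' @param chrom Chromosome name recorded on output.
#' @param min_cpg Minimum CpG sites per candidate region (default 7).
#' @return A data frame of candidate regions (possibly zero rows) with
#'   columns `chrom`, `start`, `end`, `cpg_count`, `source` and list-column
#'   `cpg_positions`.
#' @export
split_island <- function(island_start, island_end, positions, chrom = "chr",
                         min_cpg = 7L) {
  inside <- positions[positions >= island_start & positions < island_end]
  n <- length(inside)
  k <- n %/% min_cpg
  if (k < 1L) return(empty_regions())
  sizes <- balanced_block_sizes(n, k)
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    region_row(chrom, inside[starts[i]:stops[i]], "island")
  }))
}

empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             cpg_count = integer(), source = character(),
             cpg_positions = I(list()), stringsAsFactors = FALSE)
}

#' Cluster dense CpGs outside islands into candidate regions
#'
#' CpGs not covered by any island are grouped into maximal runs in which
#' consecutive coordinates differ by at most `max_gap` bp. Runs with at least
#' `min_cpg` CpGs become candidate regions; runs longer than `2 * min_cpg`
#' are split into balanced blocks exactly like islands, so region sizes stay
#' bounded.
#'
#' @param positions Sorted CpG coordinates for one chromosome.
#' @param islands Data frame with 0-based half-open `start`/`end` columns
#'   (rows for this chromosome), or NULL for none.
#' @param chrom Chromosome name recorded on output.
#' @param max_gap Maximum distance (bp) between the C coordinates of
#'   neighboring CpGs within a run (default 20).
#' @inheritParams split_island
#' @return Candidate-region data frame with `source == "cluster"`.
#' @export
cluster_dense_cpgs <- function(positions, islands = NULL, chrom = "chr",
                               max_gap = 20L, min_cpg = 7L) {
  positions <- as.integer(positions)
  if (!is.null(islands) && nrow(islands) > 0) {
    keep <- !in_intervals(positions, islands$start, islands$end)
    positions <- positions[keep]
  }
  if (length(positions) < min_cpg) return(empty_regions())
  run_id <- cumsum(c(0L, diff(positions) > max_gap))
  runs <- split(positions, run_id)
  out <- lapply(runs, function(run) {
    n <- length(run)
    if (n < min_cpg) return(NULL)
    if (n <= 2L * min_cpg) return(region_row(chrom, run, "cluster"))
    k <- n %/% min_cpg
    sizes <- balanced_block_sizes(n, k)
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1L) + 1L)
    do.call(rbind, lapply(seq_len(k), function(i) {
      region_row(chrom, run[starts[i]:stops[i]], "cluster")
    }))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_regions())
  do.call(rbind, out)
}

## membership of points in a union of half-open intervals (intervals merged
## first, so overlaps in the annotation are harmless)
in_intervals <- function(x, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(x)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]; ks <- c(); ke <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { ks <- c(ks, ms); ke <- c(ke, me); ms <- starts[i]; me <- ends[i] }
  }
  ks <- c(ks, ms); ke <- c(ke, me)
  idx <- findInterval(x, ks)
  idx >= 1L & x < ke[pmax(idx, 1L)]
}

#' Generate sample-independent candidate regions
#'
#' Combines island splitting ([split_island()]) and dense-CpG clustering
#' ([cluster_dense_cpgs()]) over a whole genome: islands are partitioned into
#' blocks of at least `min_cpg` CpGs, CpGs outside islands are clustered by
#' the `max_gap` rule, and the union is returned sorted and non-overlapping
#' with stable region identifiers.
#'
#' @param genome Genome sequence as accepted by [extract_cpg_catalog()], or a
#'   precomputed catalog (named list of integer vectors).
#' @param islands CpG island intervals: a data frame with `chrom`, `start`,
#'   `end` (0-based half-open), a path to a BED file, or NULL for none.
#' @inheritParams cluster_dense_cpgs
#' @return A `candidate_regions` data frame with columns `chrom`, `start`,
#'   `end`, `region_id`, `cpg_count`, `source` and list-column
#'   `cpg_positions`.
#' @export
generate_candidate_regions <- function(genome, islands = NULL,
                                       max_gap = 20L, min_cpg = 7L) {
  catalog <- if (is.list(genome) && !methods::is(genome, "DNAStringSet")) {
    genome
  } else {
    extract_cpg_catalog(genome)
  }
  if (is.character(islands) && length(islands) == 1L) {
    islands <- read_islands_bed(islands)
  }
  per_chrom <- lapply(sort(names(catalog)), function(chrom) {
    pos <- as.integer(catalog[[chrom]])
    isl <- if (is.null(islands)) NULL else
      islands[islands$chrom == chrom, , drop = FALSE]
    island_regs <- if (is.null(isl) || nrow(isl) == 0) empty_regions() else
      do.call(rbind, lapply(seq_len(nrow(isl)), function(i) {
        split_island(isl$start[i], isl$end[i], pos, chrom, min_cpg)
      }))
    cluster_regs <- cluster_dense_cpgs(pos, isl, chrom, max_gap, min_cpg)
    regs <- rbind(island_regs, cluster_regs)
    regs[order(regs$start), , drop = FALSE]
  })
  regions <- do.call(rbind, per_chrom)
  if (is.null(regions) || nrow(regions) == 0) {
    regions <- empty_regions()
    regions$region_id <- character()
  } else {
    if (any(regions$start[-1] < head(regions$end, -1) &
            regions$chrom[-1] == head(regions$chrom, -1))) {
      stop("internal error: overlapping candidate regions emitted")
    }
    regions$region_id <- make_region_ids(regions$chrom)
  }
  rownames(regions) <- NULL
  class(regions) <- c("candidate_regions", "data.frame")
  regions[, c("chrom", "start", "end", "region_id", "cpg_count", "source",
              "cpg_positions")]
}

make_region_ids <- function(chroms) {
  idx <- stats::ave(seq_along(chroms), chroms, FUN = seq_along)
  paste0(chroms, "_", formatC(idx, width = 5, flag = "0"))
}

#' Read CpG island intervals from a BED file
#'
#' Uses the first three BED columns; coordinates are kept 0-based half-open.
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_islands_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Write candidate regions as BED6-compatible TSV
#'
#' Columns: chrom, start, end, region_id, cpg_count, source, plus a seventh
#' column with the comma-separated CpG coordinates so that downstream steps
#' can index calls without the genome.
#'
#' @param regions A `candidate_regions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, region_id = regions$region_id,
                    cpg_count = regions$cpg_count, source = regions$source,
                    cpg_positions = vapply(regions$cpg_positions, paste,
                                           character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read candidate regions written by [write_regions_bed()]
#'
#' @param path Path to the regions TSV.
#' @return A `candidate_regions` data frame.
#' @export
read_regions_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "region_id",
                                 "cpg_count", "source", "cpg_positions"))
  df$cpg_positions <- I(lapply(strsplit(df$cpg_positions, ","),
                               function(x) as.integer(x)))
  class(df) <- c("candidate_regions", "data.frame")
  df
}
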