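## Construction of the paired methylation haplotypes per candidate region:
## phase-link the heterozygous sites into two anti-assigned skeletons, pad
## the homozygous sites into both strings, then summarise with MH levels,
## L/N/M/H labels and the methylation haplotype mode (MHM).

#' Phase parity between two heterozygous CpG sites
#'
#' Compares the weight of the same-status joint patterns (00 + 11) with the
#' cross-status ones (01 + 10) on co-covering reads. Returns 0 when the
#' homolog carrying status x at the first site carries x at the second
#' (same), 1 when it carries 1 - x (cross), and NA on ties or when no read
#' covers both sites (phase chain break).
#'
#' @param call_set Region call set or call matrix.
#' @param u,v CpG indices of two heterozygous sites.
#' @return 0, 1 or NA.
#' @export
phase_parity <- function(call_set, u, v) {
  f <- joint_pattern_counts(call_set, u, v)
  same <- f[["00"]] + f[["11"]]
  cross <- f[["01"]] + f[["10"]]
  if (same == cross) return(NA_integer_)
  if (same > cross) 0L else 1L
}

#' Build the heterozygous-site skeletons of the two haplotypes
#'
#' Links neighboring heterozygous sites sequentially through their phase
#' parity and anti-assigns the two homologs over the resulting chain.
#' Haplotype naming is deterministic: haplotype 1 carries status 0 at the
#' first chained site. If a link is undecidable the longest prefix chain is
#' kept and the remaining heterozygous sites stay uncovered.
#'
#' @param het_indices Heterozygous CpG indices in genomic order.
#' @param call_set Region call set or call matrix.
#' @return List with `sites` (chained indices), `s1`, `s2` (integer 0/1
#'   vectors over `sites`) and `n_dropped` (het sites left out of the
#'   chain).
#' @export
build_skeleton <- function(het_indices, call_set) {
  k <- length(het_indices)
  if (k == 0) {
    return(list(sites = integer(0), s1 = integer(0), s2 = integer(0),
                n_dropped = 0L))
  }
  s1 <- 0L
  sites <- het_indices[1]
  if (k >= 2) for (i in 2:k) {
    par <- phase_parity(call_set, het_indices[i - 1], het_indices[i])
    if (is.na(par)) break
    s1 <- c(s1, if (par == 0L) s1[length(s1)] else 1L - s1[length(s1)])
    sites <- c(sites, het_indices[i])
  }
  list(sites = sites, s1 = s1, s2 = 1L - s1,
       n_dropped = k - length(sites))
}

#' Pad homozygous sites into the skeletons
#'
#' Every homozygous site contributes its status to both haplotype strings;
#' filtered and ambiguous sites stay uncovered. The result is the region's
#' haplotype pair.
#'
#' @param skeleton Result of [build_skeleton()].
#' @param homozygous Data frame with columns `cpg_index` and `status` for
#'   the homozygous sites.
#' @param region_id Region identifier recorded on the pair.
#' @return A `haplotype_pair`: list with `region_id`, `covered` (ordered CpG
#'   indices), `s1`, `s2`, `mh1`, `mh2`, `labels`, `mhm`, `n_covered`.
#' @export
pad_homozygous <- function(skeleton, homozygous, region_id = "region") {
  idx <- c(skeleton$sites, homozygous$cpg_index)
  s1 <- c(skeleton$s1, homozygous$status)
  s2 <- c(skeleton$s2, homozygous$status)
  o <- order(idx)
  new_haplotype_pair(region_id, idx[o], s1[o], s2[o])
}

new_haplotype_pair <- function(region_id, covered, s1, s2) {
  stopifnot(length(s1) == length(covered), length(s2) == length(covered))
  mh1 <- mh_level(s1)
  mh2 <- mh_level(s2)
  labels <- c(mh_label(mh1), mh_label(mh2))
  structure(list(region_id = region_id, covered = as.integer(covered),
                 s1 = as.integer(s1), s2 = as.integer(s2),
                 mh1 = mh1, mh2 = mh2, labels = labels,
                 mhm = canonical_mhm(labels),
                 n_covered = length(covered)),
            class = "haplotype_pair")
}

#' @export
print.haplotype_pair <- function(x, ...) {
  cat("<haplotype_pair> ", x$region_id, ": ", x$n_covered,
      " covered CpGs\n  s1 = ", paste(x$s1, collapse = ""), " (MH ",
      format(x$mh1, digits = 3), ")\n  s2 = ", paste(x$s2, collapse = ""),
      " (MH ", format(x$mh2, digits = 3), ")\n  MHM ", x$mhm, "\n", sep = "")
  invisible(x)
}

#' Methylation haplotype level
#'
#' Fraction of methylated CpGs in a haplotype string.
#'
#' @param s Integer 0/1 vector or a character string such as `"0110"`.
#' @return Value in \[0, 1\]; NaN for an empty string.
#' @examples
#' mh_level("0011")
#' @export
mh_level <- function(s) {
  if (is.character(s)) s <- as.integer(strsplit(s, "")[[1]])
  mean(s == 1L)
}

#' Label a haplotype by its MH level
#'
#' `L` if MH <= 0.25, `N` if MH <= 0.5, `M` if MH <= 0.75, `H` otherwise
#' (boundaries inclusive downward).
#'
#' @param mh Numeric MH level(s) in \[0, 1\], or a 0/1 character string
#'   (converted via [mh_level()]).
#' @return Character vector of labels.
#' @examples
#' mh_label(c(0.25, 0.5, 0.76))
#' @export
mh_label <- function(mh) {
  if (is.character(mh)) mh <- mh_level(mh)
  ifelse(mh <= 0.25, "L", ifelse(mh <= 0.5, "N", ifelse(mh <= 0.75,
                                                        "M", "H")))
}

LABEL_RANK <- c(L = 1L, N = 2L, M = 3L, H = 4L)

## canonical MHM string: the higher-MH haplotype's label first (equal MH
## implies equal labels, so descending label rank is equivalent)
canonical_mhm <- function(labels) {
  r <- LABEL_RANK[labels]
  paste(labels[order(-r)], collapse = "")
}

#' Methylation haplotype mode of a pair
#'
#' The two labels of the paired haplotypes, higher-MH label first; one of
#' the ten modes LL, NL, ML, HL, NN, MN, MM, HN, HM, HH.
#'
#' @param pair A `haplotype_pair`.
#' @return Two-character mode string.
#' @export
mhm <- function(pair) {
  pair$mhm
}

#' Is a haplotype pair a valid methylation haplotype (VMH)?
#'
#' Valid pairs cover more than 3 CpG sites.
#'
#' @param pair A `haplotype_pair`.
#' @param min_covered Minimum covered CpG count (default 4).
#' @return Logical flag.
#' @export
is_valid_pair <- function(pair, min_covered = 4L) {
  pair$n_covered >= min_covered
}

#' Phase one candidate region into a haplotype pair
#'
#' Full per-region pipeline: pileup, initial zygosity classification, CHS
#' chain resolution, skeleton construction, homozygous padding.
#'
#' @param call_set Region call set or call matrix.
#' @param region_id Identifier recorded on the output pair.
#' @param th_dp Site depth threshold (default 10).
#' @param min_freq,single_ratio,second_ratio True-pattern selection
#'   parameters (defaults 2, 0.6, 0.4).
#' @return List with `pair` (a `haplotype_pair`) and `zygosity` (per-site
#'   class data frame).
#' @export
phase_region <- function(call_set, region_id = NULL, th_dp = 10,
                         min_freq = 2, single_ratio = 0.6,
                         second_ratio = 0.4) {
  calls <- if (is.matrix(call_set)) call_set else call_set$calls
  if (is.null(region_id)) {
    region_id <- if (is.matrix(call_set)) "region" else call_set$region_id
  }
  pu <- pileup(calls)
  zyg <- initial_classify(pu, th_dp)
  chs <- zyg$cpg_index[zyg$class == "CANDIDATE_HET"]
  if (length(chs) > 0) {
    res <- resolve_chain(chs, calls, pu$depth, min_freq, single_ratio,
                         second_ratio)
    i <- match(res$cpg_index, zyg$cpg_index)
    zyg$class[i] <- res$class
    zyg$status[i] <- res$status
  }
  het <- zyg$cpg_index[zyg$class == "HETEROZYGOUS"]
  skel <- build_skeleton(het, calls)
  dropped_het <- setdiff(het, skel$sites)
  if (length(dropped_het) > 0) {
    zyg$class[zyg$cpg_index %in% dropped_het] <- "AMBIGUOUS"
  }
  hom <- zyg[zyg$class == "HOMOZYGOUS", c("cpg_index", "status")]
  pair <- pad_homozygous(skel, hom, region_id)
  list(pair = pair, zygosity = zyg)
}

#' Build haplotype pairs for all candidate regions of a sample
#'
#' @param call_sets Named list of region call sets (one sample).
#' @param regions Optional `candidate_regions` data frame (adds coordinates
#'   to the summary table).
#' @inheritParams phase_region
#' @return Object of class `haplotype_set`: list with `pairs` (named list of
#'   `haplotype_pair`), `zygosity` (named list of per-site class frames) and
#'   `table` (per-region summary data frame).
#' @export
build_haplotypes <- function(call_sets, regions = NULL, th_dp = 10,
                             min_freq = 2, single_ratio = 0.6,
                             second_ratio = 0.4) {
  phased <- lapply(names(call_sets), function(rid) {
    phase_region(call_sets[[rid]], rid, th_dp, min_freq, single_ratio,
                 second_ratio)
  })
  names(phased) <- names(call_sets)
  pairs <- lapply(phased, `[[`, "pair")
  tab <- haplotype_table(pairs, regions)
  structure(list(pairs = pairs,
                 zygosity = lapply(phased, `[[`, "zygosity"),
                 table = tab),
            class = "haplotype_set")
}

#' Summary table of haplotype pairs
#'
#' @param pairs Named list of `haplotype_pair` objects.
#' @param regions Optional `candidate_regions` data frame for coordinates.
#' @return Data frame with one row per region: `region_id`,
#'   `covered_cpg_count`, `s1`, `s2`, `mh1`, `mh2`, `mhm`, `valid` (plus
#'   `chrom`, `start`, `end` when `regions` is given).
#' @export
haplotype_table <- function(pairs, regions = NULL) {
  tab <- data.frame(
    region_id = vapply(pairs, `[[`, character(1), "region_id"),
    covered_cpg_count = vapply(pairs, `[[`, integer(1), "n_covered"),
    s1 = vapply(pairs, function(p) paste(p$s1, collapse = ""), character(1)),
    s2 = vapply(pairs, function(p) paste(p$s2, collapse = ""), character(1)),
    mh1 = vapply(pairs, `[[`, numeric(1), "mh1"),
    mh2 = vapply(pairs, `[[`, numeric(1), "mh2"),
    mhm = vapply(pairs, `[[`, character(1), "mhm"),
    valid = vapply(pairs, is_valid_pair, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(regions)) {
    i <- match(tab$region_id, regions$region_id)
    tab <- cbind(regions[i, c("chrom", "start", "end")], tab)
    rownames(tab) <- NULL
  }
  tab
}

#' Methylation and hypomethylation consistency between homologs
#'
#' CpG-weighted agreement of the paired haplotypes over all valid pairs:
#' methylation consistency is the fraction of covered CpGs lying in pairs
#' whose MHM is consistent (`HH` or `LL`); hypomethylation consistency
#' counts `LL` only. Reported genome-wide and, when region coordinates are
#' available, per chromosome.
#'
#' @param x A `haplotype_set`, a named list of `haplotype_pair` objects, or
#'   a haplotype table data frame (columns `covered_cpg_count`, `mhm`, and
#'   optionally `chrom`, `valid`).
#' @param regions Optional `candidate_regions` data frame (for per-
#'   chromosome scope).
#' @param min_covered VMH threshold passed to [is_valid_pair()].
#' @param modes_methylation,modes_hypo Consistent mode sets (defaults
#'   `c("HH","LL")` and `"LL"`).
#' @return Data frame with one row per scope: `scope`, `n_cpg_consistent`,
#'   `n_cpg_hypo_consistent`, `n_cpg_total`, `methylation_consistency`,
#'   `hypomethylation_consistency`. Scopes without valid pairs report NA.
#' @export
consistency_report <- function(x, regions = NULL, min_covered = 4L,
                               modes_methylation = c("HH", "LL"),
                               modes_hypo = "LL") {
  tab <- if (is.data.frame(x)) x
         else if (inherits(x, "haplotype_set")) x$table
         else haplotype_table(x)
  if (!"valid" %in% names(tab)) {
    tab$valid <- tab$covered_cpg_count >= min_covered
  }
  if (!"chrom" %in% names(tab) && !is.null(regions)) {
    tab$chrom <- regions$chrom[match(tab$region_id, regions$region_id)]
  }
  tab <- tab[tab$valid & tab$covered_cpg_count >= min_covered, ,
             drop = FALSE]
  one_scope <- function(scope, t) {
    total <- sum(t$covered_cpg_count)
    cons <- sum(t$covered_cpg_count[t$mhm %in% modes_methylation])
    hypo <- sum(t$covered_cpg_count[t$mhm %in% modes_hypo])
    data.frame(scope = scope, n_cpg_consistent = cons,
               n_cpg_hypo_consistent = hypo, n_cpg_total = total,
               methylation_consistency = if (total > 0) cons / total
                                         else NA_real_,
               hypomethylation_consistency = if (total > 0) hypo / total
                                             else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- one_scope("genome", tab)
  if ("chrom" %in% names(tab) && nrow(tab) > 0) {
    per <- lapply(split(tab, tab$chrom), function(t) {
      one_scope(t$chrom[1], t)
    })
    out <- rbind(out, do.call(rbind, per))
  }
  rownames(out) <- NULL
  out
}

#' Write a haplotype table as TSV
#'
#' @param x A `haplotype_set` or haplotype table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes_tsv <- function(x, path) {
  tab <- if (is.data.frame(x)) x else x$table
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a haplotype table written by [write_haplotypes_tsv()]
#'
#' @param path TSV path.
#' @return Haplotype table data frame.
#' @export
read_haplotypes_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(s1 = "character", s2 = "character"))
  df
}
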