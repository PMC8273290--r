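## Haplotype-resolution DMR calling: compare the methylation haplotype modes
## of a candidate region across samples, score the difference with the
## methylation haplotype difference (MHD), attach a read-permutation p-value
## and classify DMRs into four mode-change types.

#' Per-group haplotype summary for one region
#'
#' The MH levels of the higher- and lower-MH haplotype of the region's pair;
#' for multi-sample groups, the mean of each across the group's samples with
#' a valid pair.
#'
#' @param pairs List of `haplotype_pair` objects for one region (one per
#'   sample in the group).
#' @param min_covered VMH threshold.
#' @return `list(hi, lo, n_samples)`, or NULL when no sample has a valid
#'   pair.
#' @export
group_summary <- function(pairs, min_covered = 4L) {
  keep <- Filter(function(p) is_valid_pair(p, min_covered), pairs)
  if (length(keep) == 0) return(NULL)
  hi <- vapply(keep, function(p) max(p$mh1, p$mh2), numeric(1))
  lo <- vapply(keep, function(p) min(p$mh1, p$mh2), numeric(1))
  list(hi = mean(hi), lo = mean(lo), n_samples = length(keep))
}

#' Methylation haplotype difference between two groups
#'
#' The larger of the absolute MH differences between like-ranked haplotypes:
#' higher-MH haplotype against higher-MH haplotype, lower against lower.
#'
#' @param gi,gj Group summaries (`list(hi, lo)`) from [group_summary()], or
#'   `haplotype_pair` objects.
#' @return MHD in \[0, 1\].
#' @examples
#' mhd(list(hi = 1, lo = 0), list(hi = 1, lo = 1))
#' @export
mhd <- function(gi, gj) {
  as_summary <- function(g) {
    if (inherits(g, "haplotype_pair")) {
      list(hi = max(g$mh1, g$mh2), lo = min(g$mh1, g$mh2))
    } else g
  }
  gi <- as_summary(gi); gj <- as_summary(gj)
  max(abs(gi$hi - gj$hi), abs(gi$lo - gj$lo))
}

#' Methylation difference among multiple groups
#'
#' The maximum pairwise MHD over all unordered group pairs; identical to
#' [mhd()] for two groups.
#'
#' @param groups List of group summaries.
#' @return Maximum pairwise MHD.
#' @export
multi_group_mhd <- function(groups) {
  stopifnot(length(groups) >= 2)
  best <- 0
  n <- length(groups)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    best <- max(best, mhd(groups[[i]], groups[[j]]))
  }
  best
}

#' Permutation p-value for a region's between-sample MHD
#'
#' Pools the reads of the two samples, reassigns them to pseudo-samples of
#' the original sizes, rebuilds each pseudo-sample's haplotype pair and
#' recomputes the MHD. The p-value is `(1 + #{perm MHD >= observed}) /
#' (1 + n_perm)` (add-one correction). Permutations whose pseudo-samples
#' yield no valid pair contribute MHD 0; their count is returned in the
#' `n_failed` attribute. With fewer usable reads than needed for any valid
#' pair the p-value is 1 with attribute `flag = "insufficient_reads"`.
#'
#' @param calls_i,calls_j Region call sets (or call matrices) of the two
#'   samples.
#' @param n_perm Number of permutations (default 200).
#' @param seed Integer seed; required for reproducibility.
#' @param observed_mhd Optional precomputed observed MHD (recomputed when
#'   NULL).
#' @param min_covered VMH threshold.
#' @inheritParams phase_region
#' @return p-value in (0, 1\].
#' @export
region_p_value <- function(calls_i, calls_j, n_perm = 200, seed = 1L,
                           observed_mhd = NULL, th_dp = 10, min_freq = 2,
                           single_ratio = 0.6, second_ratio = 0.4,
                           min_covered = 4L) {
  mi <- if (is.matrix(calls_i)) calls_i else calls_i$calls
  mj <- if (is.matrix(calls_j)) calls_j else calls_j$calls
  stopifnot(ncol(mi) == ncol(mj))
  pair_mhd <- function(a, b) {
    pa <- phase_region(a, "perm", th_dp, min_freq, single_ratio,
                       second_ratio)$pair
    pb <- phase_region(b, "perm", th_dp, min_freq, single_ratio,
                       second_ratio)$pair
    if (!is_valid_pair(pa, min_covered) || !is_valid_pair(pb, min_covered)) {
      return(NA_real_)
    }
    mhd(pa, pb)
  }
  if (is.null(observed_mhd)) {
    observed_mhd <- pair_mhd(mi, mj)
    if (is.na(observed_mhd)) {
      p <- 1
      attr(p, "flag") <- "no_valid_pair"
      return(p)
    }
  }
  ni <- nrow(mi); nj <- nrow(mj)
  if (ni + nj < 2 * min_covered) {
    p <- 1
    attr(p, "flag") <- "insufficient_reads"
    return(p)
  }
  pool <- rbind(mi, mj)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_ge <- 0L
  n_failed <- 0L
  for (b in seq_len(n_perm)) {
    take <- sample.int(ni + nj, ni)
    val <- pair_mhd(pool[take, , drop = FALSE],
                    pool[-take, , drop = FALSE])
    if (is.na(val)) {
      n_failed <- n_failed + 1L
      val <- 0
    }
    if (val >= observed_mhd) n_ge <- n_ge + 1L
  }
  p <- (1 + n_ge) / (1 + n_perm)
  attr(p, "n_failed") <- n_failed
  p
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Classify a DMR by its pair of methylation haplotype modes
#'
#' Types, evaluated with precedence 1 > 2 > 3 > 4:
#' \enumerate{
#'   \item hypomethylation mode (an MHM containing `L`) vs.
#'     non-hypomethylation mode (an MHM without `L`);
#'   \item hypomethylation-consistent `LL` vs. semi-hypomethylation (an
#'     inconsistent MHM containing `L`);
#'   \item hypermethylation-consistent `HH` vs. semi-hypermethylation (an
#'     inconsistent MHM containing `H`);
#'   \item any other differing mode pair.
#' }
#' Identical modes are not a DMR and return type NA.
#'
#' @param mhm_i,mhm_j Two-letter MHM strings (order-normalised internally).
#' @return `list(type, subtype)`; `subtype` is the ordered pair, e.g.
#'   `"LL vs HH"`.
#' @examples
#' classify_dmr("LL", "HH")
#' @export
classify_dmr <- function(mhm_i, mhm_j) {
  norm <- function(m) canonical_mhm(strsplit(m, "")[[1]])
  mi <- norm(mhm_i); mj <- norm(mhm_j)
  subtype <- paste(mi, "vs", mj)
  if (mi == mj) return(list(type = NA_integer_, subtype = subtype))
  hasL <- function(m) grepl("L", m, fixed = TRUE)
  hasH <- function(m) grepl("H", m, fixed = TRUE)
  type <- if (xor(hasL(mi), hasL(mj))) {
    1L
  } else if ((mi == "LL" && hasL(mj)) || (mj == "LL" && hasL(mi))) {
    2L
  } else if ((mi == "HH" && hasH(mj)) || (mj == "HH" && hasH(mi))) {
    3L
  } else {
    4L
  }
  list(type = type, subtype = subtype)
}

#' Call DMRs between two samples at haplotype resolution
#'
#' For each candidate region with a valid haplotype pair in both samples:
#' identical MHMs make the region a non-DMR without testing; otherwise the
#' MHD is computed and, when it exceeds `mhd_min`, a read-permutation
#' p-value is attached. A region is a DMR iff `MHD > mhd_min` and
#' `p < alpha`; DMRs are classified with [classify_dmr()].
#'
#' @param calls_1,calls_2 Named lists of region call sets, one per sample.
#' @param regions `candidate_regions` data frame.
#' @param mhd_min MHD threshold (default 0.5).
#' @param alpha Significance level on the permutation p-value (default
#'   0.05).
#' @param n_perm Permutations per tested region (default 200).
#' @param seed Base seed; each region uses a deterministic offset.
#' @param bh_fdr If TRUE, add a Benjamini-Hochberg adjusted p-value column
#'   `p_adj` and gate `is_dmr` on it instead of the raw p-value.
#' @inheritParams phase_region
#' @param min_covered VMH threshold.
#' @return Data frame with one row per region testable in both samples:
#'   `chrom`, `start`, `end`, `region_id`, `mhm_1`, `mhm_2`, `mhd`,
#'   `p_value`, `is_dmr`, `dmr_type`, `subtype`. `p_value` is NA for
#'   regions not reaching the MHD gate (their DMR status is already
#'   decided).
#' @export
call_dmrs <- function(calls_1, calls_2, regions, mhd_min = 0.5,
                      alpha = 0.05, n_perm = 200, seed = 1L,
                      th_dp = 10, min_freq = 2, single_ratio = 0.6,
                      second_ratio = 0.4, min_covered = 4L,
                      bh_fdr = FALSE) {
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    ci <- calls_1[[rid]]; cj <- calls_2[[rid]]
    if (is.null(ci) || is.null(cj)) next
    pi <- phase_region(ci, rid, th_dp, min_freq, single_ratio,
                       second_ratio)$pair
    pj <- phase_region(cj, rid, th_dp, min_freq, single_ratio,
                       second_ratio)$pair
    if (!is_valid_pair(pi, min_covered) || !is_valid_pair(pj, min_covered)) {
      next
    }
    row <- data.frame(chrom = regions$chrom[i], start = regions$start[i],
                      end = regions$end[i], region_id = rid,
                      mhm_1 = pi$mhm, mhm_2 = pj$mhm,
                      mhd = NA_real_, p_value = NA_real_, is_dmr = FALSE,
                      dmr_type = NA_integer_, subtype = NA_character_,
                      stringsAsFactors = FALSE)
    if (pi$mhm != pj$mhm) {
      row$mhd <- mhd(pi, pj)
      if (row$mhd > mhd_min) {
        region_seed <- (seed + i) %% .Machine$integer.max
        row$p_value <- as.numeric(region_p_value(
          ci, cj, n_perm = n_perm, seed = region_seed,
          observed_mhd = row$mhd, th_dp = th_dp, min_freq = min_freq,
          single_ratio = single_ratio, second_ratio = second_ratio,
          min_covered = min_covered))
      }
    } else {
      row$mhd <- 0
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = character(),
                      mhm_1 = character(), mhm_2 = character(),
                      mhd = numeric(), p_value = numeric(),
                      is_dmr = logical(), dmr_type = integer(),
                      subtype = character(), stringsAsFactors = FALSE)
    return(out)
  }
  p_gate <- out$p_value
  if (bh_fdr) {
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    p_gate <- out$p_adj
  }
  out$is_dmr <- !is.na(out$mhd) & out$mhd > mhd_min &
    !is.na(p_gate) & p_gate < alpha
  for (k in which(out$is_dmr)) {
    cl <- classify_dmr(out$mhm_1[k], out$mhm_2[k])
    out$dmr_type[k] <- cl$type
    out$subtype[k] <- cl$subtype
  }
  rownames(out) <- NULL
  out
}

#' Write a DMR table as TSV
#'
#' @param dmrs Data frame from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_tsv <- function(dmrs, path) {
  write.table(dmrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
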