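## Classification of CpG sites into methylation-homozygous and -heterozygous
## ones. "Zygosity" here is methylation zygosity: whether the two homologous
## chromosomes carry the same (homozygous) or different (heterozygous)
## methylation status at a CpG -- unrelated to genetic zygosity.
##
## Pipeline: depth filter -> initial per-site classification -> joint
## read-pattern filtering over neighboring candidate heterozygous sites
## (CHSs) -> sequential confidence-based chain resolution.

ZYG_CLASSES <- c("FILTERED", "HOMOZYGOUS", "CANDIDATE_HET", "HETEROZYGOUS",
                 "AMBIGUOUS")
PATTERNS <- c("00", "01", "10", "11")

#' Initial per-site zygosity classification
#'
#' Sites with depth below `th_dp` are filtered out. A surviving site showing
#' a single methylation status is homozygous for it. A site showing both
#' statuses is a candidate heterozygous site (CHS) when each status has at
#' least `th_dp / 2` observations; otherwise the minority count is treated as
#' sequencing / bisulfite-conversion noise and the site is homozygous for the
#' majority status.
#'
#' @param site_pileup Data frame as returned by [pileup()] (columns
#'   `cpg_index`, `n_meth`, `n_unmeth`, `depth`).
#' @param th_dp Depth threshold (default 10; must be at least 2).
#' @return Data frame `cpg_index`, `class`, `status` (0/1 for homozygous
#'   sites, NA otherwise).
#' @examples
#' initial_classify(data.frame(cpg_index = 1:3, n_meth = c(12, 6, 11),
#'                             n_unmeth = c(0, 5, 2),
#'                             depth = c(12, 11, 13)), th_dp = 10)
#' @export
initial_classify <- function(site_pileup, th_dp = 10) {
  if (th_dp < 2) stop("th_dp must be at least 2")
  n1 <- site_pileup$n_meth
  n0 <- site_pileup$n_unmeth
  depth <- n0 + n1
  cls <- rep("FILTERED", nrow(site_pileup))
  status <- rep(NA_integer_, nrow(site_pileup))
  deep <- depth >= th_dp
  chs <- deep & pmin(n0, n1) >= th_dp / 2
  hom <- deep & !chs
  cls[hom] <- "HOMOZYGOUS"
  status[hom] <- as.integer(n1[hom] > n0[hom])
  cls[chs] <- "CANDIDATE_HET"
  data.frame(cpg_index = site_pileup$cpg_index, class = cls,
             status = status, stringsAsFactors = FALSE)
}

#' Joint methylation patterns of two CpG sites on co-covering reads
#'
#' Counts the ordered status patterns `00`, `01`, `10`, `11` (status at `u`
#' first) over reads that cover both sites.
#'
#' @param call_set A region call set or bare call matrix.
#' @param u,v CpG indices (1-based, within the region).
#' @return Named integer vector of counts for `00`, `01`, `10`, `11`.
#' @export
joint_pattern_counts <- function(call_set, u, v) {
  calls <- if (is.matrix(call_set)) call_set else call_set$calls
  a <- calls[, u]; b <- calls[, v]
  ok <- !is.na(a) & !is.na(b)
  counts <- tabulate(2L * a[ok] + b[ok] + 1L, nbins = 4L)
  names(counts) <- PATTERNS
  counts
}

#' Select true-positive joint patterns
#'
#' Applies the frequency-ratio rules that separate genuine haplotype
#' patterns from error-derived ones. Patterns observed fewer than `min_freq`
#' times are dropped. If a unique maximum remains whose share of the
#' surviving total exceeds `single_ratio`, it is the single true pattern.
#' Otherwise, if an identifiable top pair remains whose second/first
#' frequency ratio is at least `second_ratio`, those two are the true
#' patterns. Unresolvable ties (three-way ties for the maximum, or ties for
#' second place) and empty survivals yield an empty set, marking the pair
#' ambiguous.
#'
#' @param counts Named pattern counts from [joint_pattern_counts()].
#' @param min_freq Minimum pattern frequency (default 2).
#' @param single_ratio Share of total required for a single true pattern
#'   (strict `>`; default 0.6).
#' @param second_ratio Minimum second/first frequency ratio for two true
#'   patterns (`>=`; default 0.4).
#' @return Named integer vector of the retained pattern counts (length 0, 1
#'   or 2).
#' @export
select_true_patterns <- function(counts, min_freq = 2, single_ratio = 0.6,
                                 second_ratio = 0.4) {
  f <- counts[counts >= min_freq]
  empty <- integer(0)
  if (length(f) == 0) return(empty)
  f <- sort(f, decreasing = TRUE)
  top <- f[1]
  n_top <- sum(f == top)
  if (n_top == 1 && top / sum(f) > single_ratio) return(f[1])
  if (n_top >= 3) return(empty)
  if (n_top == 2) return(f[1:2])
  if (length(f) == 1) return(empty)
  second <- f[2]
  if (sum(f == second) > 1) return(empty)
  if (second / top >= second_ratio) return(f[1:2])
  empty
}

## status sets observed at the first/second position of the true patterns
pattern_status_sets <- function(tp) {
  pats <- names(tp)
  list(u = unique(as.integer(substr(pats, 1, 1))),
       v = unique(as.integer(substr(pats, 2, 2))))
}

status_set_class <- function(s) {
  if (length(s) == 0) list(class = "AMBIGUOUS", status = NA_integer_)
  else if (length(s) == 2) list(class = "HETEROZYGOUS", status = NA_integer_)
  else list(class = "HOMOZYGOUS", status = s)
}

#' Reclassify a pair of neighboring CHSs from their true patterns
#'
#' A site is heterozygous iff both statuses appear at its position across the
#' true patterns; otherwise it is homozygous for the single status observed.
#' An empty pattern set leaves both sites ambiguous.
#'
#' @param true_patterns Named counts from [select_true_patterns()].
#' @return List with elements `u` and `v`, each `list(class, status)`.
#' @export
reclassify_from_patterns <- function(true_patterns) {
  if (length(true_patterns) == 0) {
    return(list(u = status_set_class(integer(0)),
                v = status_set_class(integer(0))))
  }
  sets <- pattern_status_sets(true_patterns)
  list(u = status_set_class(sets$u), v = status_set_class(sets$v))
}

#' Confidence of a neighboring-CHS pair
#'
#' The total frequency of the pair's true-positive patterns divided by the
#' maximum read depth among the CpG sites involved in the conflict (the pair
#' plus the next site, when present).
#'
#' @param true_patterns Named counts from [select_true_patterns()].
#' @param depths Depths of the sites entering the denominator (two at a
#'   region boundary, three inside a chain).
#' @return Confidence score in \[0, 1\]; 0 (with a warning) if all depths
#'   are 0.
#' @export
pattern_confidence <- function(true_patterns, depths) {
  m <- max(depths)
  if (m == 0) {
    warning("all depths zero; confidence undefined, returning 0")
    return(0)
  }
  sum(true_patterns) / m
}

#' Resolve a chain of candidate heterozygous sites
#'
#' Processes neighboring CHS pairs sequentially, left to right. The first
#' pair is classified from its true patterns. For each successive triple
#' (u, v, w) the confidences of (u, v) and (v, w) are compared over the
#' shared denominator (the maximum depth among u, v, w): if
#' `conf(u, v) >= conf(v, w)` the middle site keeps its class and `w` is
#' classified from the (v, w) patterns compatible with it; otherwise `v` is
#' revised from the (v, w) patterns. Earlier pairs are not revisited. An
#' isolated CHS (no neighbor) stays ambiguous.
#'
#' @param chs_indices CHS CpG indices in genomic order.
#' @param call_set Region call set or call matrix.
#' @param depths Per-site depths for the whole region (from [pileup()]).
#' @param min_freq,single_ratio,second_ratio Passed to
#'   [select_true_patterns()].
#' @return Data frame `cpg_index`, `class`, `status` for the CHS sites.
#' @export
resolve_chain <- function(chs_indices, call_set, depths, min_freq = 2,
                          single_ratio = 0.6, second_ratio = 0.4) {
  calls <- if (is.matrix(call_set)) call_set else call_set$calls
  m <- length(chs_indices)
  res <- data.frame(cpg_index = chs_indices,
                    class = rep("AMBIGUOUS", m),
                    status = rep(NA_integer_, m), stringsAsFactors = FALSE)
  if (m < 2) return(res)

  tp_of <- function(a, b) {
    select_true_patterns(joint_pattern_counts(calls, a, b), min_freq,
                         single_ratio, second_ratio)
  }
  set_site <- function(k, sc) {
    res$class[k] <<- sc$class
    res$status[k] <<- sc$status
  }

  tp_prev <- tp_of(chs_indices[1], chs_indices[2])
  cl <- reclassify_from_patterns(tp_prev)
  set_site(1, cl$u); set_site(2, cl$v)

  if (m >= 3) for (k in 2:(m - 1)) {
    u <- chs_indices[k - 1]; v <- chs_indices[k]; w <- chs_indices[k + 1]
    tp_next <- tp_of(v, w)
    maxd <- max(depths[c(u, v, w)])
    conf_uv <- if (maxd > 0) sum(tp_prev) / maxd else 0
    conf_vw <- if (maxd > 0) sum(tp_next) / maxd else 0
    if (conf_uv >= conf_vw) {
      ## v keeps its class; classify w from patterns compatible with v
      v_statuses <- if (res$class[k] == "HOMOZYGOUS") res$status[k] else 0:1
      compatible <- tp_next[as.integer(substr(names(tp_next), 1, 1)) %in%
                              v_statuses]
      if (length(compatible) > 0) {
        set_site(k + 1,
                 status_set_class(pattern_status_sets(compatible)$v))
      } else {
        set_site(k + 1, status_set_class(integer(0)))
      }
    } else {
      cl <- reclassify_from_patterns(tp_next)
      set_site(k, cl$u); set_site(k + 1, cl$v)
    }
    tp_prev <- tp_next
  }
  res
}
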