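## Synthetic paired-homolog bisulfite data with known truth. Reads are
## simulated at the CpG-call level (with optional SAM rendering carrying
## XM-style tags): the pipeline consumes calls, so nucleotide-level realism
## adds nothing testable.

#' Create a simulation scenario
#'
#' Builds synthetic candidate regions and a pair of 0/1 methylation
#' templates (one per homolog) for each region, according to `kind`:
#' \describe{
#'   \item{consistent}{both homologs identical; each region all-unmethylated
#'     with probability `hypo_frac`, else all-methylated. Downstream
#'     methylation consistency is 1 by construction.}
#'   \item{x_inactivation}{homolog 1 fully unmethylated, homolog 2 fully
#'     methylated in every region -- the female inactive-X situation; every
#'     region's mode is HL and consistency is 0.}
#'   \item{differentiation_shift}{homologs identical; each CpG methylated
#'     with probability `meth_rate`, shared by both homologs (partially
#'     methylated but consistent regions).}
#'   \item{cancer_like}{a fraction `het_frac` of regions is fully
#'     heterozygous (homolog 1 random, homolog 2 its complement, as in
#'     allele-specific methylation); the rest are consistent all-0/all-1
#'     regions.}
#'   \item{dmr_panel}{two samples over shared regions: sample 1 is
#'     all-unmethylated (mode LL) everywhere; in a fraction `dmr_frac` of
#'     regions sample 2 is all-methylated (mode HH, planted MHD 1), else
#'     identical to sample 1.}
#' }
#'
#' @param kind One of `"consistent"`, `"x_inactivation"`,
#'   `"differentiation_shift"`, `"cancer_like"`, `"dmr_panel"`.
#' @param n_regions Number of candidate regions (default 200).
#' @param cpg_range Range of CpG counts per region (default 7:13, matching
#'   typical CpG-island-derived regions).
#' @param depth Expected read depth per homolog (default 30).
#' @param error_rate Per-call status flip probability (default 0.01).
#' @param span Number of consecutive CpGs covered by one read; NULL (the
#'   default) covers the whole region, realistic for ~90 bp regions and
#'   WGBS read lengths. Larger values are clamped with a warning.
#' @param seed Integer seed; fixed seeds make scenarios fully reproducible.
#' @param hypo_frac,meth_rate,het_frac,dmr_frac Kind-specific parameters
#'   (defaults 0.5, 0.5, 0.3, 0.2).
#' @return For single-sample kinds, a `sim_scenario`: list with `kind`,
#'   `regions`, `templates` (per region `list(t1, t2)`), simulation
#'   parameters and a `truth` data frame (`region_id`, `t1`, `t2`, `mhm`).
#'   For `"dmr_panel"`, a `sim_panel`: list with shared `regions`, the two
#'   scenarios `sample_1`/`sample_2`, and a `truth` data frame with a
#'   planted `is_dmr` flag.
#' @export
make_scenario <- function(kind = c("consistent", "x_inactivation",
                                   "differentiation_shift", "cancer_like",
                                   "dmr_panel"),
                          n_regions = 200L, cpg_range = 7:13, depth = 30L,
                          error_rate = 0.01, span = NULL, seed = 1L,
                          hypo_frac = 0.5, meth_rate = 0.5, het_frac = 0.3,
                          dmr_frac = 0.2) {
  kind <- match.arg(kind)
  stopifnot(depth >= 1, error_rate >= 0, error_rate < 0.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  regions <- synthetic_regions(n_regions, cpg_range)
  n_cpg <- regions$cpg_count
  if (kind == "dmr_panel") {
    t_base <- lapply(n_cpg, function(n) rep(0L, n))
    is_dmr <- rep(FALSE, n_regions)
    is_dmr[sample.int(n_regions, round(dmr_frac * n_regions))] <- TRUE
    t_alt <- lapply(seq_len(n_regions), function(i) {
      if (is_dmr[i]) rep(1L, n_cpg[i]) else t_base[[i]]
    })
    s1 <- new_scenario("dmr_panel", regions,
                       lapply(t_base, function(t) list(t1 = t, t2 = t)),
                       depth, error_rate, span, seed)
    s2 <- new_scenario("dmr_panel", regions,
                       lapply(t_alt, function(t) list(t1 = t, t2 = t)),
                       depth, error_rate, span, seed + 1L)
    truth <- s1$truth
    truth$mhm_1 <- truth$mhm
    truth$mhm_2 <- s2$truth$mhm
    truth$mhm <- NULL
    truth$is_dmr <- is_dmr
    return(structure(list(kind = kind, regions = regions, sample_1 = s1,
                          sample_2 = s2, truth = truth, seed = seed),
                     class = "sim_panel"))
  }
  templates <- lapply(seq_len(n_regions), function(i) {
    n <- n_cpg[i]
    switch(kind,
      consistent = {
        t <- rep(if (runif(1) < hypo_frac) 0L else 1L, n)
        list(t1 = t, t2 = t)
      },
      x_inactivation = list(t1 = rep(0L, n), t2 = rep(1L, n)),
      differentiation_shift = {
        t <- rbinom(n, 1L, meth_rate)
        list(t1 = t, t2 = t)
      },
      cancer_like = {
        if (runif(1) < het_frac) {
          t1 <- rbinom(n, 1L, 0.5)
          list(t1 = t1, t2 = 1L - t1)
        } else {
          t <- rep(if (runif(1) < 0.5) 0L else 1L, n)
          list(t1 = t, t2 = t)
        }
      })
  })
  new_scenario(kind, regions, templates, depth, error_rate, span, seed)
}

new_scenario <- function(kind, regions, templates, depth, error_rate, span,
                         seed) {
  truth <- data.frame(
    region_id = regions$region_id,
    t1 = vapply(templates, function(t) paste(t$t1, collapse = ""),
                character(1)),
    t2 = vapply(templates, function(t) paste(t$t2, collapse = ""),
                character(1)),
    mhm = vapply(templates, function(t) {
      canonical_mhm(c(mh_label(mh_level(t$t1)), mh_label(mh_level(t$t2))))
    }, character(1)),
    stringsAsFactors = FALSE)
  structure(list(kind = kind, regions = regions, templates = templates,
                 depth = depth, error_rate = error_rate, span = span,
                 seed = seed, truth = truth),
            class = "sim_scenario")
}

## synthetic chromosome of candidate regions: CpGs gapped 2-18 bp inside a
## region (dense), regions separated by 1 kb
synthetic_regions <- function(n_regions, cpg_range) {
  pos0 <- 0L
  rows <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    n <- if (length(cpg_range) == 1) cpg_range else sample(cpg_range, 1)
    gaps <- sample(seq(2L, 18L, by = 2L), n - 1, replace = TRUE)
    pos <- pos0 + cumsum(c(0L, gaps))
    rows[[i]] <- region_row("chrSim", pos, "simulated")
    pos0 <- pos[length(pos)] + 1000L
  }
  regions <- do.call(rbind, rows)
  regions$region_id <- make_region_ids(regions$chrom)
  class(regions) <- c("candidate_regions", "data.frame")
  regions[, c("chrom", "start", "end", "region_id", "cpg_count", "source",
              "cpg_positions")]
}

#' Emit simulated reads for a scenario
#'
#' Each region receives exactly `depth` reads per homolog (2 * depth in
#' total, in random order, so the two homologs are balanced as in a diploid
#' library); every read covers a contiguous window of `span` CpGs with a
#' uniform start, and each call is flipped independently with probability
#' `error_rate`. Deterministic under the scenario's seed.
#'
#' @param scenario A `sim_scenario` from [make_scenario()].
#' @param seed Seed for read generation (defaults to the scenario seed).
#' @return Named list of region call sets, with a `truth_homolog` attribute
#'   per region recording each read's source homolog.
#' @export
emit_reads <- function(scenario, seed = scenario$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  regions <- scenario$regions
  out <- vector("list", nrow(regions))
  names(out) <- regions$region_id
  for (i in seq_len(nrow(regions))) {
    n_cpg <- regions$cpg_count[i]
    span <- scenario$span
    if (is.null(span)) span <- n_cpg
    if (span > n_cpg) {
      warning("read span ", span, " clamped to region CpG count ", n_cpg)
      span <- n_cpg
    }
    n_reads <- 2L * scenario$depth
    homolog <- sample(rep(1:2, each = scenario$depth))
    starts <- sample.int(n_cpg - span + 1L, n_reads, replace = TRUE)
    m <- matrix(NA_integer_, n_reads, n_cpg,
                dimnames = list(sprintf("read_%s_%04d",
                                        regions$region_id[i],
                                        seq_len(n_reads)), NULL))
    tmpl <- scenario$templates[[i]]
    for (r in seq_len(n_reads)) {
      idx <- starts[r]:(starts[r] + span - 1L)
      calls <- (if (homolog[r] == 1L) tmpl$t1 else tmpl$t2)[idx]
      flip <- runif(span) < scenario$error_rate
      m[r, idx] <- as.integer(xor(calls, flip))
    }
    cs <- new_read_call_set(regions$region_id[i], m)
    attr(cs, "truth_homolog") <- homolog
    out[[i]] <- cs
  }
  out
}

#' Write a scenario's truth table as TSV
#'
#' @param scenario A `sim_scenario` or `sim_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(scenario, path) {
  write.table(scenario$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Render simulated reads as a SAM file with Bismark-style XM tags
#'
#' Reads are laid on the synthetic chromosome: the sequence carries `CG` at
#' every CpG (shown as `C`+XM `Z` when methylated, bisulfite-converted
#' `T`+XM `z` when unmethylated) and `A` elsewhere. One `<len>M` CIGAR per
#' read; mapping quality 60.
#'
#' @param call_sets Region call sets from [emit_reads()].
#' @param regions The scenario's `candidate_regions`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(call_sets, regions, path) {
  chrom_len <- max(regions$end) + 100L
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", regions$chrom[1], "\tLN:", chrom_len))
  for (i in seq_len(nrow(regions))) {
    cs <- call_sets[[regions$region_id[i]]]
    pos <- regions$cpg_positions[[i]]
    m <- cs$calls
    for (r in seq_len(nrow(m))) {
      covered <- which(!is.na(m[r, ]))
      if (length(covered) == 0) next
      first <- pos[covered[1]]
      last <- pos[covered[length(covered)]] + 1L
      len <- last - first + 1L
      seq_chars <- rep("A", len)
      xm_chars <- rep(".", len)
      for (k in covered) {
        off <- pos[k] - first + 1L
        meth <- m[r, k] == 1L
        seq_chars[off] <- if (meth) "C" else "T"
        seq_chars[off + 1L] <- "G"
        xm_chars[off] <- if (meth) "Z" else "z"
      }
      lines <- c(lines, paste(
        rownames(m)[r], 0L, regions$chrom[i], first + 1L, 60L,
        paste0(len, "M"), "*", 0L, 0L, paste(seq_chars, collapse = ""),
        "*", paste0("XM:Z:", paste(xm_chars, collapse = "")),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Score pipeline output against a scenario's planted truth
#'
#' Compares reconstructed haplotype pairs and site classifications with the
#' scenario templates. A region is *recovered* when its pair matches the
#' templates on all covered sites, up to homolog swap; it is *fully
#' covered* when every region CpG is covered. Site-level truth: a CpG is
#' heterozygous when the templates differ there. Heterozygous-site recall
#' is the fraction of truly heterozygous sites classified HETEROZYGOUS;
#' homozygous-site misclassification is the fraction of truly homozygous
#' sites classified HETEROZYGOUS or homozygous for the wrong status
#' (filtered/ambiguous sites count as neither).
#'
#' @param hapset A `haplotype_set` from [build_haplotypes()] on the
#'   scenario's reads.
#' @param scenario The `sim_scenario` that generated the reads.
#' @return List with `regions` (per-region data frame: `region_id`,
#'   `recovered`, `fully_covered`, `n_covered`, `mhm`, `true_mhm`) and
#'   scalar summaries `recovery_rate`, `het_recall`, `hom_error`.
#' @export
score_against_truth <- function(hapset, scenario) {
  regs <- scenario$regions
  n_het_true <- 0L; n_het_found <- 0L
  n_hom_true <- 0L; n_hom_wrong <- 0L
  per_region <- vector("list", nrow(regs))
  for (i in seq_len(nrow(regs))) {
    rid <- regs$region_id[i]
    tmpl <- scenario$templates[[i]]
    pair <- hapset$pairs[[rid]]
    zyg <- hapset$zygosity[[rid]]
    cov <- pair$covered
    direct <- all(pair$s1 == tmpl$t1[cov]) && all(pair$s2 == tmpl$t2[cov])
    swapped <- all(pair$s1 == tmpl$t2[cov]) && all(pair$s2 == tmpl$t1[cov])
    per_region[[i]] <- data.frame(
      region_id = rid,
      recovered = length(cov) > 0 && (direct || swapped),
      fully_covered = length(cov) == regs$cpg_count[i],
      n_covered = length(cov), mhm = pair$mhm,
      true_mhm = scenario$truth$mhm[i], stringsAsFactors = FALSE)
    is_het <- tmpl$t1 != tmpl$t2
    n_het_true <- n_het_true + sum(is_het)
    n_het_found <- n_het_found +
      sum(zyg$class[is_het] == "HETEROZYGOUS")
    n_hom_true <- n_hom_true + sum(!is_het)
    hom_cls <- zyg$class[!is_het]
    hom_status <- zyg$status[!is_het]
    n_hom_wrong <- n_hom_wrong + sum(hom_cls == "HETEROZYGOUS") +
      sum(hom_cls == "HOMOZYGOUS" & hom_status != tmpl$t1[!is_het])
  }
  regions <- do.call(rbind, per_region)
  list(regions = regions,
       recovery_rate = mean(regions$recovered),
       het_recall = if (n_het_true > 0) n_het_found / n_het_true
                    else NA_real_,
       hom_error = if (n_hom_true > 0) n_hom_wrong / n_hom_true
                   else NA_real_)
}
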