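reads_matrix <- function(...) {
  do.call(rbind, lapply(list(...), function(r) {
    ch <- strsplit(r, "")[[1]]
    ifelse(ch == ".", NA_integer_, as.integer(ch == "1"))
  }))
}

test_that("skeletons chain heterozygous sites through phase parity", {
  # three het sites: pair (1,2) same-phase (00/11), pair (2,3) cross-phase
  # (01/10) -> skeletons 001 / 110
  m <- reads_matrix("001", "001", "001", "001", "110", "110", "110", "110")
  sk <- build_skeleton(c(1L, 2L, 3L), m)
  expect_equal(sk$sites, c(1L, 2L, 3L))
  expect_equal(sk$s1, c(0L, 0L, 1L))
  expect_equal(sk$s2, c(1L, 1L, 0L))
  # no het sites -> empty skeleton
  sk0 <- build_skeleton(integer(0), m)
  expect_equal(sk0$sites, integer(0))
  # a phase break keeps the longest prefix chain
  m2 <- rbind(reads_matrix("00.", "00.", "11.", "11."),
              reads_matrix("..0", "..1"))
  sk2 <- build_skeleton(c(1L, 2L, 3L), m2)
  expect_equal(sk2$sites, c(1L, 2L))
  expect_equal(sk2$n_dropped, 1L)
})

test_that("homozygous padding composes the full pair", {
  m <- reads_matrix("101", "101", "101", "111", "111", "111")
  sk <- build_skeleton(2L, m)
  pair <- pad_homozygous(sk, data.frame(cpg_index = c(1L, 3L),
                                        status = c(1L, 1L)), "rX")
  expect_equal(pair$covered, c(1L, 2L, 3L))
  expect_equal(pair$s1, c(1L, 0L, 1L))
  expect_equal(pair$s2, c(1L, 1L, 1L))
  # all-homozygous region: both haplotypes identical, mode LL
  pair0 <- pad_homozygous(build_skeleton(integer(0), m),
                          data.frame(cpg_index = 1:8,
                                     status = rep(0L, 8)), "rY")
  expect_equal(pair0$s1, rep(0L, 8))
  expect_equal(pair0$s2, rep(0L, 8))
  expect_equal(pair0$mhm, "LL")
})

test_that("MH level and labels match oracles exhaustively", {
  expect_equal(mh_level("0000"), 0)
  expect_equal(mh_level("0011"), 0.5)
  expect_equal(mh_level("111"), 1)
  # boundary labels are inclusive downward
  expect_equal(mh_label(0.25), "L")
  expect_equal(mh_label(0.5), "N")
  expect_equal(mh_label(0.75), "M")
  expect_equal(mh_label(0.76), "H")
  # exhaustive over all 0-1 strings of length <= 10
  for (len in 1:10) {
    for (code in 0:(2^len - 1)) {
      s <- paste(as.integer(intToBits(code))[len:1], collapse = "")
      expect_equal(mh_level(s), oracle_mh(s))
      expect_equal(mh_label(mh_level(s)), oracle_label(oracle_mh(s)))
    }
  }
})

test_that("MHM is canonical with the higher-MH label first", {
  mk <- function(s1, s2) {
    n <- nchar(s1)
    methaplotype:::new_haplotype_pair(
      "r", seq_len(n),
      as.integer(strsplit(s1, "")[[1]]), as.integer(strsplit(s2, "")[[1]]))
  }
  expect_equal(mhm(mk("1111", "0000")), "HL")
  expect_equal(mhm(mk("0000", "1111")), "HL")  # swap symmetric
  expect_equal(mhm(mk("0000", "0000")), "LL")
  expect_equal(mhm(mk("1100", "0011")), "NN")
  expect_equal(mhm(mk("0000", "0011")), "NL")
  expect_equal(mhm(mk("111111", "110000")), "HN")
  # the ten modes, as produced over representative MH pairs
  expect_setequal(all_mhms(),
                  c("LL", "HL", "NL", "ML", "NN", "MM", "MN", "HN", "HM",
                    "HH"))
})

test_that("VMH validity requires more than 3 covered CpGs", {
  mk <- function(n) methaplotype:::new_haplotype_pair("r", seq_len(n),
                                                      rep(0L, n),
                                                      rep(0L, n))
  expect_false(is_valid_pair(mk(3)))
  expect_true(is_valid_pair(mk(4)))
  expect_false(is_valid_pair(mk(0)))
})

test_that("consistency is CpG-weighted over valid pairs", {
  tab <- data.frame(region_id = c("a", "b"),
                    covered_cpg_count = c(5L, 5L),
                    mhm = c("LL", "HL"), valid = TRUE,
                    stringsAsFactors = FALSE)
  rep1 <- consistency_report(tab)
  expect_equal(rep1$methylation_consistency[1], 0.5)
  expect_equal(rep1$hypomethylation_consistency[1], 0.5)
  rep1b <- consistency_report(rbind(tab, data.frame(
    region_id = "c", covered_cpg_count = 10L, mhm = "HH", valid = TRUE)))
  expect_equal(rep1b$methylation_consistency[1], 0.75)
  expect_equal(rep1b$hypomethylation_consistency[1], 0.25)
  tab$mhm <- "LL"
  expect_equal(consistency_report(tab)$hypomethylation_consistency[1], 1)
  # invalid pairs are excluded; empty scope reports NA
  tab$valid <- FALSE
  expect_true(is.na(consistency_report(tab)$methylation_consistency[1]))
  # hypomethylation consistency never exceeds methylation consistency
  set.seed(8)
  tab2 <- data.frame(region_id = letters[1:20],
                     covered_cpg_count = sample(4:12, 20, replace = TRUE),
                     mhm = sample(all_mhms(), 20, replace = TRUE),
                     valid = TRUE, stringsAsFactors = FALSE)
  r <- consistency_report(tab2)
  expect_lte(r$hypomethylation_consistency[1],
             r$methylation_consistency[1])
})

test_that("homolog swap changes no derived quantity", {
  sc <- make_scenario("cancer_like", n_regions = 15, seed = 21)
  reads <- emit_reads(sc)
  for (rid in names(reads)[1:5]) {
    p <- phase_region(reads[[rid]], rid)$pair
    q <- methaplotype:::new_haplotype_pair(rid, p$covered, p$s2, p$s1)
    expect_equal(sort(c(p$mh1, p$mh2)), sort(c(q$mh1, q$mh2)))
    expect_equal(p$mhm, q$mhm)
    gi <- list(hi = max(p$mh1, p$mh2), lo = min(p$mh1, p$mh2))
    expect_equal(mhd(p, q), 0)
    expect_equal(mhd(gi, list(hi = 1, lo = 0.2)),
                 mhd(list(hi = 1, lo = 0.2), gi))
  }
})

test_that("simulated two-template regions reconstruct the planted pair", {
  sc <- make_scenario("x_inactivation", n_regions = 30, error_rate = 0,
                      seed = 4)
  hs <- build_haplotypes(emit_reads(sc), sc$regions)
  s <- score_against_truth(hs, sc)
  expect_equal(s$recovery_rate, 1)
  expect_true(all(hs$table$mhm == "HL"))
})
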