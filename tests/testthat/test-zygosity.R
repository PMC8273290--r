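pu_row <- function(n_meth, n_unmeth) {
  data.frame(cpg_index = 1L, n_meth = n_meth, n_unmeth = n_unmeth,
             depth = n_meth + n_unmeth)
}

test_that("initial classification follows the depth and status rules", {
  cases <- list(
    list(12, 0, "HOMOZYGOUS", 1L),    # single status at depth
    list(0, 15, "HOMOZYGOUS", 0L),
    list(6, 5, "CANDIDATE_HET", NA_integer_),  # both >= th_dp/2
    list(5, 5, "CANDIDATE_HET", NA_integer_),
    list(4, 4, "FILTERED", NA_integer_),       # depth 8 < 10
    list(9, 0, "FILTERED", NA_integer_),
    list(11, 2, "HOMOZYGOUS", 1L),    # minority treated as noise
    list(2, 11, "HOMOZYGOUS", 0L),
    list(6, 4, "HOMOZYGOUS", 1L))     # minor 4 < 5, depth 10
  for (cs in cases) {
    z <- initial_classify(pu_row(cs[[1]], cs[[2]]), th_dp = 10)
    expect_equal(z$class, cs[[3]],
                 label = sprintf("(%d,%d) class", cs[[1]], cs[[2]]))
    expect_equal(z$status, cs[[4]],
                 label = sprintf("(%d,%d) status", cs[[1]], cs[[2]]))
  }
  expect_error(initial_classify(pu_row(5, 5), th_dp = 1), "th_dp")
})

test_that("joint pattern counts equal a pairwise tally", {
  m <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(NA, 1L), c(1L, NA))
  f <- joint_pattern_counts(m, 1, 2)
  expect_equal(f, c("00" = 1L, "01" = 0L, "10" = 0L, "11" = 2L))
  expect_equal(joint_pattern_counts(matrix(NA_integer_, 3, 2), 1, 2),
               c("00" = 0L, "01" = 0L, "10" = 0L, "11" = 0L))
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(sample(c(0L, 1L, NA), 120, replace = TRUE), 40, 3)
    f <- joint_pattern_counts(m, 1, 3)
    for (p in c("00", "01", "10", "11")) {
      a <- as.integer(substr(p, 1, 1)); b <- as.integer(substr(p, 2, 2))
      expect_equal(unname(f[p]),
                   sum(m[, 1] == a & m[, 3] == b, na.rm = TRUE))
    }
  }
})

test_that("true-pattern selection applies the frequency-ratio rules", {
  tp <- select_true_patterns(c("11" = 20L, "01" = 2L, "00" = 1L,
                               "10" = 0L))
  expect_equal(names(tp), "11")         # 20/22 > 0.6 after filtering
  tp2 <- select_true_patterns(c("00" = 9L, "11" = 7L, "01" = 1L,
                                "10" = 0L))
  expect_setequal(names(tp2), c("00", "11"))  # 9/16 <= 0.6, 7/9 >= 0.4
  # three-way tie for the maximum -> ambiguous
  expect_length(select_true_patterns(c("00" = 5L, "11" = 5L, "01" = 5L,
                                       "10" = 0L)), 0)
  # second/first ratio below 0.4 and share below 0.6 -> ambiguous
  expect_length(select_true_patterns(c("00" = 10L, "11" = 3L, "01" = 7L,
                                       "10" = 0L)), 2)
  expect_length(select_true_patterns(c("00" = 10L, "11" = 3L, "01" = 9L,
                                       "10" = 0L)), 2)
  # share 10/17 below 0.6 and second/first 3/10 below 0.4 -> ambiguous
  expect_length(select_true_patterns(c("00" = 10L, "11" = 3L, "01" = 2L,
                                       "10" = 2L)), 0)
  # everything below min_freq -> ambiguous
  expect_length(select_true_patterns(c("00" = 1L, "11" = 1L, "01" = 1L,
                                       "10" = 0L)), 0)
  # tie for second place is unresolved
  expect_length(select_true_patterns(c("00" = 10L, "11" = 4L, "01" = 4L,
                                       "10" = 0L)), 0)
  # two-way tie for the maximum is an identifiable top pair
  expect_setequal(names(select_true_patterns(c("00" = 8L, "11" = 8L,
                                               "01" = 2L, "10" = 0L))),
                  c("00", "11"))
})

test_that("reclassification derives site classes from pattern status sets", {
  r <- reclassify_from_patterns(c("11" = 10L))
  expect_equal(r$u$class, "HOMOZYGOUS"); expect_equal(r$u$status, 1L)
  expect_equal(r$v$class, "HOMOZYGOUS"); expect_equal(r$v$status, 1L)
  r2 <- reclassify_from_patterns(c("00" = 8L, "11" = 7L))
  expect_equal(r2$u$class, "HETEROZYGOUS")
  expect_equal(r2$v$class, "HETEROZYGOUS")
  r3 <- reclassify_from_patterns(c("11" = 8L, "01" = 5L))
  expect_equal(r3$u$class, "HETEROZYGOUS")
  expect_equal(r3$v$class, "HOMOZYGOUS"); expect_equal(r3$v$status, 1L)
  r4 <- reclassify_from_patterns(integer(0))
  expect_equal(r4$u$class, "AMBIGUOUS")
})

test_that("pair confidence is total true-pattern frequency over max depth", {
  expect_equal(pattern_confidence(c("11" = 8L, "00" = 6L), c(15, 16, 20)),
               0.7)
  expect_equal(pattern_confidence(integer(0), c(10, 10, 10)), 0)
  expect_warning(p0 <- pattern_confidence(c("11" = 2L), c(0, 0, 0)),
                 "depths")
  expect_equal(p0, 0)
  set.seed(77)
  for (rep in 1:1000) {
    tp <- sample(0:20, sample(0:2, 1))
    names(tp) <- sample(c("00", "01", "10", "11"), length(tp))
    d <- sample(1:40, 3)
    expect_equal(pattern_confidence(tp, d), oracle_conf(tp, d))
  }
})

# build a call matrix from read strings; "." means site not covered
reads_matrix <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    ifelse(ch == ".", NA_integer_, as.integer(ch == "1"))
  }))
}

test_that("chain resolution classifies planted heterozygous pairs", {
  # two CHSs with clean 00/11 patterns -> both heterozygous
  m <- reads_matrix("00", "00", "00", "00", "00", "11", "11", "11", "11",
                    "11")
  res <- resolve_chain(c(1L, 2L), m, pileup(m)$depth)
  expect_equal(res$class, c("HETEROZYGOUS", "HETEROZYGOUS"))
  # an isolated CHS stays ambiguous
  res1 <- resolve_chain(1L, m[, 1, drop = FALSE], c(10))
  expect_equal(res1$class, "AMBIGUOUS")
})

test_that("higher-confidence pair wins a middle-site conflict", {
  # sites u, v strongly linked (00/11 x 10 reads); pair (v, w) has weaker,
  # conflicting evidence (only 4 co-covering reads, pattern 10)
  strong <- reads_matrix("00.", "00.", "00.", "00.", "00.", "11.", "11.",
                         "11.", "11.", "11.")
  weak <- rbind(c(NA, 1L, 0L), c(NA, 1L, 0L), c(NA, 1L, 0L),
                c(NA, 1L, 0L), c(NA, 0L, NA), c(NA, 0L, NA),
                c(NA, 0L, NA), c(NA, 0L, NA), c(NA, 0L, NA),
                c(NA, 0L, NA))
  m <- rbind(strong, weak)
  depths <- pileup(m)$depth
  res <- resolve_chain(c(1L, 2L, 3L), m, depths)
  # conf(u,v) = 10/20 vs conf(v,w) = 4/20: v keeps HETEROZYGOUS, and w is
  # classified from (v,w) patterns compatible with it
  expect_equal(res$class[2], "HETEROZYGOUS")
  expect_equal(res$class[3], "HOMOZYGOUS")
  expect_equal(res$status[3], 0L)
})

test_that("lower-confidence middle class is revised by the next pair", {
  # pair (u,v): only 3 co-covering reads, pattern 11 -> v looks homozygous;
  # pair (v,w): 10 reads with 00/11 -> v revised to heterozygous
  first <- rbind(c(1L, 1L, NA), c(1L, 1L, NA), c(1L, 1L, NA))
  second <- reads_matrix(".00", ".00", ".00", ".00", ".00", ".11", ".11",
                         ".11", ".11", ".11")
  m <- rbind(first, second)
  res <- resolve_chain(c(1L, 2L, 3L), m, pileup(m)$depth)
  expect_equal(res$class[2], "HETEROZYGOUS")
  expect_equal(res$class[3], "HETEROZYGOUS")
})

test_that("error-free two-template regions classify every site correctly", {
  sc <- make_scenario("cancer_like", n_regions = 40, error_rate = 0,
                      seed = 13)
  reads <- emit_reads(sc)
  hs <- build_haplotypes(reads, sc$regions)
  s <- score_against_truth(hs, sc)
  expect_equal(s$het_recall, 1)
  expect_equal(s$hom_error, 0)
})
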