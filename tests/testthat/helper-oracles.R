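# Independent brute-force oracles, deliberately coded with plain loops so
# they share no logic with the package implementations they check.

oracle_cpg_scan <- function(seq) {
  seq <- toupper(seq)
  hits <- integer(0)
  if (nchar(seq) < 2) return(hits)
  for (i in 1:(nchar(seq) - 1)) {
    if (substr(seq, i, i + 1) == "CG") hits <- c(hits, i - 1L)
  }
  hits
}

# balanced consecutive partition of a vector into k blocks, longest first
oracle_partition <- function(x, k) {
  n <- length(x)
  sizes <- integer(k)
  for (i in 1:k) sizes[i] <- n %/% k + (i <= n %% k)
  out <- list()
  at <- 1L
  for (i in 1:k) {
    out[[i]] <- x[at:(at + sizes[i] - 1L)]
    at <- at + sizes[i]
  }
  out
}

# brute-force candidate regions for one chromosome: list of
# list(positions, source)
oracle_regions <- function(positions, islands, max_gap = 20, min_cpg = 7) {
  out <- list()
  # island regions
  if (!is.null(islands) && nrow(islands) > 0) {
    for (r in seq_len(nrow(islands))) {
      inside <- positions[positions >= islands$start[r] &
                          positions < islands$end[r]]
      if (length(inside) >= min_cpg) {
        k <- length(inside) %/% min_cpg
        for (blk in oracle_partition(inside, k)) {
          out[[length(out) + 1L]] <- list(positions = blk,
                                          source = "island")
        }
      }
    }
  }
  # dense clusters outside islands
  outside <- positions
  if (!is.null(islands) && nrow(islands) > 0) {
    drop <- rep(FALSE, length(positions))
    for (r in seq_len(nrow(islands))) {
      drop <- drop | (positions >= islands$start[r] &
                      positions < islands$end[r])
    }
    outside <- positions[!drop]
  }
  run <- integer(0)
  flush_run <- function(run, out) {
    n <- length(run)
    if (n >= min_cpg) {
      if (n <= 2 * min_cpg) {
        out[[length(out) + 1L]] <- list(positions = run, source = "cluster")
      } else {
        for (blk in oracle_partition(run, n %/% min_cpg)) {
          out[[length(out) + 1L]] <- list(positions = blk,
                                          source = "cluster")
        }
      }
    }
    out
  }
  for (p in outside) {
    if (length(run) == 0 || p - run[length(run)] <= max_gap) {
      run <- c(run, p)
    } else {
      out <- flush_run(run, out)
      run <- p
    }
  }
  out <- flush_run(run, out)
  out[order(vapply(out, function(r) r$positions[1], numeric(1)))]
}

oracle_mh <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n1 <- 0
  for (ch in chars) if (ch == "1") n1 <- n1 + 1
  n1 / length(chars)
}

oracle_label <- function(mh) {
  if (mh <= 0.25) "L" else if (mh <= 0.5) "N" else if (mh <= 0.75) "M"
  else "H"
}

oracle_mhd <- function(hi_i, lo_i, hi_j, lo_j) {
  a <- abs(hi_i - hi_j)
  b <- abs(lo_i - lo_j)
  if (a > b) a else b
}

oracle_conf <- function(tp_counts, depths) {
  s <- 0
  for (v in tp_counts) s <- s + v
  s / max(depths)
}

# DMR type rules restated independently (precedence 1 > 2 > 3 > 4)
oracle_dmr_type <- function(a, b) {
  La <- grepl("L", a); Lb <- grepl("L", b)
  Ha <- grepl("H", a); Hb <- grepl("H", b)
  if (a == b) return(NA_integer_)
  if ((La && !Lb) || (Lb && !La)) return(1L)
  if ((a == "LL" && Lb && b != "LL") || (b == "LL" && La && a != "LL")) {
    return(2L)
  }
  if ((a == "HH" && Hb && b != "HH") || (b == "HH" && Ha && a != "HH")) {
    return(3L)
  }
  4L
}

# all canonical two-label modes (higher label first, rank H > M > N > L)
all_mhms <- function() {
  lab <- c("H", "M", "N", "L")
  out <- character(0)
  for (i in 1:4) for (j in i:4) {
    out <- c(out, paste0(lab[i], lab[j]))
  }
  out
}

# random binary string of length n
rand_bits <- function(n) paste(sample(c("0", "1"), n, replace = TRUE),
                               collapse = "")
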