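# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive (explicit character loops) so they share no code with
# the package implementation beyond the pinned data tables.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptides <- function(n, min_len, max_len, seed) {
  withr::with_seed(seed, {
    lens <- sample(min_len:max_len, n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

oracle_classes <- function(seq, part) {
  chars <- strsplit(seq, "")[[1]]
  out <- integer(length(chars))
  for (i in seq_along(chars)) {
    for (k in 1:3) {
      if (chars[i] %in% part[[as.character(k)]]) out[i] <- k
    }
  }
  out
}

# all 21 CTD values (3 C, 3 T, 15 D) for one partition, by hand counting
oracle_ctd <- function(seq, part) {
  v <- oracle_classes(seq, part)
  L <- length(v)
  comp <- c(sum(v == 1), sum(v == 2), sum(v == 3)) / L
  tr <- c(0, 0, 0)
  if (L >= 2) {
    n12 <- n13 <- n23 <- 0
    for (i in 1:(L - 1)) {
      p <- sort(c(v[i], v[i + 1]))
      if (p[1] == 1 && p[2] == 2) n12 <- n12 + 1
      if (p[1] == 1 && p[2] == 3) n13 <- n13 + 1
      if (p[1] == 2 && p[2] == 3) n23 <- n23 + 1
    }
    tr <- c(n12, n13, n23) / (L - 1)
  }
  dist <- numeric(15)
  fr <- c(0, 0.25, 0.5, 0.75, 1)
  for (k in 1:3) {
    pos <- which(v == k)
    nk <- length(pos)
    if (nk > 0) {
      for (j in 1:5) {
        rk <- max(1, ceiling(fr[j] * nk))
        dist[(k - 1) * 5 + j] <- 100 * pos[rk] / L
      }
    }
  }
  c(comp, tr, dist)
}

oracle_instability <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  s <- 0
  for (i in 1:(length(chars) - 1)) {
    s <- s + pepstack:::DIWV[chars[i], chars[i + 1]]
  }
  10 * s / length(chars)
}

oracle_confusion <- function(pred_class, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(truth)) {
    if (pred_class[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred_class[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred_class[i] == 0 && truth[i] == 1) fn <- fn + 1
    if (pred_class[i] == 0 && truth[i] == 0) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# hand-coded trypsin site finder: cleave after K or R unless the next
# residue is P, except that WK^P and MR^P are cleaved anyway
oracle_trypsin_fragments <- function(s) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  sites <- integer(0)
  for (pos in 1:(L - 1)) {
    cleaves <- FALSE
    if (chars[pos] %in% c("K", "R") && chars[pos + 1] != "P") cleaves <- TRUE
    if (pos >= 2 && chars[pos] == "K" && chars[pos - 1] == "W" &&
        chars[pos + 1] == "P") cleaves <- TRUE
    if (pos >= 2 && chars[pos] == "R" && chars[pos - 1] == "M" &&
        chars[pos + 1] == "P") cleaves <- TRUE
    if (cleaves) sites <- c(sites, pos)
  }
  bounds <- c(0L, sites, L)
  substring(s, bounds[-length(bounds)] + 1L, bounds[-1L])
}

# brute-force candidate pooling: apply each rule via cleave(), then do the
# union / dedup / length filtering independently
oracle_enumerate <- function(proteome_seqs, rules, min_len, max_len,
                             missed_cleavages = 0L) {
  all_seqs <- character(0)
  for (s in proteome_seqs) {
    for (r in rules) {
      all_seqs <- c(all_seqs, cleave(s, r, missed_cleavages))
    }
  }
  keep <- nchar(all_seqs) >= min_len & nchar(all_seqs) <= max_len
  unique(all_seqs[keep])
}

# benchmark fixture: trained stack on the 500/class synthetic benchmark,
# built once per test run and shared across files
.fixture_env <- new.env(parent = emptyenv())

benchmark_result <- function() {
  if (is.null(.fixture_env$benchmark)) {
    ps <- generate_labeled_set(
      generator_config(n_per_class = 500L, signal_strength = 1.0,
                       seed = 40L))
    .fixture_env$benchmark <- run_pipeline(ps, outdir = NULL)
  }
  .fixture_env$benchmark
}
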