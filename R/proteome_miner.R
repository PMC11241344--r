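# In-silico proteolytic digestion and candidate mining: cleave proteins with
# enzymatic rules, length-filter the fragments, thin them by composition
# diversity, and rank the survivors by predicted cell-penetration
# probability.

#' The enzymatic cleavage-rule registry
#'
#' Named Perl-compatible regular expressions for 35 ExPASy-style proteases
#' and chemical cleavage agents (trypsin, chymotrypsin, pepsin, CNBr, the
#' caspases, ...). Each pattern's consumed text is the residue after which
#' the backbone is cleaved; lookarounds express context such as trypsin's
#' "not before proline".
#'
#' @return Named character vector of 35 rules.
#' @export
cleavage_rules <- function() CLEAVAGE_RULES

#' Cleave a protein with an enzymatic rule
#'
#' Splits the sequence after every position matched by the rule. With
#' `missed_cleavages = m`, every run of up to `m + 1` consecutive fragments
#' is also emitted. At `missed_cleavages = 0` the fragments concatenate back
#' to the protein exactly.
#'
#' @param seq Protein sequence (character scalar).
#' @param rule A rule name from [cleavage_rules()] or a regex pattern.
#' @param missed_cleavages Maximum number of internal sites a fragment may
#'   span (default 0).
#' @return Character vector of fragments, in sequence order (runs ordered by
#'   start position, then length).
#' @export
cleave <- function(seq, rule = "trypsin", missed_cleavages = 0L) {
  if (rule %in% names(CLEAVAGE_RULES)) {
    pattern <- CLEAVAGE_RULES[[rule]]
  } else if (grepl("[[(?\\\\^]", rule) || nchar(rule) == 1L) {
    pattern <- rule
  } else {
    stop("unknown cleavage rule '", rule, "'; registry: ",
         paste(names(CLEAVAGE_RULES), collapse = ", "), call. = FALSE)
  }
  L <- nchar(seq)
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  sites <- integer(0)
  if (m[1] != -1L) {
    sites <- as.integer(m) + attr(m, "match.length") - 1L  # cleave after
    sites <- sites[sites >= 1L & sites < L]
  }
  bounds <- c(0L, sites, L)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nfrag <- length(starts)
  out <- character(0)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + missed_cleavages)) {
      out <- c(out, substr(seq, starts[i], ends[j]))
    }
  }
  out
}

count_cleavage_sites <- function(seq, rule = "trypsin") {
  length(cleave(seq, rule, missed_cleavages = 0L)) - 1L
}

#' Enumerate digestion candidates from a proteome
#'
#' Applies every rule to every protein, pools the fragments, deduplicates by
#' sequence (first occurrence kept) and keeps those inside the length
#' window.
#'
#' @param proteome A [peptide_set()] of protein sequences.
#' @param rules Rule names (default: the full 35-rule registry).
#' @param min_len,max_len Length window for candidates (default 9--35).
#' @param missed_cleavages Passed to [cleave()].
#' @return A [peptide_set()] of unique candidate peptides; ids record the
#'   source protein and rule of first occurrence.
#' @export
enumerate_candidates <- function(proteome, rules = names(cleavage_rules()),
                                 min_len = 9L, max_len = 35L,
                                 missed_cleavages = 0L) {
  if (nrow(proteome) == 0L) {
    warning("empty proteome; no candidates")
    return(peptide_set(character(), character())[0, ])
  }
  seqs <- character(0)
  src <- character(0)
  rl <- character(0)
  for (i in seq_len(nrow(proteome))) {
    for (r in rules) {
      frags <- cleave(proteome$seq[i], r, missed_cleavages)
      len <- nchar(frags)
      keep <- len >= min_len & len <= max_len
      seqs <- c(seqs, frags[keep])
      src <- c(src, rep(proteome$id[i], sum(keep)))
      rl <- c(rl, rep(r, sum(keep)))
    }
  }
  first <- !duplicated(seqs)
  out <- peptide_set(paste0(src[first], "|", rl[first]), seqs[first],
                     provenance = "digestion candidates")
  attr(out, "source") <- data.frame(id = out$id, source_protein = src[first],
                                    rule = rl[first],
                                    stringsAsFactors = FALSE)
  out
}

aa_composition <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  tabulate(match(v, AA_ALPHABET), nbins = 20L) / length(v)
}

#' Composition-diversity filter
#'
#' Greedy thinning of a candidate list by amino-acid composition: scanning
#' in input order, a candidate is dropped if the L1 distance between its
#' 20-component composition vector and that of any already-kept candidate is
#' below the threshold. This enforces a minimum compositional spacing of
#' `threshold` among survivors; `threshold = 0` disables the filter.
#'
#' @param candidates A [peptide_set()].
#' @param threshold Minimum L1 composition distance in (0, 1] (default
#'   0.30), or 0 to disable.
#' @return The filtered [peptide_set()].
#' @export
diversity_filter <- function(candidates, threshold = 0.30) {
  if (threshold == 0) return(candidates)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  comp <- t(vapply(candidates$seq, aa_composition, numeric(20L)))
  keep_idx <- integer(0)
  for (i in seq_len(n)) {
    if (length(keep_idx) == 0L) {
      keep_idx <- i
      next
    }
    d <- rowSums(abs(comp[keep_idx, , drop = FALSE] -
                       matrix(comp[i, ], length(keep_idx), 20L,
                              byrow = TRUE)))
    if (all(d >= threshold)) keep_idx <- c(keep_idx, i)
  }
  out <- candidates[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(candidates, "provenance")
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' Mine a proteome for candidate cell-penetrating peptides
#'
#' Runs the full mining chain: enzymatic digestion over the rule registry,
#' length filtering (9--35 by default), composition-diversity thinning,
#' featurization, ensemble prediction, and ranking by predicted probability.
#'
#' @param proteome A [peptide_set()] of protein sequences.
#' @param model A `trained_ensemble` from [train_stack()].
#' @param top_k Number of top-ranked candidates to return (default 50;
#'   larger than the candidate count returns all).
#' @param rules,min_len,max_len,missed_cleavages Passed to
#'   [enumerate_candidates()].
#' @param diversity_threshold Passed to [diversity_filter()]; 0 disables.
#' @param ph pH for featurization.
#' @return A `candidate_table`: data frame with columns `seq`,
#'   `source_protein`, `rule`, `probability`, `class`, sorted by decreasing
#'   probability. The attribute `"n_candidates"` records the number of
#'   candidates scored before truncation to `top_k`.
#' @export
mine <- function(proteome, model, top_k = 50L,
                 rules = names(cleavage_rules()), min_len = 9L,
                 max_len = 35L, missed_cleavages = 0L,
                 diversity_threshold = 0.30, ph = 7.0) {
  cand <- enumerate_candidates(proteome, rules, min_len, max_len,
                               missed_cleavages)
  src <- attr(cand, "source")
  cand <- diversity_filter(cand, diversity_threshold)
  if (nrow(cand) == 0L) {
    warning("no candidates after filtering")
    return(data.frame(seq = character(), source_protein = character(),
                      rule = character(), probability = numeric(),
                      class = integer()))
  }
  fm <- featurize(cand, ph = ph)
  pred <- stats::predict(model, fm)
  src <- src[match(cand$id, src$id), ]
  tab <- data.frame(seq = cand$seq,
                    source_protein = src$source_protein,
                    rule = src$rule,
                    probability = pred$probability,
                    class = pred$class,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$probability, tab$seq), , drop = FALSE]
  rownames(tab) <- NULL
  n_all <- nrow(tab)
  tab <- utils::head(tab, top_k)
  attr(tab, "n_candidates") <- n_all
  class(tab) <- c("candidate_table", "data.frame")
  tab
}
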