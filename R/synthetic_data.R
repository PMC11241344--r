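# Synthetic labeled peptide sets and toy proteomes, so every pipeline stage
# can be exercised and benchmarked without downloading any database.
#
# The positive class emulates the hallmark of known cell-penetrating
# peptides -- enrichment in cationic (R, K) and aromatic/hydrophobic (W, L)
# residues -- against a near-uniform background composition. signal_strength
# interpolates the positive-class residue table toward the background, so 0
# makes the classes exchangeable and 1 gives the full compositional signal.

default_cpp_bias <- function() {
  freq <- rep((1 - 0.53) / 16, 20)
  names(freq) <- AA_ALPHABET
  freq[c("R", "K", "W", "L")] <- c(0.20, 0.15, 0.08, 0.10)
  freq
}

default_background <- function() {
  stats::setNames(rep(0.05, 20), AA_ALPHABET)
}

#' Generator configuration for synthetic labeled peptide sets
#'
#' @param n_per_class Number of peptides per class.
#' @param length_range Inclusive length window, default `c(5, 30)`.
#' @param seed Integer seed.
#' @param signal_strength In \eqn{[0, 1]}: 1 draws the positive class from
#'   the full cationic/aromatic bias table, 0 from the background (classes
#'   exchangeable).
#' @param cpp_bias,background Residue-frequency tables (named over the 20
#'   residues, summing to 1). Defaults: bias R 0.20, K 0.15, W 0.08,
#'   L 0.10, remainder shared; background uniform.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_class = 500L, length_range = c(5L, 30L),
                             seed = 40L, signal_strength = 1.0,
                             cpp_bias = default_cpp_bias(),
                             background = default_background()) {
  stopifnot(n_per_class >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2], length_range[1] >= 2L,
            signal_strength >= 0, signal_strength <= 1)
  for (tab in list(cpp_bias, background)) {
    if (any(tab < 0) || sum(tab) <= 0) {
      stop("degenerate residue-frequency table", call. = FALSE)
    }
    if (!setequal(names(tab), AA_ALPHABET)) {
      stop("frequency table must be named over the 20 residues",
           call. = FALSE)
    }
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed),
                 signal_strength = signal_strength,
                 cpp_bias = cpp_bias / sum(cpp_bias),
                 background = background / sum(background)),
            class = "generator_config")
}

sample_peptides <- function(n, freq, length_range) {
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE,
                 prob = freq[AA_ALPHABET]), collapse = "")
  }, character(1))
}

#' Generate a labeled synthetic peptide set
#'
#' Draws `n_per_class` positive-class peptides from the (interpolated) bias
#' table and the same number of background peptides, with lengths uniform in
#' the configured window. Deterministic per seed.
#'
#' @param cfg A [generator_config()].
#' @return A labeled [peptide_set()] (label 1 = CPP-like, 0 = background).
#' @export
generate_labeled_set <- function(cfg = generator_config()) {
  s <- cfg$signal_strength
  pos_freq <- s * cfg$cpp_bias + (1 - s) * cfg$background
  withr::with_seed(cfg$seed, {
    pos <- sample_peptides(cfg$n_per_class, pos_freq, cfg$length_range)
    neg <- sample_peptides(cfg$n_per_class, cfg$background, cfg$length_range)
  })
  n <- cfg$n_per_class
  peptide_set(
    id = c(sprintf("cpp_%04d", seq_len(n)), sprintf("bg_%04d", seq_len(n))),
    seq = c(pos, neg),
    label = rep(c(1L, 0L), each = n),
    provenance = sprintf("synthetic (signal %.2f, seed %d)", s, cfg$seed))
}

#' Generate a toy proteome, optionally with an embedded spike peptide
#'
#' Background-composition proteins of the given length. If `spike` is
#' given, it is embedded verbatim at the C-terminus of the first protein,
#' preceded by a lysine, so that tryptic digestion with enough missed
#' cleavages recovers the spike exactly (the required missed-cleavage count,
#' the number of internal tryptic sites of the spike, is returned in the
#' `"spike"` attribute).
#'
#' @param n_proteins Number of proteins.
#' @param length Protein length (residues).
#' @param spike Optional peptide sequence to embed.
#' @param seed Integer seed.
#' @return A [peptide_set()]; if spiked, attribute `"spike"` holds
#'   `list(seq, protein_id, min_missed_cleavages)`.
#' @export
generate_toy_proteome <- function(n_proteins = 20L, length = 200L,
                                  spike = NULL, seed = 40L) {
  stopifnot(n_proteins >= 1L, length >= 10L)
  bg <- default_background()
  prots <- withr::with_seed(seed,
    sample_peptides(n_proteins, bg, c(length, length)))
  spike_info <- NULL
  if (!is.null(spike)) {
    spike <- toupper(spike)
    if (nchar(spike) + 1L > length) {
      stop("spike longer than protein length", call. = FALSE)
    }
    if (startsWith(spike, "P")) {
      stop("spike starting with proline cannot be preceded by a tryptic ",
           "site", call. = FALSE)
    }
    left <- substr(prots[1], 1L, length - nchar(spike) - 1L)
    prots[1] <- paste0(left, "K", spike)
    spike_info <- list(seq = spike, protein_id = "prot_0001",
                       min_missed_cleavages =
                         count_cleavage_sites(spike, "trypsin"))
  }
  out <- peptide_set(sprintf("prot_%04d", seq_len(n_proteins)), prots,
                     provenance = sprintf("toy proteome (seed %d)", seed))
  attr(out, "spike") <- spike_info
  out
}
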