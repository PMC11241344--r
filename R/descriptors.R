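# CTD (composition / transition / distribution) descriptors over the seven
# three-class property partitions, the Guruprasad instability index, and a
# small suite of global physicochemical descriptors.

partition_classes <- function(partition) {
  if (is.character(partition) && length(partition) == 1L) {
    partition <- PROPERTY_PARTITIONS[[match.arg(partition,
                                                names(PROPERTY_PARTITIONS))]]
  }
  cls <- integer(20L)
  names(cls) <- AA_ALPHABET
  for (k in 1:3) cls[partition[[as.character(k)]]] <- k
  cls
}

seq_to_classes <- function(seq, cls) {
  unname(cls[strsplit(seq, "")[[1]]])
}

#' CTD composition descriptors
#'
#' Fraction of residues falling in each of the three classes of a property
#' partition: \eqn{C_k = n_k / L}.
#'
#' @param seq Amino-acid sequence (character scalar, natural residues only).
#' @param partition Partition name (one of
#'   `names(PROPERTY_PARTITIONS)`: hydrophobicity, normalized_vdw_volume,
#'   polarity, polarizability, charge, secondary_structure,
#'   solvent_accessibility) or a partition list.
#' @return Numeric vector of three fractions summing to 1.
#' @export
ctd_composition <- function(seq, partition) {
  v <- seq_to_classes(seq, partition_classes(partition))
  tabulate(v, nbins = 3L) / length(v)
}

#' CTD transition descriptors
#'
#' Frequency of adjacent residue pairs whose classes differ:
#' \eqn{T_{kl} = (n_{kl} + n_{lk}) / (L - 1)} for the unordered class pairs
#' (1,2), (1,3), (2,3). A single-residue sequence has no adjacent pairs and
#' returns zeros with a warning.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of three transition frequencies, order
#'   (1,2), (1,3), (2,3).
#' @export
ctd_transition <- function(seq, partition) {
  v <- seq_to_classes(seq, partition_classes(partition))
  L <- length(v)
  if (L < 2L) {
    warning("transition undefined for a single residue; returning zeros")
    return(c(0, 0, 0))
  }
  a <- v[-L]
  b <- v[-1L]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  c(sum(lo == 1L & hi == 2L),
    sum(lo == 1L & hi == 3L),
    sum(lo == 2L & hi == 3L)) / (L - 1L)
}

#' CTD distribution descriptors
#'
#' Positional percentiles of each class along the sequence. For class k with
#' \eqn{n_k > 0} occurrences, the reported values are \eqn{100 \cdot pos / L}
#' for the occurrences at ranks \eqn{\max(1, \lceil f \cdot n_k \rceil)},
#' \eqn{f \in \{0, 0.25, 0.50, 0.75, 1\}} (so f = 0 reports the first
#' occurrence). An absent class reports five zeros. Rounding conventions
#' differ between published CTD implementations; this ceiling convention is
#' pinned here and mirrored by the test oracle.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of 15 values (5 per class, classes 1..3).
#' @export
ctd_distribution <- function(seq, partition) {
  v <- seq_to_classes(seq, partition_classes(partition))
  L <- length(v)
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  out <- numeric(15L)
  for (k in 1:3) {
    pos <- which(v == k)
    nk <- length(pos)
    if (nk > 0L) {
      ranks <- pmax(1L, ceiling(fracs * nk))
      out[(k - 1L) * 5L + seq_len(5L)] <- 100 * pos[ranks] / L
    }
  }
  out
}

#' Instability index
#'
#' Guruprasad dipeptide-weight instability index:
#' \eqn{II = (10 / L) \sum_{i=1}^{L-1} DIWV(x_i, x_{i+1})}.
#'
#' @inheritParams ctd_composition
#' @return The instability index (dimensionless).
#' @export
instability_index <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  if (L < 2L) stop("instability index undefined for length < 2", call. = FALSE)
  idx <- cbind(match(v[-L], AA_ALPHABET), match(v[-1L], AA_ALPHABET))
  (10 / L) * sum(DIWV[idx])
}

#' Net peptide charge at a given pH
#'
#' Henderson--Hasselbalch sum over the ionizable groups (free termini plus
#' the side chains of D, E, C, Y, H, K, R) with the EMBOSS pKa set
#' (`PKA_SET` in this package).
#'
#' @inheritParams ctd_composition
#' @param ph pH at which to evaluate the charge (default 7.0).
#' @return Net charge in elementary charge units.
#' @export
net_charge <- function(seq, ph = 7.0) {
  stopifnot(ph > 0, ph < 14)
  v <- strsplit(seq, "")[[1]]
  n_pos <- c(nterm = 1, H = sum(v == "H"), K = sum(v == "K"),
             R = sum(v == "R"))
  n_neg <- c(cterm = 1, C = sum(v == "C"), D = sum(v == "D"),
             E = sum(v == "E"), Y = sum(v == "Y"))
  pos <- sum(n_pos / (1 + 10^(ph - PKA_SET[names(n_pos)])))
  neg <- sum(n_neg / (1 + 10^(PKA_SET[names(n_neg)] - ph)))
  pos - neg
}

#' Isoelectric point
#'
#' pH at which [net_charge()] is zero, found by bisection on (0, 14).
#'
#' @inheritParams ctd_composition
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(seq) {
  stats::uniroot(function(ph) net_charge(seq, ph),
                 interval = c(1e-4, 14 - 1e-4), tol = 1e-8)$root
}

#' Global physicochemical descriptors
#'
#' Length, molecular weight (average residue masses + one water), net charge
#' at `ph`, charge density (net charge / molecular weight), isoelectric
#' point, aromaticity (fraction of F, W, Y), aliphatic index
#' (\eqn{100 (n_A + 2.9 n_V + 3.9 (n_I + n_L)) / L}), and hydrophobic ratio
#' (fraction of residues in the hydrophobic class C, L, V, I, M, F, W).
#'
#' @inheritParams ctd_composition
#' @param ph pH for the charge descriptors.
#' @return Named numeric vector of 8 descriptors.
#' @export
global_descriptors <- function(seq, ph = 7.0) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  mw <- sum(RESIDUE_MASS[v]) + WATER_MASS
  nc <- net_charge(seq, ph)
  c(length = L,
    molecular_weight = unname(mw),
    net_charge = nc,
    charge_density = nc / mw,
    isoelectric_point = isoelectric_point(seq),
    aromaticity = sum(v %in% AROMATIC_SET) / L,
    aliphatic_index = 100 * (sum(v == "A") + 2.9 * sum(v == "V") +
                               3.9 * (sum(v == "I") + sum(v == "L"))) / L,
    hydrophobic_ratio = sum(v %in% HYDROPHOBIC_SET) / L)
}

ctd_feature_names <- function() {
  unlist(lapply(names(PROPERTY_PARTITIONS), function(p) {
    c(paste0(p, ".C", 1:3),
      paste0(p, ".T", c("12", "13", "23")),
      paste0(p, ".D", rep(1:3, each = 5), ".",
             rep(c("000", "025", "050", "075", "100"), 3)))
  }))
}

descriptor_names <- function(ph = 7.0) {
  c(ctd_feature_names(), "instability_index",
    names(global_descriptors("AC", ph)))
}

#' Featurize a peptide set
#'
#' Computes the full descriptor vector for every record: 147 CTD descriptors
#' (7 partitions x (3 composition + 3 transition + 15 distribution)), the
#' instability index, and the 8 global descriptors of
#' [global_descriptors()]. Column names and order are deterministic; labels
#' are carried through. All peptides must be valid natural-residue sequences
#' of length >= 2.
#'
#' @param ps A [peptide_set()].
#' @param ph pH for the charge descriptors (default 7.0).
#' @return A `feature_matrix`: data frame with columns `id`, `label`, then
#'   one numeric column per descriptor.
#' @export
featurize <- function(ps, ph = 7.0) {
  bad <- !is_natural(ps$seq) | nchar(ps$seq) < 2L
  if (any(bad)) {
    stop("cannot featurize records (non-natural residues or length < 2): ",
         paste(utils::head(ps$id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  parts <- names(PROPERTY_PARTITIONS)
  rows <- lapply(ps$seq, function(s) {
    ctd <- unlist(lapply(parts, function(p) {
      c(ctd_composition(s, p), ctd_transition(s, p), ctd_distribution(s, p))
    }))
    c(ctd, instability_index(s), global_descriptors(s, ph))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- descriptor_names(ph)
  out <- data.frame(id = ps$id, label = ps$label, mat,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Descriptor column names of a feature matrix
#' @param fm A `feature_matrix` from [featurize()].
#' @return Character vector of descriptor column names.
#' @export
feature_names <- function(fm) {
  setdiff(names(fm), c("id", "label"))
}

feature_values <- function(fm, cols = feature_names(fm)) {
  as.matrix(fm[, cols, drop = FALSE])
}
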