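#' Construct a peptide set
#'
#' A `peptide_set` is a data frame with columns `id`, `seq` and `label`
#' (1 = cell-penetrating, 0 = not, `NA` = unlabeled) plus a free-text
#' `provenance` attribute. Sequences are uppercased on construction; validity
#' against the 20-letter natural alphabet is enforced later by [curate()],
#' so that raw inputs (which may contain non-natural residues) can be read,
#' inspected and reported on before filtering.
#'
#' @param id Character vector of record identifiers.
#' @param seq Character vector of amino-acid sequences (any case).
#' @param label Optional numeric/integer vector of class labels (1/0/`NA`).
#' @param provenance Free-text source tag.
#' @return A `peptide_set` (data frame with columns `id`, `seq`, `label`).
#' @export
peptide_set <- function(id, seq, label = NA_integer_, provenance = "") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have equal length", call. = FALSE)
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence in peptide set", call. = FALSE)
  }
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep(label, length(seq))
  if (!all(label %in% c(0L, 1L, NA_integer_))) {
    stop("labels must be 0, 1 or NA", call. = FALSE)
  }
  out <- data.frame(id = id, seq = seq, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set: %d records (%d labeled 1, %d labeled 0)\n",
              nrow(x), sum(x$label == 1L, na.rm = TRUE),
              sum(x$label == 0L, na.rm = TRUE)))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("provenance:", attr(x, "provenance"), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_natural <- function(seq) {
  !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seq)
}

#' Read peptide sequences from a FASTA file
#'
#' Headers become record ids (text after `>`), sequences are uppercased and
#' line wrapping is joined. A file whose first non-blank line does not start
#' with `>` is rejected with an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param label Optional label (0/1) assigned to every record.
#' @return A [peptide_set()].
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(peptide_set(character(), character(), provenance = path)[0, ])
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start with '>' (%s)",
                 first, path), call. = FALSE)
  }
  ss <- Biostrings::readAAStringSet(path)
  peptide_set(names(ss), as.character(ss), label = label, provenance = path)
}

#' Write a peptide set to FASTA
#'
#' @param ps A [peptide_set()].
#' @param path Output path.
#' @param width Line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ps, path, width = 60L) {
  ss <- Biostrings::AAStringSet(stats::setNames(ps$seq, ps$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read/write a labeled sequence table
#'
#' Tab-separated table with columns `id`, `sequence`, `label`; labels may be
#' written as `CPP`/`non-CPP` or 1/0 (CPP is the positive class, encoded 1).
#'
#' @param path Path to a TSV file.
#' @return A [peptide_set()].
#' @export
read_labeled_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(tab))) {
    stop("labeled table must have columns id, sequence, label", call. = FALSE)
  }
  lab <- tab$label
  if (is.character(lab)) {
    lab <- ifelse(toupper(lab) == "CPP", 1L,
                  ifelse(tolower(lab) %in% c("non-cpp", "noncpp"), 0L,
                         suppressWarnings(as.integer(lab))))
  }
  peptide_set(tab$id, tab$sequence, label = as.integer(lab), provenance = path)
}

#' @rdname read_labeled_tsv
#' @param ps A [peptide_set()].
#' @export
write_labeled_tsv <- function(ps, path) {
  lab <- ifelse(is.na(ps$label), NA_character_,
                ifelse(ps$label == 1L, "CPP", "non-CPP"))
  utils::write.table(
    data.frame(id = ps$id, sequence = ps$seq, label = lab),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Curate a peptide set
#'
#' Keeps records that contain only the 20 natural residues, fall inside the
#' length window, and are unique by sequence (first occurrence kept, in input
#' order). A curation report counting removals per reason is attached as the
#' `"curation_report"` attribute. Curation is idempotent.
#'
#' @param ps A [peptide_set()].
#' @param min_len,max_len Inclusive length window (training default 5--61).
#' @return The curated [peptide_set()] with a `"curation_report"` attribute.
#' @export
curate <- function(ps, min_len = 5L, max_len = 61L) {
  stopifnot(min_len <= max_len)
  n_input <- nrow(ps)
  natural <- is_natural(ps$seq)
  ps1 <- ps[natural, , drop = FALSE]
  len <- nchar(ps1$seq)
  in_window <- len >= min_len & len <= max_len
  n_short <- sum(len < min_len)
  n_long <- sum(len > max_len)
  ps2 <- ps1[in_window, , drop = FALSE]
  dup <- duplicated(ps2$seq)
  out <- ps2[!dup, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(
    n_input = n_input,
    n_removed_nonnatural = sum(!natural),
    n_removed_too_short = n_short,
    n_removed_too_long = n_long,
    n_removed_duplicate = sum(dup),
    n_kept = nrow(out)
  )
  attr(out, "provenance") <- attr(ps, "provenance")
  attr(out, "curation_report") <- report
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' Pairwise global-alignment identity between two sequences
#'
#' Identity is the number of exactly matching aligned positions in a global
#' (Needleman--Wunsch) alignment divided by the length of the shorter
#' sequence. Scoring is match +1, mismatch 0, gap -1 per position
#' (BLOSUM-free), a deliberately simple convention pinned for determinism.
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @return Identity fraction in \eqn{[0, 1]}.
#' @export
pairwise_identity <- function(a, b) {
  sub <- diag(1L, 20L)
  dimnames(sub) <- list(AA_ALPHABET, AA_ALPHABET)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sub, gapOpening = 0, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy incremental identity clustering
#'
#' Redundancy reduction in the style of CD-HIT: records are sorted by length
#' (descending, ties in input order); each record joins the first existing
#' cluster whose representative shares pairwise identity at or above the
#' cutoff, otherwise it founds a new cluster. The cluster representatives
#' (the longest member of each cluster) are returned in input order.
#'
#' This is a self-contained approximation of the external CD-HIT program:
#' the greedy strategy is the same, but identity uses the exact global
#' alignment of [pairwise_identity()], so results are not expected to
#' bit-match CD-HIT.
#'
#' @param ps A curated [peptide_set()].
#' @param identity_cutoff Identity threshold in (0, 1]; default 0.45.
#' @return A [peptide_set()] of representatives, with a `"clusters"`
#'   attribute mapping each input record to its representative.
#' @export
greedy_identity_cluster <- function(ps, identity_cutoff = 0.45) {
  if (!is.numeric(identity_cutoff) || identity_cutoff <= 0 ||
      identity_cutoff > 1) {
    stop("identity_cutoff must be in (0, 1]", call. = FALSE)
  }
  if (nrow(ps) <= 1L) return(ps)
  ord <- order(-nchar(ps$seq))  # stable: ties keep input order
  sub <- diag(1L, 20L)
  dimnames(sub) <- list(AA_ALPHABET, AA_ALPHABET)
  rep_idx <- integer(0)
  assignment <- integer(nrow(ps))
  for (i in ord) {
    hit <- 0L
    if (length(rep_idx) > 0L) {
      # one vectorized alignment call against all current representatives
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(ps$seq[rep_idx]),
        Biostrings::AAString(ps$seq[i]),
        substitutionMatrix = sub, gapOpening = 0, gapExtension = 1,
        type = "global")
      ident <- Biostrings::nmatch(aln) /
        pmin(nchar(ps$seq[rep_idx]), nchar(ps$seq[i]))
      match_pos <- which(ident >= identity_cutoff)
      if (length(match_pos) > 0L) hit <- rep_idx[match_pos[1L]]
    }
    if (hit > 0L) {
      assignment[i] <- hit
    } else {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- i
    }
  }
  keep <- sort(rep_idx)
  out <- ps[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(ps, "provenance")
  attr(out, "clusters") <- data.frame(id = ps$id,
                                      representative = ps$id[assignment],
                                      stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  out
}
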