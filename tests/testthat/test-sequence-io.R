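test_that("read_fasta normalizes case, preserves order and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "acde"), f)
  ps <- read_fasta(f)
  expect_equal(ps$id, "p1")
  expect_equal(ps$seq, "ACDE")

  writeLines(c(">a", "MK", ">b", "MR"), f)
  ps <- read_fasta(f)
  expect_equal(ps$id, c("a", "b"))
  expect_equal(ps$seq, c("MK", "MR"))

  # line wrapping joined
  writeLines(c(">w", "ACDEF", "GHIKL"), f)
  expect_equal(read_fasta(f)$seq, "ACDEFGHIKL")

  # round trip
  ps <- peptide_set(c("x", "y"), c("MKWVTFISLLLLFSSAYSR", "ACDE"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ps, f2)
  back <- read_fasta(f2)
  expect_equal(back$id, ps$id)
  expect_equal(back$seq, ps$seq)
})

test_that("read_fasta rejects malformed input and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACDE", ">p1", "MK"), f)
  expect_error(read_fasta(f), "line 1")
  file.create(f)
  expect_warning(ps <- read_fasta(f), "empty")
  expect_equal(nrow(ps), 0L)
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
})

test_that("labeled TSV round-trips sequences and the CPP=1 label encoding", {
  ps <- peptide_set(c("a", "b"), c("RRKKWWLL", "ACDEFGHI"), label = c(1L, 0L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_tsv(ps, f)
  back <- read_labeled_tsv(f)
  expect_equal(back$seq, ps$seq)
  expect_equal(back$label, c(1L, 0L))
  # text labels in either spelling
  writeLines(c("id\tsequence\tlabel", "a\tMK\tCPP", "b\tMR\tnon-CPP"), f)
  expect_equal(read_labeled_tsv(f)$label, c(1L, 0L))
})

test_that("curate removes duplicates, non-natural and out-of-window records", {
  ps <- peptide_set(paste0("p", 1:3), c("ACDE", "ACDE", "ACDE"))
  out <- curate(ps, 1, 61)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "curation_report")$n_removed_duplicate, 2L)

  out <- curate(peptide_set("p", "ACXDE"), 1, 61)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "curation_report")$n_removed_nonnatural, 1L)
  # B J O U X Z are non-natural
  for (ch in c("B", "J", "O", "U", "X", "Z")) {
    expect_equal(nrow(curate(peptide_set("p", paste0("ACD", ch)), 1, 61)), 0L)
  }

  out <- curate(peptide_set("p", "AAAA"), 5, 61)
  expect_equal(attr(out, "curation_report")$n_removed_too_short, 1L)
  expect_equal(nrow(out), 0L)
})

test_that("curate is idempotent and keeps first occurrence in file order", {
  seqs <- random_peptides(50, 3, 70, seed = 11)
  seqs <- c(seqs, seqs[1:5])  # re-inject duplicates
  ps <- peptide_set(sprintf("p%02d", seq_along(seqs)), seqs)
  once <- curate(ps, 5, 61)
  twice <- curate(once, 5, 61)
  # records are unchanged on re-curation (the report necessarily differs)
  expect_equal(twice[, c("id", "seq", "label")],
               once[, c("id", "seq", "label")], ignore_attr = TRUE)
  expect_equal(attr(twice, "curation_report")$n_removed_duplicate, 0L)
  # first occurrence kept: duplicated ids are from the original block
  expect_true(all(grepl("^p(0[1-9]|[1-4][0-9]|50)$", once$id)))
})

test_that("pairwise identity follows the matches-over-shorter-length pin", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwise_identity("AAAAAAAAAA", "CCCCCCCCCC"), 0.0)
  expect_equal(pairwise_identity("AAAAAAAAAA", "AAAAAAAAAC"), 0.9)
  # contiguous substring aligns gap-free: identity 1 by the shorter length
  expect_equal(pairwise_identity("ACDEF", "GGACDEFGG"), 1.0)
})

test_that("greedy clustering merges identical and near-identical sequences", {
  ps <- peptide_set(c("a", "b"), c("ACDEACDEAC", "ACDEACDEAC"))
  expect_equal(nrow(greedy_identity_cluster(ps, 0.45)), 1L)

  ps <- peptide_set(c("a", "b"), c("AAAAAAAAAA", "CCCCCCCCCC"))
  expect_equal(nrow(greedy_identity_cluster(ps, 0.45)), 2L)

  ps <- peptide_set(c("a", "b"), c("AAAAAAAAAA", "AAAAAAAAAC"))
  expect_equal(nrow(greedy_identity_cluster(ps, 0.45)), 1L)

  expect_error(greedy_identity_cluster(ps, 0), "identity_cutoff")
  expect_error(greedy_identity_cluster(ps, 1.2), "identity_cutoff")
})

test_that("cluster output shrinks as the cutoff drops and contains no chimeras", {
  seqs <- random_peptides(40, 6, 25, seed = 21)
  ps <- curate(peptide_set(sprintf("s%02d", 1:40), seqs), 5, 61)
  sizes <- vapply(c(1.0, 0.8, 0.6, 0.4, 0.2),
                  function(ct) nrow(greedy_identity_cluster(ps, ct)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
  reps <- greedy_identity_cluster(ps, 0.45)
  expect_true(all(reps$seq %in% ps$seq))
})
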