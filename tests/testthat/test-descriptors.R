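test_that("the seven property partitions each cover the 20 residues exactly once", {
  parts <- pepstack:::PROPERTY_PARTITIONS
  expect_length(parts, 7L)
  for (p in parts) {
    all_res <- unlist(p)
    expect_setequal(all_res, AA20)
    expect_length(all_res, 20L)          # disjoint classes
    expect_true(all(lengths(p) > 0))
  }
})

test_that("CTD composition matches hand counts and is permutation invariant", {
  expect_equal(ctd_composition("AAAA", "hydrophobicity"), c(0, 1, 0))
  # R is polar (class 1), C hydrophobic (class 3)
  expect_equal(ctd_composition("RC", "hydrophobicity"), c(0.5, 0, 0.5))
  s <- "RKWCILGAST"
  perm <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (p in names(pepstack:::PROPERTY_PARTITIONS)) {
    expect_equal(ctd_composition(s, p), ctd_composition(perm, p))
    expect_equal(sum(ctd_composition(s, p)), 1, tolerance = 1e-12)
  }
})

test_that("CTD transition counts class changes and is reversal symmetric", {
  for (p in names(pepstack:::PROPERTY_PARTITIONS)) {
    expect_equal(ctd_transition("AAAA", p), c(0, 0, 0))
  }
  expect_equal(ctd_transition("RC", "hydrophobicity"), c(0, 1, 0))
  s <- "RKWCILGASTDEQNHPVMFY"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (p in names(pepstack:::PROPERTY_PARTITIONS)) {
    expect_equal(ctd_transition(s, p), ctd_transition(rev_s, p))
  }
  expect_warning(z <- ctd_transition("A", "charge"), "single residue")
  expect_equal(z, c(0, 0, 0))
})

test_that("CTD distribution follows the pinned rank convention", {
  d <- ctd_distribution("RRRR", "hydrophobicity")
  expect_equal(d[1:5], c(25, 25, 50, 75, 100))   # class 1, n=4, L=4
  expect_equal(d[6:15], rep(0, 10))              # classes 2,3 absent
  # a single class-k residue at position p gives five copies of 100 p / L
  d <- ctd_distribution("AARAA", "hydrophobicity")
  expect_equal(d[1:5], rep(100 * 3 / 5, 5))
})

test_that("instability index reproduces the dipeptide-weight formula", {
  DIWV <- pepstack:::DIWV
  expect_equal(instability_index("GG"), 5 * DIWV["G", "G"])
  # homopolymer closed form: 10 (L-1) / L * DIWV(a, a)
  for (a in c("A", "W", "K")) {
    s <- strrep(a, 7)
    expect_equal(instability_index(s), 10 * 6 / 7 * DIWV[a, a])
  }
  # frozen value computed independently with the published table (checked
  # against the ProtParam implementation): melittin
  expect_equal(instability_index("GIGAVLKVLTTGLPALISWIKRKRQQ"),
               44.73077, tolerance = 1e-5)
  expect_error(instability_index("G"), "length")
})

test_that("global descriptors behave as their definitions require", {
  g <- global_descriptors("FWY")
  expect_equal(unname(g["aromaticity"]), 1.0)
  expect_equal(unname(global_descriptors("AAAA")["aromaticity"]), 0.0)
  expect_lt(net_charge("DDDD", 7), 0)
  expect_gt(net_charge("KKKK", 7), 0)
  # direct Henderson-Hasselbalch evaluation for "K" with the pinned pKa set
  expected <- 1 / (1 + 10^(7 - 8.6)) + 1 / (1 + 10^(7 - 10.8)) -
    1 / (1 + 10^(3.6 - 7))
  expect_equal(net_charge("K", 7), expected, tolerance = 1e-12)
  # the isoelectric point is the root of the charge curve
  s <- "RQIKIWFQNRRMKWKK"
  expect_equal(net_charge(s, isoelectric_point(s)), 0, tolerance = 1e-6)
  # aliphatic index closed form on a known mix
  expect_equal(unname(global_descriptors("AVIL")["aliphatic_index"]),
               100 * (1 + 2.9 + 3.9 * 2) / 4)
})

test_that("featurize yields the documented 147 CTD columns plus globals", {
  ps <- peptide_set(c("a", "b", "b2"), c("RQIKIWFQNRRMKWKK", "ACDEFGH",
                                         "ACDEFGH"), label = c(1L, 0L, 0L))
  fm <- featurize(ps)
  ctd_cols <- grep("\\.(C|T|D)", feature_names(fm), value = TRUE)
  expect_length(ctd_cols, 147L)
  expect_equal(nrow(fm), 3L)
  expect_equal(fm$label, c(1L, 0L, 0L))
  # identical sequences give identical rows
  expect_equal(unname(feature_values(fm)[2, ]), unname(feature_values(fm)[3, ]))
  # deterministic across calls
  expect_identical(featurize(ps), fm)
  expect_true(all(is.finite(feature_values(fm))))
  expect_error(featurize(peptide_set("x", "ACXDE")), "non-natural")
})

test_that("CTD values agree with the brute-force oracle on random peptides", {
  seqs <- random_peptides(40, 5, 61, seed = 31)
  parts <- pepstack:::PROPERTY_PARTITIONS
  for (s in seqs) {
    for (pn in names(parts)) {
      got <- c(ctd_composition(s, pn), ctd_transition(s, pn),
               ctd_distribution(s, pn))
      expect_equal(got, oracle_ctd(s, parts[[pn]]), tolerance = 1e-12)
    }
  }
})
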