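# pepstack

Prediction and proteome mining of cell-penetrating peptides (CPPs) from
sequence alone.

CPPs are short peptides (roughly 5–50 residues, typically cationic and
often amphipathic) that cross cell membranes without disrupting them,
which makes them attractive vehicles for intracellular drug delivery.
`pepstack` implements a complete, reproducible in-silico discovery
pipeline:

1. **Sequence curation** — FASTA/TSV input, validation against the
   20-letter natural alphabet, deduplication, length windows, and greedy
   CD-HIT-style redundancy clustering (identity = matches ÷ shorter
   sequence length in a global alignment).
2. **Descriptors** — 147 CTD descriptors (composition, transition,
   distribution over seven three-class physicochemical partitions:
   hydrophobicity, van der Waals volume, polarity, polarizability, charge,
   secondary-structure propensity, solvent accessibility), the Guruprasad
   instability index II = (10/L)·Σᵢ DIWV(xᵢ, xᵢ₊₁), and global descriptors
   (net charge by Henderson–Hasselbalch, isoelectric point, aromaticity,
   aliphatic index, molecular weight, ...) — 156 features per peptide.
3. **Feature selection** — correlation pruning (|r| > 0.9) followed by
   L1-regularized, cross-validated selection capped at 20 features.
4. **Classification** — a stacked ensemble of three base learners
   (k-nearest neighbors with manhattan metric and inverse-distance
   weights, gradient-boosted trees, random forest) whose out-of-fold
   probabilities feed an L2-regularized logistic meta-learner.
5. **Proteome mining** — in-silico digestion with a 35-rule enzymatic
   cleavage registry (trypsin, chymotrypsin, pepsin, CNBr, caspases, ...),
   length filtering (9–35 aa), composition-diversity thinning, and ranking
   of candidates by predicted CPP probability.
6. **Synthetic data** — a generator emulating a cationic/aromatic CPP-like
   class against a background composition, with a `signal_strength` dial
   from exchangeable classes (0) to full signal (1), so the entire
   pipeline is testable and benchmarkable without any downloads.

## Worked example

```r
library(pepstack)

# 500 CPP-like + 500 background peptides, full compositional signal
ps  <- generate_labeled_set(generator_config(n_per_class = 500, seed = 40))
res <- run_pipeline(ps, outdir = "run1")
res$metrics
#> accuracy 1.0000  precision 1.0000  recall 1.0000  f1 1.0000  roc_auc 1.0000
#> confusion: TP 79  FP 0  FN 0  TN 31

length(res$selection$kept)
#> [1] 20

# mine a toy proteome spiked with penetratin, the canonical CPP control
prot <- generate_toy_proteome(n_proteins = 20, length = 200,
                              spike = reference_peptides["penetratin"],
                              seed = 40)
tab <- mine(prot, res$model, top_k = 5, missed_cleavages = 6,
            diversity_threshold = 0)
head(tab$seq, 3)
#> [1] "EHKRQIKIWFQNRRM"          "IEYRWEHKRQIKIWFQNRRMKW"
#> [3] "IEYRWEHKRQIKIWFQNRRMKWKK"
```

The validation block is the held-out 15% of the curated benchmark (the
fully separable synthetic conditions; expect less on real data). The mined
table lists digestion fragments sorted by predicted probability of
membrane penetration, with source protein and cleavage rule; the top hits
are cleavage variants containing the spiked penetratin, which itself ranks
in the top 1% of ~9,500 candidates.

A command-line front end with subcommands mirroring the pipeline stages
(`synth`, `curate`, `featurize`, `select`, `pipeline`, `predict`, `mine`)
is installed at `system.file("cli", "pepstack.R", package = "pepstack")`.

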