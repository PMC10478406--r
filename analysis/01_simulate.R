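#!/usr/bin/env Rscript
# Build the study corpus: 5,000 synthetic abstracts with AUC values drawn
# from a smooth base distribution, a 30% promotion probability at the 0.7 /
# 0.8 / 0.9 thresholds (the planted "hacking" signal), the full mix of
# reporting styles, and decoy content. Writes the MEDLINE-dialect XML the
# rest of the workflow consumes, plus the ground-truth table.
suppressPackageStartupMessages(library(aucexcess))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(n_abstracts = 5000L, promotion_prob = 0.3,
                        seed = 20260928L)
corp <- generate_corpus(cfg, xml_path = "results/corpus.xml.gz")
write.csv(corp$truth, "results/ground_truth.csv", row.names = FALSE)

n_planted <- nrow(corp$truth)
cat("corpus written to results/corpus.xml.gz:",
    length(corp$records), "abstracts,", n_planted, "planted numbers\n")
cat("promoted values:", sum(corp$truth$promoted[corp$truth$role == "point"]),
    "of", sum(corp$truth$role == "point"), "point values\n")
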