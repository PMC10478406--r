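#!/usr/bin/env Rscript
# Validation of the extraction algorithm against the corpus ground truth,
# treated as the manual annotation: presence/absence agreement with exact
# binomial intervals for the predictive values, and Bland-Altman limits of
# agreement for the per-abstract count difference. Also prints the two
# reference intervals every 100-abstract manual check would use.
suppressPackageStartupMessages(library(aucexcess))

report <- if (file.exists("scratch/report.rds")) {
  readRDS("scratch/report.rds")
} else {
  run_analysis(parse_pubmed_xml("results/corpus.xml.gz"),
               auc_config(spline = list(df = 4L, fit_lower = 0.4,
                                        fit_upper = 1)))
}
truth <- read.csv("results/ground_truth.csv",
                  colClasses = c(pmid = "character"))

candidates <- report$corpus$pmid[report$corpus$reason %in%
                                   c("none", "no_auc_value")]
manual <- truth[truth$should_be_extracted & truth$pmid %in% candidates,
                c("pmid", "rendered_value")]
names(manual)[2] <- "value"
pairs <- annotation_pairs(report$values[, c("pmid", "value")], manual,
                          pmids = candidates)
vr <- compare_annotations(pairs)
print(vr)

jsonlite::write_json(
  list(n_abstracts = vr$n_abstracts, confusion = as.list(vr$confusion),
       npv = vr$npv, ppv = vr$ppv,
       loa = as.list(vr$loa), loa_coverage = vr$loa_coverage),
  "results/validation.json", auto_unbox = TRUE, digits = NA)

cat("\nexact 95% interval, 100/100 correct:",
    paste(round(exact_binomial_ci(100, 100), 3), collapse = " to "), "\n")
cat("exact 95% interval, 99/100 correct:",
    paste(round(exact_binomial_ci(99, 100), 3), collapse = " to "), "\n")
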