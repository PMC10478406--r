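#!/usr/bin/env Rscript
# Distribution analysis: the 0.01-bin histogram of extracted point values,
# the Poisson natural-spline smooth, residuals, and the threshold reports
# for the full corpus and the subgroups (highest value per abstract,
# results-section-only, PLoS One only). Draws the histogram + smooth and
# the residual bar chart.
suppressPackageStartupMessages(library(aucexcess))

report <- if (file.exists("scratch/report.rds")) {
  readRDS("scratch/report.rds")
} else {
  run_analysis(parse_pubmed_xml("results/corpus.xml.gz"),
               auc_config(spline = list(df = 4L, fit_lower = 0.4,
                                        fit_upper = 1)),
               journal = "PLoS One")
}

for (nm in names(report$subgroups)) {
  tr <- report$subgroups[[nm]]$thresholds
  if (is.null(tr)) next
  cat("\nsubgroup:", nm, "\n")
  print(tr, digits = 4)
}

pdf("results/histogram_smooth.pdf", width = 8, height = 7)
par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
tab <- report$subgroups$all$table
mid <- (tab$lower_edge + tab$upper_edge) / 2
plot(mid, tab$observed, type = "h", lwd = 3, col = "grey55",
     xlab = "AUC value", ylab = "count", xlim = c(0.4, 1),
     main = "Extracted AUC point values and smooth fit")
lines(mid, tab$fitted, lty = 2, lwd = 2)
abline(v = c(0.7, 0.8, 0.9), col = "red3", lty = 3)
plot(mid, tab$residual, type = "h", lwd = 3, col = "grey30",
     xlab = "AUC value", ylab = "observed - fitted", xlim = c(0.4, 1),
     main = "Residuals from the smooth fit")
abline(h = 0)
abline(v = c(0.7, 0.8, 0.9), col = "red3", lty = 3)
invisible(dev.off())
cat("\nwrote results/histogram_smooth.pdf\n")
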