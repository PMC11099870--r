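#!/usr/bin/env Rscript

# Stage 2 — differential expression of every treatment arm against control.
#
# Median-of-ratios normalization over all samples, then the NB Wald
# contrast per arm with the study thresholds (adjusted p < 0.05 and
# |log2FC| > 0.5). Writes one contrast table per arm plus a DEG summary
# under results/expression/.

suppressPackageStartupMessages(library(glucomem))

study <- read_study("results/synthetic")
dir.create("results/expression", recursive = TRUE, showWarnings = FALSE)

sf <- estimate_size_factors(study$expression$counts)
cond <- study$expression$samples$condition
summary_rows <- list()
for (trt in setdiff(unique(cond), "control")) {
  sel <- cond %in% c("control", trt)
  res <- nb_wald_contrast(study$expression$counts[, sel], cond[sel],
                          "control", trt, size_factors = sf[sel])
  write_tsv(res, file.path("results/expression",
                           paste0("contrast_", trt, "_vs_control.tsv")))
  truth_col <- paste0("lfc_", trt)
  truth <- study$expression$truth[[truth_col]] != 0
  called <- res$is_deg
  summary_rows[[trt]] <- data.frame(
    contrast = paste0(trt, "_vs_control"),
    n_deg = sum(called), n_up = sum(res$direction == "up"),
    n_down = sum(res$direction == "down"),
    planted = sum(truth),
    sensitivity = round(sum(called & truth) / max(1, sum(truth)), 3),
    fdr = round(sum(called & !truth) / max(1, sum(called)), 3))
}
smry <- do.call(rbind, summary_rows)
write_tsv(smry, "results/expression/deg_summary.tsv")
print(smry, row.names = FALSE)
cat("\nContrast tables written to results/expression/\n")
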