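#!/usr/bin/env Rscript

# Stage 3 — chromatin accessibility: consensus peaks, the Poisson
# differential test (fold > 1.5, Poisson p < 1e-4) per arm vs control, and
# genomic-feature annotation of the DARs. Writes tables under
# results/accessibility/.

suppressPackageStartupMessages(library(glucomem))

study <- read_study("results/synthetic")
dir.create("results/accessibility", recursive = TRUE, showWarnings = FALSE)

atac <- study$accessibility
for (cn in unique(atac$samples$condition)) {
  reps <- atac$peaks[atac$samples$sample_id[atac$samples$condition == cn]]
  cons <- consensus_peaks(reps)
  write_bed(cons, file.path("results/accessibility",
                            paste0("consensus_", cn, ".bed")))
  cat(sprintf("%s: %d replicate peaks -> %d consensus peaks\n",
              cn, nrow(reps[[1]]), nrow(cons)))
}

for (trt in setdiff(unique(atac$samples$condition), "control")) {
  res <- poisson_differential(study$genome$regions, atac$counts,
                              atac$samples$condition, "control", trt)
  write_tsv(res, file.path("results/accessibility",
                           paste0("da_", trt, "_vs_control.tsv")))
  ds <- dar_direction_summary(res)
  cat(sprintf("%s vs control: %d DARs (%d up, %d down; %s%% up)\n",
              trt, ds$n_dar, ds$n_up, ds$n_down, format(ds$percent_up)))
  ann <- annotation_summary(
    annotate_regions(res[res$is_dar, ], study$genome$genes,
                     study$genome$exons))
  write_tsv(ann, file.path("results/accessibility",
                           paste0("annotation_", trt, ".tsv")))
  nonprom <- sum(ann$n[ann$feature_class %in% c("intron", "intergenic")])
  cat(sprintf("  %d of %d DARs (%s%%) in intronic/intergenic space\n",
              nonprom, sum(ann$n), format(pct_int(nonprom, sum(ann$n)))))
}
cat("\nAccessibility tables written to results/accessibility/\n")
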