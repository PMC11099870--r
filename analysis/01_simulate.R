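#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic glucose-memory study.
#
# Seven expression arms (control, HG, memory, memory+SF, HG+SF, NRF2-OE
# under HG and memory; 3 replicates each) and four accessibility arms
# (2 replicates each) over a 2 x 1.5 Mb genome with 16 TADs, 600 genes and
# 800 candidate enhancer regions. Every artifact is written as plain text
# under results/synthetic/ together with the planted ground truth.

suppressPackageStartupMessages(library(glucomem))

cfg <- synthetic_config(seed = 20260923L)
study <- simulate_study(cfg, dir = "results/synthetic")

cat("Synthetic study written to results/synthetic/\n")
cat(sprintf("  genome: %d chromosomes x %d bp, %d TADs, %d genes, %d regions\n",
            cfg$n_chroms, cfg$chrom_length, nrow(study$genome$tads),
            nrow(study$genome$genes), nrow(study$genome$regions)))
cat(sprintf("  expression: %d samples (%d conditions x %d replicates)\n",
            ncol(study$expression$counts),
            length(cfg$conditions_expression), cfg$n_samples_expression))
cat(sprintf("  accessibility: %d samples; %d enhancer-class regions\n",
            ncol(study$accessibility$counts),
            sum(study$accessibility$truth$is_enhancer)))
cat(sprintf("  planted DEG classes: %d genes; planted DAR classes: %d regions\n",
            sum(cfg$deg_classes), sum(cfg$dar_classes)))
cat(sprintf("  motif occurrences embedded: %d\n",
            nrow(study$sequences$embedded)))
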