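#!/usr/bin/env Rscript

# Stage 5 — the integrated memory report: shared/unique DEG set algebra,
# restoration under sulforaphane and NRF2 overexpression (expression and
# accessibility), DAE linkage concordance, motif and pathway summaries —
# all assembled into one validated, deterministic report.

suppressPackageStartupMessages(library(glucomem))

study <- read_study("results/synthetic")
dir.create("results/report", recursive = TRUE, showWarnings = FALSE)

res <- run_pipeline(study)
validate_memory_report(res$report)
write_report(res$report, "results/report/memory_report.json")

print(res$report)
cat(sprintf("\nreport hash: %s\n", report_hash(res$report)))
cat("Report written to results/report/memory_report.json\n")
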