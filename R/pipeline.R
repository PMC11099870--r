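# End-to-end orchestration over a (synthetic or user-assembled) study:
# differential expression -> differential accessibility -> consensus /
# annotation -> enhancer calling -> TAD linkage -> set algebra and
# restoration -> motif enrichment -> memory report. Deterministic for a
# fixed study and seed.

#' Run the full glucose-memory analysis pipeline
#'
#' Stages run in dependency order on a study object shaped like the output
#' of [simulate_study()] (the same structure can be assembled from files
#' with the `read_*` helpers). All thresholds default to the study design:
#' DEGs at adjusted p < 0.05 and |log2FC| > 0.5; DARs at fold > 1.5 and
#' Poisson p < 1e-4; ORA and motif enrichment at p < 0.05.
#'
#' @param study list with `config`, `genome`, `expression`,
#'   `accessibility`, `sequences`, `gene_sets` (see [simulate_study()]).
#' @param padj_cutoff,lfc_cutoff DEG thresholds.
#' @param fold_cutoff,poisson_p_cutoff DAR thresholds.
#' @param ora_p_cutoff over-representation call threshold.
#' @param threshold_frac ZOOPS motif-scan threshold fraction.
#' @param deg_filter `"intersection"` (genes differential in both HG and
#'   memory; default) or `"union"` — the DEG set eligible as DAE targets.
#' @param directional_restoration use the stricter direction-aware
#'   restoration rule.
#' @param seed seed for the motif shuffle background (defaults to the study
#'   seed).
#' @return list with `report` (a `memory_report`) and all stage outputs
#'   (`contrasts`, `deg_sets`, `da`, `consensus`, `annotation`, `daes`,
#'   `linkage`, `motifs`, `ora`).
#' @export
run_pipeline <- function(study,
                         padj_cutoff = 0.05, lfc_cutoff = 0.5,
                         fold_cutoff = 1.5, poisson_p_cutoff = 1e-4,
                         ora_p_cutoff = 0.05, threshold_frac = 0.8,
                         deg_filter = c("intersection", "union"),
                         directional_restoration = FALSE,
                         seed = NULL) {
  deg_filter <- match.arg(deg_filter)
  if (is.null(seed)) seed <- study$config$seed
  expr <- study$expression
  atac <- study$accessibility
  conds_e <- unique(expr$samples$condition)
  conds_a <- unique(atac$samples$condition)
  if (!"control" %in% conds_e || !"control" %in% conds_a) {
    stop("study must include a 'control' condition in both assays")
  }

  ## differential expression, every arm vs control (plus memory vs HG)
  sf <- estimate_size_factors(expr$counts)
  contrasts <- list()
  for (trt in setdiff(conds_e, "control")) {
    sel <- expr$samples$condition %in% c("control", trt)
    contrasts[[trt]] <- nb_wald_contrast(
      expr$counts[, sel, drop = FALSE], expr$samples$condition[sel],
      "control", trt, size_factors = sf[sel],
      padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff)
  }
  if (all(c("HG", "memory") %in% conds_e)) {
    sel <- expr$samples$condition %in% c("HG", "memory")
    contrasts[["memory_vs_HG"]] <- nb_wald_contrast(
      expr$counts[, sel, drop = FALSE], expr$samples$condition[sel],
      "HG", "memory", size_factors = sf[sel],
      padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff)
  }
  deg_sets <- lapply(contrasts, deg_ids)
  contrast_summaries <- lapply(contrasts, function(cr) {
    list(n_deg = sum(cr$is_deg),
         n_up = sum(cr$direction == "up"),
         n_down = sum(cr$direction == "down"))
  })

  ## shared / restoration set algebra
  shared <- shared_dir <- NULL
  if (all(c("HG", "memory") %in% names(deg_sets))) {
    shared <- set_algebra(deg_sets$HG, deg_sets$memory)
    key <- function(cr) paste(deg_ids(cr),
                              cr$direction[match(deg_ids(cr), cr$feature)])
    shared_dir <- set_algebra(key(contrasts$HG), key(contrasts$memory))
  }
  rest_pairs <- list(HG_SF = c("HG", "HG_SF"),
                     memory_SF = c("memory", "memory_SF"),
                     OE_HG = c("HG", "OE_HG"),
                     OE_memory = c("memory", "OE_memory"))
  restoration_out <- list()
  for (nm in names(rest_pairs)) {
    pr <- rest_pairs[[nm]]
    if (!all(pr %in% names(deg_sets))) next
    restoration_out[[nm]] <- if (directional_restoration) {
      dir_of <- function(cr) {
        ids <- deg_ids(cr)
        stats::setNames(cr$direction[match(ids, cr$feature)], ids)
      }
      restoration_directional(dir_of(contrasts[[pr[1]]]),
                              dir_of(contrasts[[pr[2]]]))
    } else {
      restoration(deg_sets[[pr[1]]], deg_sets[[pr[2]]])
    }
  }

  ## differential accessibility vs control
  da <- list()
  for (trt in setdiff(conds_a, "control")) {
    da[[trt]] <- poisson_differential(
      study$genome$regions, atac$counts, atac$samples$condition,
      "control", trt, fold_cutoff = fold_cutoff,
      p_cutoff = poisson_p_cutoff)
  }
  da_summaries <- lapply(da, dar_direction_summary)
  dar_sets <- lapply(da, function(x) x$region_id[x$is_dar])

  ## consensus peaks per condition
  consensus <- lapply(stats::setNames(conds_a, conds_a), function(cn) {
    reps <- atac$peaks[atac$samples$sample_id[
      atac$samples$condition == cn]]
    consensus_peaks(reps)
  })

  ## genomic annotation of the DARs
  annotation <- lapply(da, function(x) {
    annotation_summary(annotate_regions(x[x$is_dar, , drop = FALSE],
                                        study$genome$genes,
                                        study$genome$exons))
  })

  ## DAEs: DARs co-overlapping both histone marks
  daes <- lapply(da, function(x) call_daes(x, atac$k4me1, atac$k27ac))
  dae_counts <- lapply(daes, nrow)

  ## TAD-constrained linkage for the HG and memory arms
  filt <- if (is.null(shared)) character(0) else {
    if (deg_filter == "intersection") shared$shared
    else union(deg_sets$HG, deg_sets$memory)
  }
  linkage <- list()
  for (nm in intersect(c("HG", "memory"), names(daes))) {
    lk <- link_daes_to_degs(daes[[nm]], contrasts[[nm]],
                            study$genome$genes, study$genome$tads, filt)
    linkage[[nm]] <- concordance_summary(lk)
    linkage[[nm]]$links <- NULL
    attr(linkage[[nm]], "links") <- lk$links
  }

  ## DAR restoration under SF
  dar_restoration <- list()
  if (all(c("memory", "memory_SF") %in% names(dar_sets))) {
    dar_restoration[["memory_SF"]] <-
      restoration(dar_sets$memory, dar_sets$memory_SF)
  }

  ## motif enrichment: promoters of down memory DEGs; DAE central windows
  motifs <- list()
  if (!is.null(study$sequences)) {
    pfms <- study$sequences$motifs
    if ("memory" %in% names(contrasts)) {
      down <- deg_ids(contrasts$memory, "down")
      gsel <- study$genome$genes[study$genome$genes$gene_id %in% down, ,
                                 drop = FALSE]
      if (nrow(gsel) > 0) {
        win <- extract_windows("promoter", gsel, study$sequences$seqs)
        motifs$promoter_down_memory <-
          motif_enrichment(win, pfms, seed = seed,
                           threshold_frac = threshold_frac)
      }
    }
    all_daes <- unique(do.call(rbind, lapply(daes, function(d) {
      d[, c("region_id", "chrom", "start", "end"), drop = FALSE]
    })))
    if (!is.null(all_daes) && nrow(all_daes) > 0) {
      win <- extract_windows("dae_center", all_daes, study$sequences$seqs)
      motifs$dae_windows <-
        motif_enrichment(win, pfms, seed = seed + 1L,
                         threshold_frac = threshold_frac)
    }
  }
  motif_heads <- lapply(motifs, function(m) {
    as.list(m[1, c("motif", "target_hits", "n_targets", "p", "padj")])
  })

  ## over-representation of the shared DEGs
  ora <- NULL
  if (!is.null(shared) && length(shared$shared) > 0 &&
      length(study$gene_sets) > 0) {
    ora <- overrepresentation_test(shared$shared,
                                   rownames(expr$counts),
                                   study$gene_sets,
                                   p_cutoff = ora_p_cutoff)
  }
  ora_summary <- if (is.null(ora)) NULL else {
    list(n_sets = nrow(ora), n_enriched = sum(ora$enriched),
         top_set = ora$set[which.min(ora$p)])
  }

  report <- build_report(
    contrasts = contrast_summaries, shared = shared,
    shared_directional = shared_dir, restoration = restoration_out,
    accessibility = da_summaries, annotation = annotation,
    daes = dae_counts, linkage = linkage,
    dar_restoration = dar_restoration, motifs = motif_heads,
    ora = ora_summary,
    config = list(seed = study$config$seed,
                  padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff,
                  fold_cutoff = fold_cutoff,
                  poisson_p_cutoff = poisson_p_cutoff,
                  ora_p_cutoff = ora_p_cutoff,
                  threshold_frac = threshold_frac,
                  deg_filter = deg_filter,
                  directional_restoration = directional_restoration))
  validate_memory_report(report)
  list(report = report, contrasts = contrasts, deg_sets = deg_sets,
       da = da, consensus = consensus, annotation = annotation,
       daes = daes, linkage = linkage, dar_restoration = dar_restoration,
       motifs = motifs, ora = ora)
}
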