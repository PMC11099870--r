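# TAD-constrained enhancer-to-gene linkage. An enhancer's candidate
# "regulatory domain" is the topologically associating domain (TAD) that
# contains it; only DEGs whose TSS shares that TAD are candidate targets.

#' Assign features to TADs by midpoint
#'
#' Each feature interval is assigned to the TAD containing its midpoint
#' (half-open containment); features whose midpoint falls outside every TAD
#' get `NA`.
#'
#' @param features interval data.frame.
#' @param tads interval data.frame with a `tad_id` column; TADs must not
#'   overlap within a chromosome.
#' @return character vector of TAD ids (or `NA`), one per feature row.
#' @export
assign_tad <- function(features, tads) {
  validate_intervals(tads, "tads")
  stopifnot("tad_id" %in% names(tads))
  self <- overlap_query(tads, tads)
  if (any(self$query_idx != self$subject_idx)) {
    stop("TADs overlap within a chromosome")
  }
  out <- rep(NA_character_, nrow(features))
  if (nrow(features) == 0) return(out)
  mid <- interval_midpoint(features)
  pts <- data.frame(chrom = features$chrom, start = mid, end = mid + 1L)
  ov <- overlap_query(pts, tads)
  out[ov$query_idx] <- as.character(tads$tad_id[ov$subject_idx])
  out
}

#' Link DAEs to candidate target DEGs within shared TADs
#'
#' For every differentially accessible enhancer (DAE), all genes from
#' `deg_filter` whose TSS lies in the DAE's TAD become candidate target
#' links. A link is concordant when the enhancer's accessibility direction
#' (more accessible = up) matches the gene's expression direction.
#'
#' @param daes data.frame of DAEs: interval columns plus `region_id` and
#'   `direction` (more_accessible/less_accessible).
#' @param contrast DE contrast result ([nb_wald_contrast()]) supplying each
#'   gene's `log2fc` and `direction`.
#' @param genes gene models (`gene_id`, `chrom`, `tss`).
#' @param tads TAD data.frame with `tad_id`.
#' @param deg_filter character vector of gene ids eligible as targets
#'   (e.g. the HG/M-shared DEG set).
#' @return list with `links` (data.frame: `dae_id`, `gene_id`, `tad_id`,
#'   `acc_direction`, `log2fc`, `expr_direction`, `concordant`) and
#'   `n_daes` (total DAEs examined).
#' @export
link_daes_to_degs <- function(daes, contrast, genes, tads, deg_filter) {
  empty <- data.frame(dae_id = character(), gene_id = character(),
                      tad_id = character(), acc_direction = character(),
                      log2fc = numeric(), expr_direction = character(),
                      concordant = logical(), stringsAsFactors = FALSE)
  if (nrow(daes) == 0) return(list(links = empty, n_daes = 0L))
  stopifnot(all(c("region_id", "direction") %in% names(daes)))
  dae_tad <- assign_tad(daes, tads)
  g <- genes[genes$gene_id %in% deg_filter, , drop = FALSE]
  if (nrow(g) == 0) return(list(links = empty, n_daes = nrow(daes)))
  g_tad <- assign_tad(
    data.frame(chrom = g$chrom, start = g$tss, end = g$tss + 1L), tads)
  stats <- contrast[match(g$gene_id, contrast$feature), , drop = FALSE]
  rows <- lapply(seq_len(nrow(daes)), function(i) {
    if (is.na(dae_tad[i])) return(NULL)
    hit <- which(!is.na(g_tad) & g_tad == dae_tad[i])
    if (length(hit) == 0) return(NULL)
    data.frame(
      dae_id = daes$region_id[i], gene_id = g$gene_id[hit],
      tad_id = dae_tad[i], acc_direction = daes$direction[i],
      log2fc = stats$log2fc[hit], expr_direction = stats$direction[hit],
      stringsAsFactors = FALSE)
  })
  links <- do.call(rbind, c(list(empty[, 1:6]), rows))
  acc_sign <- ifelse(links$acc_direction == "more_accessible", 1, -1)
  expr_sign <- ifelse(links$expr_direction == "up", 1,
                      ifelse(links$expr_direction == "down", -1, 0))
  links$concordant <- acc_sign == expr_sign
  list(links = links, n_daes = nrow(daes))
}

#' Per-enhancer concordance summary
#'
#' A DAE with at least one candidate target gene counts once; it is
#' concordant when at least one of its links is concordant. The percentage
#' is rounded half away from zero to an integer.
#'
#' @param linkage output of [link_daes_to_degs()] (or a bare links
#'   data.frame).
#' @return list: `n_daes`, `n_daes_with_target`, `n_concordant`,
#'   `percent_concordant` (`NA` when no DAE has a target).
#' @export
concordance_summary <- function(linkage) {
  if (is.data.frame(linkage)) {
    links <- linkage
    n_daes <- NA_integer_
  } else {
    links <- linkage$links
    n_daes <- linkage$n_daes
  }
  if (nrow(links) == 0) {
    return(list(n_daes = n_daes, n_daes_with_target = 0L,
                n_concordant = 0L, percent_concordant = NA_real_))
  }
  conc <- tapply(links$concordant, links$dae_id, any)
  list(n_daes = n_daes,
       n_daes_with_target = length(conc),
       n_concordant = as.integer(sum(conc)),
       percent_concordant = pct_int(sum(conc), length(conc)))
}
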