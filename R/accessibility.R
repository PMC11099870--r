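# Chromatin accessibility: consensus peaks across replicates and the
# Poisson differential-accessibility test (fold > 1.5, Poisson p < 1e-4).

#' Consensus peaks across replicate peak sets
#'
#' A peak from the first replicate is retained iff it overlaps (>= 1 bp)
#' at least one peak in every other replicate; each retained peak is
#' reported as the merged span (union) of itself and all peaks it overlaps
#' in the other replicates. Overlapping or duplicated spans in the result
#' are merged so the consensus set is non-overlapping.
#'
#' @param replicate_peaks list (length >= 2) of interval data.frames.
#' @return interval data.frame (`chrom`, `start`, `end`), non-overlapping,
#'   sorted by chrom then start.
#' @export
consensus_peaks <- function(replicate_peaks) {
  if (!is.list(replicate_peaks) || length(replicate_peaks) < 2) {
    stop("need at least two replicate peak sets")
  }
  for (i in seq_along(replicate_peaks)) {
    validate_intervals(replicate_peaks[[i]], paste0("replicate ", i))
  }
  if (any(vapply(replicate_peaks, nrow, 0L) == 0)) {
    warning("a replicate has no peaks; consensus is empty")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  base <- replicate_peaks[[1]]
  keep <- rep(TRUE, nrow(base))
  lo <- base$start
  hi <- base$end
  for (other in replicate_peaks[-1]) {
    ov <- overlap_query(base, other)
    keep <- keep & seq_len(nrow(base)) %in% ov$query_idx
    if (nrow(ov) > 0) {
      lo2 <- tapply(other$start[ov$subject_idx], ov$query_idx, min)
      hi2 <- tapply(other$end[ov$subject_idx], ov$query_idx, max)
      idx <- as.integer(names(lo2))
      lo[idx] <- pmin(lo[idx], lo2)
      hi[idx] <- pmax(hi[idx], hi2)
    }
  }
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  spans <- data.frame(chrom = base$chrom[keep], start = lo[keep],
                      end = hi[keep])
  red <- GenomicRanges::reduce(as_gr(spans))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Poisson differential-accessibility test
#'
#' Replicates are pooled within each condition and the pooled counts scaled
#' to tags per `scale` (default 1e7, i.e. tags-per-10-million) using the
#' condition's pooled library total. For each region the reference rate is
#' \eqn{\lambda = \max(\mathrm{ref}_{norm}, 1)} and the upper-tail
#' probability \eqn{P(X \ge \lceil \mathrm{trt}_{norm} \rceil)} is computed
#' by exact Poisson tail summation; the opposite direction swaps the roles.
#' The fold change is computed on the floored normalized counts
#' (`max(trt,1)/max(ref,1)`) so that swapping conditions inverts it exactly.
#' A region is a DAR when the fold criterion (`fold > fold_cutoff` or
#' `fold < 1/fold_cutoff`) and the corresponding tail p < `p_cutoff` both
#' hold.
#'
#' @param regions interval data.frame, one row per region (non-overlapping).
#' @param counts integer matrix, regions x samples.
#' @param condition per-sample condition labels.
#' @param reference,treatment condition labels to compare.
#' @param fold_cutoff,p_cutoff DAR thresholds (defaults 1.5 and 1e-4).
#' @param scale normalization scale (tags per `scale` total).
#' @return data.frame: region coordinates plus `norm_ref`, `norm_trt`,
#'   `fold`, `p`, `is_dar`, `direction`
#'   (more_accessible/less_accessible/none).
#' @export
poisson_differential <- function(regions, counts, condition, reference,
                                 treatment, fold_cutoff = 1.5,
                                 p_cutoff = 1e-4, scale = 1e7) {
  validate_intervals(regions, "regions")
  counts <- as.matrix(counts)
  if (nrow(regions) == 0) stop("region list is empty")
  if (nrow(counts) != nrow(regions)) {
    stop("counts must have one row per region")
  }
  condition <- as.character(condition)
  pool <- function(lab) {
    cols <- which(condition == lab)
    if (length(cols) == 0) stop("no replicate for condition: ", lab)
    rowSums(counts[, cols, drop = FALSE])
  }
  ref_pool <- pool(reference)
  trt_pool <- pool(treatment)
  if (sum(ref_pool) == 0 || sum(trt_pool) == 0) {
    stop("zero total library count in a condition")
  }
  norm_ref <- ref_pool * scale / sum(ref_pool)
  norm_trt <- trt_pool * scale / sum(trt_pool)
  lam_up <- pmax(norm_ref, 1)
  lam_down <- pmax(norm_trt, 1)
  p_up <- stats::ppois(ceiling(norm_trt) - 1, lam_up, lower.tail = FALSE)
  p_down <- stats::ppois(ceiling(norm_ref) - 1, lam_down, lower.tail = FALSE)
  fold <- pmax(norm_trt, 1) / pmax(norm_ref, 1)
  up <- fold > fold_cutoff & p_up < p_cutoff
  down <- fold < 1 / fold_cutoff & p_down < p_cutoff
  direction <- ifelse(up, "more_accessible",
                      ifelse(down, "less_accessible", "none"))
  out <- regions
  out$norm_ref <- norm_ref
  out$norm_trt <- norm_trt
  out$fold <- fold
  out$p <- ifelse(fold >= 1, p_up, p_down)
  out$is_dar <- up | down
  out$direction <- direction
  out
}
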