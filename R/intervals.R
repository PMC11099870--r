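# Interval engine. All coordinates in this package are 0-based, half-open
# (BED-native): a region [start, end) covers bases start .. end-1. The
# overlap machinery is GenomicRanges/IRanges behind this surface; conversion
# adds 1 to start because GRanges is 1-based closed.

#' Validate a genomic-interval data frame
#'
#' @param x data.frame with at least columns `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @param what label used in error messages.
#' @return `x`, invisibly, after checks.
#' @keywords internal
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) stop(what, " must be a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$start)) || any(is.na(x$end))) {
      stop(what, " has NA coordinates")
    }
    if (any(x$start < 0)) stop(what, " has negative start coordinates")
    if (any(x$start >= x$end)) {
      stop(what, " has start >= end (empty/inverted interval)")
    }
    if (any(!nzchar(as.character(x$chrom)))) stop(what, " has empty chrom")
  }
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' All pairwise overlaps between two interval sets
#'
#' Strand is ignored; two intervals overlap when they share at least
#' `min_bp` bases on the same chromosome.
#'
#' @param query,subject interval data.frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param min_bp minimum shared bases (default 1).
#' @return data.frame with columns `query_idx`, `subject_idx`,
#'   `overlap_bp` (row indices into the inputs).
#' @export
overlap_query <- function(query, subject, min_bp = 1L) {
  validate_intervals(query, "query")
  validate_intervals(subject, "subject")
  empty <- data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_bp = integer())
  if (nrow(query) == 0 || nrow(subject) == 0) return(empty)
  # findOverlaps warns when the two sets share no chromosome; for this
  # surface that is an ordinary empty result, not a user error
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_gr(query), as_gr(subject),
                                minoverlap = as.integer(min_bp)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  data.frame(query_idx = qi, subject_idx = si, overlap_bp = as.integer(ov))
}

#' Midpoint of intervals (0-based position)
#' @param x interval data.frame.
#' @return integer vector of midpoints, `start + floor(width/2)`.
#' @export
interval_midpoint <- function(x) {
  as.integer(x$start + (x$end - x$start) %/% 2L)
}

#' Strand-aware promoter windows around gene TSS
#'
#' The window spans `upstream` bases 5' of the TSS and `downstream` bases
#' from the TSS onwards (TSS included), on the gene's strand; on the minus
#' strand "upstream" extends to higher coordinates.
#'
#' @param genes gene-model data.frame with `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tss` (0-based position of the first transcribed base).
#' @param upstream,downstream window extents in bp (defaults 1000 and 100,
#'   i.e. TSS-1000 .. TSS+100).
#' @return interval data.frame (`chrom`, `start`, `end`, `gene_id`,
#'   `strand`), clipped at 0.
#' @export
promoter_windows <- function(genes, upstream = 1000L, downstream = 100L) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(genes)))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss + 1L - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + 1L + upstream)
  data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(start)),
             end = as.integer(end), gene_id = genes$gene_id,
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Annotate regions by genomic feature class
#'
#' Each region is assigned exactly one class by the position of its midpoint,
#' with precedence promoter > exon > intron > intergenic (the usual
#' peak-annotation ordering). Promoter windows are strand-aware
#' TSS-1000..TSS+100; "intron" means inside a gene span but in neither a
#' promoter window nor an exon.
#'
#' @param regions interval data.frame.
#' @param genes gene models (see [promoter_windows()]), with additional
#'   `start`/`end` giving the gene span.
#' @param exons interval data.frame of exons (may be empty).
#' @param upstream,downstream promoter window extents.
#' @return `regions` with an added factor column `feature_class` with levels
#'   promoter, exon, intron, intergenic.
#' @export
annotate_regions <- function(regions, genes, exons,
                             upstream = 1000L, downstream = 100L) {
  validate_intervals(regions, "regions")
  cls <- rep("intergenic", nrow(regions))
  if (nrow(regions) > 0) {
    mid <- interval_midpoint(regions)
    pts <- data.frame(chrom = regions$chrom, start = mid, end = mid + 1L)
    known <- pts$chrom %in% unique(as.character(genes$chrom))
    if (any(!known)) {
      warning(sum(!known), " region(s) on chromosomes absent from the gene ",
              "model; classed intergenic")
    }
    hit_rows <- function(subject) {
      if (nrow(subject) == 0) return(integer())
      unique(overlap_query(pts, subject)$query_idx)
    }
    spans <- data.frame(chrom = genes$chrom, start = genes$start,
                        end = genes$end)
    cls[hit_rows(spans)] <- "intron"
    cls[hit_rows(exons)] <- "exon"
    cls[hit_rows(promoter_windows(genes, upstream, downstream))] <- "promoter"
  }
  regions$feature_class <- factor(cls, levels = c("promoter", "exon",
                                                  "intron", "intergenic"))
  regions
}

#' Call differentially accessible putative enhancers (DAEs)
#'
#' A DAR qualifies as a putative enhancer when it overlaps (>= 1 bp) at least
#' one H3K4me1 peak AND at least one H3K27ac peak. The accessibility
#' direction is retained.
#'
#' @param dars data.frame of differential-accessibility results (must carry
#'   `chrom`, `start`, `end`, `is_dar`, `direction`).
#' @param k4me1,k27ac histone-mark peak interval data.frames.
#' @return the DAR rows that are DAEs, with an added logical column `is_dae`
#'   (all TRUE) — a subset of the `is_dar` rows of the input.
#' @export
call_daes <- function(dars, k4me1, k27ac) {
  stopifnot(all(c("is_dar", "direction") %in% names(dars)))
  dar <- dars[dars$is_dar, , drop = FALSE]
  if (nrow(dar) == 0) {
    dar$is_dae <- logical(0)
    return(dar)
  }
  has4 <- seq_len(nrow(dar)) %in% overlap_query(dar, k4me1)$query_idx
  has27 <- seq_len(nrow(dar)) %in% overlap_query(dar, k27ac)$query_idx
  out <- dar[has4 & has27, , drop = FALSE]
  out$is_dae <- rep(TRUE, nrow(out))
  out
}

#' Tabulate feature-class annotation
#' @param annotated output of [annotate_regions()].
#' @return data.frame with class, count and integer percentage.
#' @export
annotation_summary <- function(annotated) {
  tab <- table(annotated$feature_class)
  data.frame(feature_class = names(tab), n = as.integer(tab),
             percent = pct_int(as.integer(tab), sum(tab)),
             stringsAsFactors = FALSE)
}
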