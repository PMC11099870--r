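# Plain-text readers/writers for the formats the pipeline consumes and
# emits: BED6 intervals, counts TSV (features x samples), gene-model TSV,
# GMT gene sets, FASTA (via Biostrings) and JASPAR-style PFMs (motif.R).

#' Read a BED file (first 3-6 columns)
#' @param path BED file path (no header; 0-based half-open).
#' @return interval data.frame with `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = list(V1 = "character"))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(min(ncol(x), 6))]
  validate_intervals(x, path)
  x
}

#' Write intervals as BED
#' @param x interval data.frame (extra columns beyond BED6 are dropped).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "x")
  bed6 <- c("chrom", "start", "end", "name", "score", "strand")
  k <- 3L  # BED requires contiguous leading columns
  while (k < 6L && bed6[k + 1L] %in% names(x)) k <- k + 1L
  utils::write.table(x[, bed6[seq_len(k)], drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a counts TSV (features x samples, header of sample ids)
#' @param path TSV path; first column = feature ids.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(x)
}

#' Write a counts matrix as TSV
#' @param counts matrix with feature rownames and sample colnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-model TSV
#' @param path TSV with header: gene_id, chrom, strand, tss, start, end.
#' @return gene-model data.frame.
#' @export
read_gene_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = list(chrom = "character"))
}

#' Write a gene-model TSV
#' @param genes gene-model data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, then member ids per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read chromosome sequences from FASTA
#' @param path FASTA path.
#' @return named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a data.frame as TSV (with header)
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Load a study from the plain-text artifacts written by [simulate_study()]
#'
#' Rebuilds the study object (configuration, genome layout, count matrices,
#' peak and mark intervals, sequences, motifs, gene sets) from a directory
#' of TSV/BED/FASTA/PFM/GMT/YAML files, so downstream stages can run from
#' files rather than from an in-memory simulation. User-assembled data in
#' the same layout loads the same way.
#'
#' @param dir directory written by `simulate_study(config, dir = ...)`.
#' @return a study list as returned by [simulate_study()].
#' @export
read_study <- function(dir) {
  p <- function(...) file.path(dir, ...)
  cfgl <- yaml::read_yaml(p("config.yaml"))
  for (nm in c("deg_classes", "dar_classes")) cfgl[[nm]] <- unlist(cfgl[[nm]])
  config <- do.call(synthetic_config, cfgl)
  rename <- function(x, from, to) {
    names(x)[names(x) == from] <- to
    x
  }
  genome <- list(
    chroms = read_tsv(p("chroms.tsv")),
    tads = rename(read_bed(p("tads.bed")), "name", "tad_id"),
    genes = read_gene_table(p("genes.tsv")),
    exons = rename(read_bed(p("exons.bed")), "name", "gene_id"),
    regions = rename(read_bed(p("regions.bed")), "name", "region_id"))
  genome$regions <- genome$regions[, c("region_id", "chrom", "start",
                                       "end")]
  expression <- list(counts = read_counts(p("expression_counts.tsv")),
                     samples = read_tsv(p("expression_samples.tsv")),
                     truth = read_tsv(p("truth_expression.tsv")))
  asamples <- read_tsv(p("accessibility_samples.tsv"))
  peaks <- lapply(stats::setNames(asamples$sample_id, asamples$sample_id),
                  function(sid) read_bed(p(paste0("peaks_", sid, ".bed"))))
  accessibility <- list(counts = read_counts(p("accessibility_counts.tsv")),
                        samples = asamples,
                        truth = read_tsv(p("truth_accessibility.tsv")),
                        peaks = peaks,
                        k4me1 = read_bed(p("k4me1.bed")),
                        k27ac = read_bed(p("k27ac.bed")))
  fa <- read_fasta(p("genome.fa"))
  sequences <- list(seqs = stats::setNames(as.character(fa), names(fa)),
                    motifs = read_pfm(p("motifs.pfm")))
  list(config = config, genome = genome, expression = expression,
       accessibility = accessibility, sequences = sequences,
       gene_sets = read_gmt(p("gene_sets.gmt")))
}
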