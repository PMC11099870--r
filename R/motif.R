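# PWM motif scanning (ZOOPS) and enrichment. The study's motif of interest
# is the bZIP core TGA(C/G)TCA shared by AP-1 and NRF2-family factors;
# scanning is log-odds over both strands with a hit threshold expressed as
# a fraction of the motif's maximum achievable score.

DNA_BASES <- c("A", "C", "G", "T")

#' Read a JASPAR-style PFM file
#'
#' Accepts the common JASPAR text layout: a `>` header line (`>id name`)
#' followed by four rows of per-position counts, either bare numbers or the
#' bracketed `A [ 1 2 3 ]` form.
#'
#' @param path file path.
#' @return named list of motifs; each motif is a list with `id`, `name` and
#'   `counts` (4 x L numeric matrix, rows A, C, G, T).
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' header found in PFM file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4) stop("motif ", toks[1], ": expected 4 count rows")
    rows <- lapply(body, function(ln) {
      ln <- gsub("^\\s*[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(vapply(rows, length, 0L))) != 1) {
      stop("motif ", toks[1], ": ragged count rows")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- DNA_BASES
    list(id = toks[1],
         name = if (length(toks) > 1) paste(toks[-1], collapse = " ")
                else toks[1],
         counts = counts)
  })
  stats::setNames(motifs, vapply(motifs, `[[`, "", "id"))
}

#' Write motifs to a JASPAR-style PFM file
#' @param motifs list as returned by [read_pfm()].
#' @param path output file.
#' @export
write_pfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id, " ", m$name), con)
    for (b in DNA_BASES) {
      writeLines(paste0(b, " [ ",
                        paste(format(m$counts[b, ], trim = TRUE),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Build a PFM from a consensus word
#'
#' Each position puts `weight` counts on the consensus base(s) and 1 on the
#' others; IUPAC S (C or G) splits the weight. Only A/C/G/T/S are accepted.
#'
#' @param consensus consensus string, e.g. `"TGASTCA"` for TGA(C/G)TCA.
#' @param id,name motif identifiers.
#' @param weight consensus count weight per position (default 97).
#' @return a motif list entry (see [read_pfm()]).
#' @export
pfm_from_consensus <- function(consensus, id = consensus, name = id,
                               weight = 97) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, c(DNA_BASES, "S"))
  if (length(bad) > 0) {
    stop("consensus has characters outside ACGT(S): ",
         paste(unique(bad), collapse = ""))
  }
  counts <- sapply(chars, function(ch) {
    col <- stats::setNames(rep(1, 4), DNA_BASES)
    if (ch == "S") col[c("C", "G")] <- weight / 2 else col[ch] <- weight
    col
  })
  dimnames(counts) <- list(DNA_BASES, NULL)
  list(id = id, name = name, counts = counts)
}

#' Log2-odds score matrix of a motif
#'
#' Counts are converted to probabilities with a pseudocount per base and
#' compared to the background base frequencies.
#'
#' @param motif a motif list entry.
#' @param background background base frequencies (A, C, G, T).
#' @param pseudocount added to each count cell (default 0.25).
#' @return 4 x L numeric matrix of log2 odds, with attribute `max_score`.
#' @export
pwm_logodds <- function(motif, background = rep(0.25, 4),
                        pseudocount = 0.25) {
  counts <- motif$counts + pseudocount
  probs <- sweep(counts, 2, colSums(counts), "/")
  lo <- log2(probs / background)
  attr(lo, "max_score") <- sum(apply(lo, 2, max))
  lo
}

# encode a DNA string as indices into DNA_BASES (NA for anything else)
encode_dna <- function(s) {
  match(strsplit(toupper(as.character(s)), "")[[1]], DNA_BASES)
}

# score every window of an encoded sequence against a 4xL matrix;
# windows touching non-ACGT bases score -Inf
score_windows <- function(idx, mat) {
  L <- ncol(mat)
  nw <- length(idx) - L + 1L
  if (nw < 1) return(numeric(0))
  s <- numeric(nw)
  bad <- logical(nw)
  for (l in seq_len(L)) {
    v <- mat[idx[l:(l + nw - 1L)], l]
    miss <- is.na(v)
    bad <- bad | miss
    v[miss] <- 0
    s <- s + v
  }
  s[bad] <- -Inf
  s
}

#' ZOOPS motif scan over both strands
#'
#' Scores every window of every sequence with the motif's log-odds matrix on
#' both strands, and flags a sequence as a hit when its best window scores
#' at least `threshold_frac` times the motif's maximum achievable score
#' (zero-or-one occurrence per sequence counting). Sequences shorter than
#' the motif never hit.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @param motif a motif list entry (see [read_pfm()]).
#' @param threshold_frac fraction of the maximum score (default 0.8).
#' @param background background base frequencies.
#' @return data.frame: `seq_id`, `best_score`, `hit`.
#' @export
scan_zoops <- function(sequences, motif, threshold_frac = 0.8,
                       background = rep(0.25, 4)) {
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  lo <- pwm_logodds(motif, background)
  # reverse-complement strand: scan with the reverse-complemented matrix
  lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(lo_rc) <- DNA_BASES
  thr <- threshold_frac * attr(lo, "max_score")
  best <- vapply(seqs, function(s) {
    idx <- encode_dna(s)
    sc <- c(score_windows(idx, lo), score_windows(idx, lo_rc))
    if (length(sc) == 0) -Inf else max(sc)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(seq_id = ids, best_score = best, hit = best >= thr,
             stringsAsFactors = FALSE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: produces a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) composition, by building a
#' random Eulerian walk over the dinucleotide graph. Uses the current RNG
#' stream.
#'
#' @param s a single sequence (character).
#' @return shuffled sequence (character).
#' @export
dinuc_shuffle <- function(s) {
  chars <- strsplit(toupper(as.character(s)), "")[[1]]
  n <- length(chars)
  if (n <= 2) return(paste(chars, collapse = ""))
  verts <- unique(chars)
  adj <- lapply(stats::setNames(verts, verts),
                function(v) chars[which(chars[-n] == v) + 1L])
  first <- chars[1]
  last <- chars[n]
  connects_to_last <- function(last_edge) {
    # do the chosen terminal edges lead every vertex to `last`?
    for (v in names(last_edge)) {
      seen <- character(0)
      cur <- v
      repeat {
        if (cur == last) break
        if (cur %in% seen) return(FALSE)
        seen <- c(seen, cur)
        nxt <- last_edge[[cur]]
        if (is.null(nxt)) return(FALSE)
        cur <- nxt
      }
    }
    TRUE
  }
  others <- setdiff(names(adj)[vapply(adj, length, 0L) > 0], last)
  repeat {
    last_edge <- lapply(stats::setNames(others, others), function(v) {
      edges <- adj[[v]]
      edges[sample.int(length(edges), 1)]
    })
    if (connects_to_last(last_edge)) break
  }
  shuffled <- adj
  for (v in names(shuffled)) {
    edges <- shuffled[[v]]
    if (v %in% others) {
      le <- last_edge[[v]]
      drop <- match(le, edges)
      rest <- edges[-drop]
      shuffled[[v]] <- c(rest[sample.int(length(rest))], le)
    } else if (length(edges) > 1) {
      shuffled[[v]] <- edges[sample.int(length(edges))]
    }
  }
  ptr <- stats::setNames(rep(1L, length(shuffled)), names(shuffled))
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Motif enrichment in target vs background sequences
#'
#' ZOOPS hit counts in targets and background are compared with a
#' hypergeometric upper-tail test (per motif), BH-adjusted across motifs.
#' When no background is supplied, a seeded dinucleotide-shuffled background
#' (`shuffle_n` copies of each target) is generated.
#'
#' @param targets target sequences (named character vector or
#'   `DNAStringSet`).
#' @param motifs list of motifs (see [read_pfm()]).
#' @param background background sequences, or `NULL` for shuffled targets.
#' @param threshold_frac ZOOPS threshold fraction.
#' @param shuffle_n shuffled copies per target when background is `NULL`.
#' @param seed RNG seed for the shuffle (required when background is
#'   `NULL`).
#' @param pooled_universe set `TRUE` to allow targets and background to
#'   share sequence ids (pooled-universe mode); otherwise shared ids error.
#' @return data.frame per motif: `motif`, `target_hits`, `background_hits`,
#'   `n_targets`, `n_background`, `p`, `padj`, ordered by increasing `p`.
#' @export
motif_enrichment <- function(targets, motifs, background = NULL,
                             threshold_frac = 0.8, shuffle_n = 3,
                             seed = NULL, pooled_universe = FALSE) {
  tseq <- stats::setNames(as.character(targets), names(targets))
  if (is.null(names(tseq))) names(tseq) <- paste0("target_", seq_along(tseq))
  if (is.null(background)) {
    if (is.null(seed)) {
      stop("supply background sequences or a seed for the dinucleotide ",
           "shuffle background")
    }
    if (length(tseq) == 0) stop("no target sequences")
    background <- local({
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      bg <- unlist(lapply(seq_len(shuffle_n), function(k) {
        vapply(tseq, dinuc_shuffle, character(1), USE.NAMES = FALSE)
      }))
      names(bg) <- paste0("shuffle_", seq_along(bg))
      bg
    })
  }
  bseq <- stats::setNames(as.character(background), names(background))
  if (is.null(names(bseq))) names(bseq) <- paste0("bg_", seq_along(bseq))
  if (length(bseq) == 0) {
    stop("empty background: supply background sequences or use shuffle mode")
  }
  if (!pooled_universe && length(intersect(names(tseq), names(bseq))) > 0) {
    stop("target and background share sequence ids; pass ",
         "pooled_universe = TRUE for pooled-universe mode")
  }
  rows <- lapply(motifs, function(m) {
    ht <- sum(scan_zoops(tseq, m, threshold_frac)$hit)
    hb <- sum(scan_zoops(bseq, m, threshold_frac)$hit)
    n_t <- length(tseq)
    n_b <- length(bseq)
    p <- stats::phyper(ht - 1, ht + hb, n_t + n_b - ht - hb, n_t,
                       lower.tail = FALSE)
    data.frame(motif = m$id, target_hits = ht, background_hits = hb,
               n_targets = n_t, n_background = n_b, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$motif), , drop = FALSE]
}

#' Extract sequence windows for motif analysis
#'
#' Promoter mode extracts strand-aware TSS-1000..TSS+100 windows (reverse-
#' complemented for minus-strand genes); `dae_center` mode extracts +/-
#' `flank` bp around each region's midpoint. Windows extending past a
#' chromosome end are clipped with a warning.
#'
#' @param mode `"promoter"` or `"dae_center"`.
#' @param features gene models (promoter mode: `gene_id`, `chrom`,
#'   `strand`, `tss`) or regions (`region_id`/`name`, `chrom`, `start`,
#'   `end`).
#' @param chrom_seqs named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param upstream,downstream promoter extents (defaults 1000/100).
#' @param flank DAE half-window (default 50).
#' @return named character vector of window sequences.
#' @export
extract_windows <- function(mode = c("promoter", "dae_center"), features,
                            chrom_seqs, upstream = 1000L, downstream = 100L,
                            flank = 50L) {
  mode <- match.arg(mode)
  seqs <- stats::setNames(as.character(chrom_seqs), names(chrom_seqs))
  if (mode == "promoter") {
    win <- promoter_windows(features, upstream, downstream)
    ids <- features$gene_id
    strand <- features$strand
  } else {
    win <- data.frame(chrom = features$chrom,
                      start = interval_midpoint(features) - flank,
                      end = interval_midpoint(features) + flank)
    ids <- if ("region_id" %in% names(features)) features$region_id
           else if ("name" %in% names(features)) features$name
           else as.character(seq_len(nrow(features)))
    strand <- rep("+", nrow(win))
  }
  missing_chr <- setdiff(unique(as.character(win$chrom)), names(seqs))
  if (length(missing_chr) > 0) {
    stop("no sequence for chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  }
  lens <- nchar(seqs)[as.character(win$chrom)]
  lo <- pmax(0L, as.integer(win$start))
  hi <- pmin(as.integer(lens), as.integer(win$end))
  full_w <- if (mode == "promoter") upstream + downstream else 2L * flank
  if (any(lo > win$start | hi < win$end | hi - lo < full_w)) {
    warning("window(s) clipped at chromosome bounds")
  }
  out <- vapply(seq_len(nrow(win)), function(i) {
    s <- substr(seqs[[as.character(win$chrom[i])]], lo[i] + 1L, hi[i])
    if (strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  stats::setNames(out, ids)
}
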