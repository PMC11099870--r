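# Independent brute-force oracles and shared fixtures. Oracles deliberately
# avoid the package's code paths (plain loops, direct summation) so the
# implementation and its check stay independent.

# all pairs of intervals sharing >= min_bp bases, O(n*m) double loop
brute_overlaps <- function(a, b, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (as.character(a$chrom[i]) != as.character(b$chrom[j])) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) {
        out[[length(out) + 1]] <- c(i, j, ov)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_bp = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(query_idx = m[, 1], subject_idx = m[, 2], overlap_bp = m[, 3])
}

# sort an overlap pair table into canonical order for comparison
canon_pairs <- function(x) {
  x <- x[order(x$query_idx, x$subject_idx), c("query_idx", "subject_idx",
                                              "overlap_bp")]
  rownames(x) <- NULL
  x
}

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                           max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Poisson upper tail P(X >= k | lambda), independent of ppois: terms are
# built recursively from the distribution's mode (anchor value 1, so no
# large-argument lgamma error) and both the tail and the normalizing total
# are accumulated with Kahan compensation.
pois_tail_kahan <- function(k, lambda) {
  k <- max(0, ceiling(k))
  if (k == 0) return(1)
  kahan_add <- function(state, x) {
    y <- x - state[2]
    t <- state[1] + y
    c(t, (t - state[1]) - y)
  }
  mode <- max(0, floor(lambda))
  total <- c(0, 0)
  tail <- c(0, 0)
  # upward from the mode
  term <- 1
  j <- mode
  repeat {
    total <- kahan_add(total, term)
    if (j >= k) tail <- kahan_add(tail, term)
    j <- j + 1
    term <- term * lambda / j
    # stop only once the *tail* sum has converged (tail terms can sit many
    # orders below the distribution total)
    if (j > lambda + 10 && j > k &&
        (term == 0 || (tail[1] > 0 && term < tail[1] * 1e-20))) break
  }
  # downward from the mode
  term <- 1
  j <- mode
  while (j > 0) {
    term <- term * j / lambda
    j <- j - 1
    total <- kahan_add(total, term)
    if (j >= k) tail <- kahan_add(tail, term)
    if (term < total[1] * 1e-20 && j < k) break
  }
  tail[1] / total[1]
}

# hypergeometric upper tail P(X >= k) by direct term summation
hyper_tail <- function(k, n_success, n_total, n_draw) {
  i <- seq(max(0, k), min(n_success, n_draw))
  if (length(i) == 0) return(0)
  sum(exp(lchoose(n_success, i) + lchoose(n_total - n_success, n_draw - i) -
            lchoose(n_total, n_draw)))
}

# reverse complement, independent of Biostrings
revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]),
        collapse = "")
}

# per-region feature-class oracle: midpoint containment with promoter >
# exon > intron > intergenic precedence, windows re-derived from scratch
brute_annotate <- function(regions, genes, exons) {
  vapply(seq_len(nrow(regions)), function(i) {
    mid <- regions$start[i] + (regions$end[i] - regions$start[i]) %/% 2
    chrom <- as.character(regions$chrom[i])
    cls <- "intergenic"
    for (j in seq_len(nrow(genes))) {
      if (as.character(genes$chrom[j]) != chrom) next
      t <- genes$tss[j]
      if (genes$strand[j] == "+") {
        p_lo <- t - 1000; p_hi <- t + 100
      } else {
        p_lo <- t + 1 - 100; p_hi <- t + 1 + 1000
      }
      if (mid >= max(0, p_lo) && mid < p_hi) return("promoter")
    }
    for (j in seq_len(nrow(exons))) {
      if (as.character(exons$chrom[j]) == chrom &&
          mid >= exons$start[j] && mid < exons$end[j]) {
        cls <- "exon"
      }
    }
    if (cls == "exon") return(cls)
    for (j in seq_len(nrow(genes))) {
      if (as.character(genes$chrom[j]) == chrom &&
          mid >= genes$start[j] && mid < genes$end[j]) {
        cls <- "intron"
      }
    }
    cls
  }, character(1))
}

# small, fast study configuration for pipeline-level tests
small_config <- function(seed = 5L) {
  synthetic_config(
    n_chroms = 2L, chrom_length = 600000L, n_tads_per_chrom = 4L,
    n_genes = 150L, n_regions = 200L,
    deg_classes = c(shared_up = 8L, shared_down = 5L,
                    shared_up_sf_restored = 8L,
                    shared_down_sf_restored = 6L,
                    shared_up_oe_restored = 8L,
                    shared_down_oe_restored = 6L,
                    hg_unique_up = 8L, hg_unique_down = 5L,
                    memory_unique_up = 6L, memory_unique_down = 4L),
    dar_classes = c(hg_up = 8L, hg_up_enhancer = 6L, hg_down = 2L,
                    persistent_up = 3L, persistent_up_enhancer = 3L,
                    persistent_down = 1L,
                    sf_restored_up = 7L, sf_restored_up_enhancer = 6L),
    seed = seed)
}

# memoised fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_study(small_config())
  }
  .fixtures$small
}

default_study <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- simulate_study(synthetic_config(seed = 101L))
  }
  .fixtures$default
}
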