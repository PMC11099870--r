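# PFM handling, window extraction, ZOOPS scanning, dinucleotide shuffling
# and hypergeometric motif enrichment.

test_that("PFM round-trips through the JASPAR-style text format", {
  m <- pfm_from_consensus("TGASTCA", id = "bzip", name = "bZIP core")
  decoy <- pfm_from_consensus("CACGTG", id = "ebox")
  tf <- tempfile(fileext = ".pfm")
  write_pfm(list(m, decoy), tf)
  back <- read_pfm(tf)
  expect_equal(names(back), c("bzip", "ebox"))
  expect_equal(back$bzip$counts, m$counts, tolerance = 1e-9)
  expect_error(pfm_from_consensus("TGANTCA"), "outside")
})

test_that("log-odds columns come from pseudocounted probabilities", {
  m <- pfm_from_consensus("ACGT", weight = 97)
  lo <- pwm_logodds(m, pseudocount = 0.25)
  probs <- 2^lo * 0.25
  expect_equal(unname(colSums(probs)), rep(1, 4), tolerance = 1e-9)
  expect_equal(attr(lo, "max_score"), sum(apply(lo, 2, max)))
})

test_that("window arithmetic is strand-aware and clipped", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(5000, 5000))
  pw <- promoter_windows(genes)
  expect_equal(pw$start[1], 4000)
  expect_equal(pw$end[1], 5100)
  expect_equal(pw$end[2] - pw$start[2], 1100)
  dae <- data.frame(chrom = "chr1", start = 1000, end = 1200,
                    region_id = "d1")
  set.seed(20)
  chrom <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  win <- extract_windows("dae_center", dae, c(chr1 = chrom))
  # center 1100 -> [1050, 1150)
  expect_equal(nchar(win[["d1"]]), 100L)
  expect_equal(win[["d1"]], substr(chrom, 1051, 1150))
  expect_warning(
    extract_windows("promoter",
                    data.frame(gene_id = "g", chrom = "chr1",
                               strand = "+", tss = 500),
                    c(chr1 = chrom)), "clipped")
  expect_error(
    extract_windows("promoter",
                    data.frame(gene_id = "g", chrom = "chr9",
                               strand = "+", tss = 5000),
                    c(chr1 = chrom)), "chr9")
})

test_that("minus-strand promoters equal the mirrored reverse complement", {
  set.seed(21)
  chrom <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  gm <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-", tss = 6000)
  win <- extract_windows("promoter", gm, c(chr1 = chrom))
  # plus-strand coordinates of the minus promoter: [tss+1-100, tss+1+1000)
  fwd <- substr(chrom, 6000 + 1 - 100 + 1, 6000 + 1 + 1000)
  expect_equal(win[["gm"]], revcomp_oracle(fwd))
})

test_that("ZOOPS scanning finds the consensus and honors thresholds", {
  m <- pfm_from_consensus("TGACTCA")
  lo <- pwm_logodds(m)
  hitseq <- paste0(strrep("A", 30), "TGACTCA", strrep("C", 30))
  res <- scan_zoops(c(s = hitseq), m, threshold_frac = 1)
  expect_true(res$hit)
  expect_equal(res$best_score, attr(lo, "max_score"), tolerance = 1e-9)
  # hit on the reverse strand too
  rc <- revcomp_oracle(hitseq)
  expect_true(scan_zoops(c(s = rc), m, threshold_frac = 1)$hit)
  # all-N and too-short sequences never hit
  expect_false(scan_zoops(c(n = strrep("N", 50)), m)$hit)
  expect_false(scan_zoops(c(short = "TGA"), m)$hit)
})

test_that("scan results equal an exhaustive per-window rescoring oracle", {
  set.seed(22)
  m <- pfm_from_consensus("TGASTCA")
  lo <- pwm_logodds(m)
  seqs <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:100)
  got <- scan_zoops(seqs, m, threshold_frac = 0.8)
  oracle_best <- vapply(seqs, function(s) {
    best <- -Inf
    for (str in c(s, revcomp_oracle(s))) {
      ch <- strsplit(str, "")[[1]]
      for (o in 1:(length(ch) - 6)) {
        sc <- 0
        for (l in 1:7) sc <- sc + lo[ch[o + l - 1], l]
        best <- max(best, sc)
      }
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(got$best_score, oracle_best, tolerance = 1e-9)
  expect_equal(got$hit, oracle_best >= 0.8 * attr(lo, "max_score"))
})

test_that("hit flags are strand-symmetric and monotone in the threshold", {
  set.seed(25)
  m <- pfm_from_consensus("TGASTCA")
  seqs <- vapply(1:60, function(i) {
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:60)
  fwd <- scan_zoops(seqs, m, threshold_frac = 0.75)
  rc <- vapply(seqs, revcomp_oracle, character(1))
  rev <- scan_zoops(rc, m, threshold_frac = 0.75)
  expect_equal(fwd$hit, rev$hit)
  hits_loose <- sum(scan_zoops(seqs, m, threshold_frac = 0.6)$hit)
  hits_tight <- sum(scan_zoops(seqs, m, threshold_frac = 0.9)$hit)
  expect_lte(hits_tight, hits_loose)
})

test_that("dinucleotide shuffle preserves doublet composition", {
  set.seed(26)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE,
                    prob = c(0.4, 0.1, 0.2, 0.3)), collapse = "")
  sh <- dinuc_shuffle(s)
  doublets <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  expect_equal(nchar(sh), nchar(s))
  expect_equal(doublets(sh), doublets(s))
  expect_false(sh == s)  # astronomically unlikely to be identity
})

test_that("enrichment p is the hypergeometric tail on hit counts", {
  # deterministic hit structure: targets rich in the word, background poor
  m <- pfm_from_consensus("TGACTCA")
  with_word <- function(n) {
    vapply(seq_len(n), function(i) {
      paste0(strrep("A", 20), "TGACTCA", strrep("G", 20))
    }, character(1))
  }
  without <- function(n) vapply(seq_len(n), function(i) strrep("AC", 25),
                                character(1))
  targets <- c(with_word(8), without(2))
  names(targets) <- paste0("t", 1:10)
  bg <- c(with_word(10), without(90))
  names(bg) <- paste0("b", 1:100)
  res <- motif_enrichment(targets, list(m), background = bg)
  expect_equal(res$target_hits, 8L)
  expect_equal(res$background_hits, 10L)
  expect_equal(res$p, hyper_tail(8, 18, 110, 10), tolerance = 1e-12)
  # equal hit rates are not enriched
  res0 <- motif_enrichment(targets[1:4], list(m),
                           background = setNames(with_word(4),
                                                 paste0("b", 1:4)))
  expect_gte(res0$p, 0.5)
  expect_error(motif_enrichment(targets, list(m),
                                background = targets), "share")
  expect_error(motif_enrichment(targets, list(m), background = bg[0]),
               "empty background")
})

test_that("the planted motif outranks decoys against a shuffled background", {
  st <- small_study()
  tr <- st$expression$truth
  down <- tr$feature[grepl("down", tr$class)]
  gsel <- st$genome$genes[st$genome$genes$gene_id %in% down, ]
  win <- extract_windows("promoter", gsel, st$sequences$seqs)
  res <- motif_enrichment(win, st$sequences$motifs, seed = 99)
  expect_equal(res$motif[1], "bZIP_core")
  expect_lt(res$padj[1], 0.05)
})
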