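# The synthetic-study generator: layout guarantees, determinism, planted
# truth consistency and distributional sanity.

test_that("TADs tile each chromosome exactly, back to back", {
  cfg <- synthetic_config(n_chroms = 1L, chrom_length = 100000L,
                          n_tads_per_chrom = 4L, n_genes = 10L,
                          n_regions = 5L,
                          deg_classes = c(shared_up = 2L),
                          dar_classes = c(hg_up = 1L), seed = 1L)
  g <- simulate_genome(cfg)
  expect_equal(g$tads$start, c(0, 25000, 50000, 75000))
  expect_equal(g$tads$end, c(25000, 50000, 75000, 100000))
  # uniform tiling leaves no gaps: consecutive starts equal previous ends
  expect_equal(g$tads$start[-1], g$tads$end[-4])
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 77L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  # and genuinely different under another seed
  s3 <- simulate_study(small_config(seed = 78L))
  expect_false(identical(s1$expression$counts, s3$expression$counts))
})

test_that("every TSS and enhancer lies in exactly one TAD (brute force)", {
  st <- small_study()
  tads <- st$genome$tads
  count_containing <- function(chrom, lo, hi) {
    sum(as.character(tads$chrom) == as.character(chrom) &
          tads$start <= lo & hi <= tads$end)
  }
  for (i in seq_len(nrow(st$genome$genes))) {
    g <- st$genome$genes[i, ]
    expect_equal(count_containing(g$chrom, g$tss, g$tss + 1), 1)
  }
  for (i in seq_len(nrow(st$genome$regions))) {
    r <- st$genome$regions[i, ]
    expect_equal(count_containing(r$chrom, r$start, r$end), 1)
  }
})

test_that("candidate regions never overlap promoter windows", {
  st <- small_study()
  pw <- promoter_windows(st$genome$genes)
  expect_equal(nrow(overlap_query(st$genome$regions, pw)), 0L)
})

test_that("planted class labels exactly determine the nonzero lfcs", {
  st <- small_study()
  tr <- st$expression$truth
  conds <- st$config$conditions_expression
  for (i in seq_len(nrow(tr))) {
    want <- glucomem:::deg_class_lfc(tr$class[i], conds, st$config$deg_lfc)
    got <- unlist(tr[i, paste0("lfc_", conds)])
    expect_equal(unname(got), unname(want))
  }
  # the memory_SF column realizes restoration: sf classes go to zero
  sf <- tr$class %in% c("shared_up_sf_restored", "shared_down_sf_restored")
  expect_true(all(tr$lfc_memory_SF[sf] == 0))
  expect_true(all(tr$lfc_memory[sf] != 0))
})

test_that("null genes have sample means near their baseline", {
  st <- default_study()
  tr <- st$expression$truth
  null <- tr$class == "none"
  m <- rowMeans(st$expression$counts[null, ])
  mu <- tr$base_mean[null]
  alpha <- st$config$nb_dispersion_expression
  se <- sqrt((mu + alpha * mu^2) / ncol(st$expression$counts))
  # tolerance 4 SE per gene; allow for size-factor jitter with a small
  # fraction of excursions
  expect_gte(mean(abs(m - mu) <= 4 * se), 0.99)
})

test_that("planted fold changes are realized in the counts", {
  st <- default_study()
  tr <- st$expression$truth
  cnt <- st$expression$counts
  cond <- st$expression$samples$condition
  ratio <- rowMeans(cnt[, cond == "HG"]) /
    rowMeans(cnt[, cond == "control"])
  up <- grepl("^shared_up", tr$class) & tr$base_mean >= 100
  # lfc = 2: empirical HG/control ratio concentrates in [2^1.5, 2^2.5]
  expect_gte(mean(ratio[up] >= 2^1.5 & ratio[up] <= 2^2.5), 0.8)
  expect_gt(median(ratio[up]), 2^1.5)
  # stable accessibility regions: fold within [1/1.5, 1.5]
  at <- st$accessibility$truth
  acnt <- st$accessibility$counts
  acond <- st$accessibility$samples$condition
  afold <- rowSums(acnt[, acond == "HG"]) /
    rowSums(acnt[, acond == "control"])
  stable <- at$class == "none" & at$base_mean >= 200
  expect_gte(mean(afold[stable] > 1 / 1.5 & afold[stable] < 1.5), 0.99)
})

test_that("restored accessibility classes carry the planted fold pattern", {
  st <- small_study()
  at <- st$accessibility$truth
  sf <- grepl("^sf_restored", at$class)
  expect_true(all(2^at$lfc_memory[sf] >= 2))
  expect_true(all(at$lfc_memory_SF[sf] == 0))
  pers <- grepl("^persistent_up", at$class)
  expect_true(all(at$lfc_memory_SF[pers] > 0))
})

test_that("enhancer-class regions are covered by both histone marks", {
  st <- small_study()
  at <- st$accessibility$truth
  enh <- st$genome$regions[at$is_enhancer, ]
  hit4 <- unique(overlap_query(enh, st$accessibility$k4me1)$query_idx)
  hit27 <- unique(overlap_query(enh, st$accessibility$k27ac)$query_idx)
  expect_setequal(hit4, seq_len(nrow(enh)))
  expect_setequal(hit27, seq_len(nrow(enh)))
  # non-enhancer regions are never co-marked
  non <- st$genome$regions[!at$is_enhancer, ]
  both <- intersect(unique(overlap_query(non, st$accessibility$k4me1)$query_idx),
                    unique(overlap_query(non, st$accessibility$k27ac)$query_idx))
  expect_length(both, 0)
})

test_that("motif planting follows p_target exactly at the extremes", {
  cfg1 <- small_config(seed = 9L)
  cfg1$p_target <- 1
  st1 <- simulate_study(cfg1)
  tr <- st1$expression$truth
  down <- tr$feature[grepl("down", tr$class)]
  gsel <- st1$genome$genes[st1$genome$genes$gene_id %in% down, ]
  win <- extract_windows("promoter", gsel, st1$sequences$seqs)
  expect_true(all(grepl("TGA[CG]TCA", win)))
  # enhancer central windows contain the word on one of the strands
  enh <- st1$genome$regions[st1$accessibility$truth$is_enhancer, ]
  ewin <- extract_windows("dae_center", enh, st1$sequences$seqs)
  hit <- vapply(ewin, function(s) {
    grepl("TGA[CG]TCA", s) || grepl("TGA[CG]TCA", revcomp_oracle(s))
  }, logical(1))
  expect_true(all(hit))
  cfg0 <- small_config(seed = 9L)
  cfg0$p_target <- 0
  st0 <- simulate_study(cfg0)
  expect_equal(nrow(st0$sequences$embedded), 0L)
})

test_that("background chance hits match the binomial expectation", {
  set.seed(30)
  n_seq <- 100
  len <- 500
  seqs <- vapply(seq_len(n_seq), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }, character(1))
  hits <- sum(vapply(seqs, function(s) {
    length(gregexpr("TGA[CG]TCA", s)[[1]][
      gregexpr("TGA[CG]TCA", s)[[1]] > 0])
  }, numeric(1)))
  # a length-7 degenerate word (2 of 4^7) at 494 offsets per sequence
  p <- 2 / 4^7
  expected <- n_seq * (len - 6) * p
  sd <- sqrt(n_seq * (len - 6) * p * (1 - p))
  expect_lt(abs(hits - expected), 3 * sd)
})

test_that("the NB sampler approaches the Poisson limit as alpha -> 0", {
  set.seed(33)
  x <- glucomem:::rnb(50000, mu = 100, dispersion = 1e-6)
  expect_lt(abs(var(x) / mean(x) - 1), 0.03)
  # and is visibly overdispersed at alpha = 0.05
  y <- glucomem:::rnb(50000, mu = 100, dispersion = 0.05)
  expect_gt(var(y) / mean(y), 4)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(deg_classes = c(shared_up = 10000L)),
               "exceed")
  expect_error(synthetic_config(deg_classes = c(bogus_class = 5L)),
               "unknown DEG")
  expect_error(synthetic_config(nb_dispersion_expression = 0), "positive")
  expect_error(synthetic_config(deg_lfc = -1), "positive")
  expect_error(synthetic_config(consensus = "TGAXTCA"), "outside")
  expect_error(simulate_genome(synthetic_config(n_genes = 5000L,
                                                deg_classes = integer(0))),
               "infeasible packing")
})
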