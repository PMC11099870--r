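# Consensus-peak construction and the Poisson differential-accessibility
# test (fold > 1.5 and Poisson p < 1e-4).

test_that("consensus keeps only cross-replicate peaks as merged spans", {
  r1 <- data.frame(chrom = "chr1", start = c(100, 1000), end = c(200, 1100))
  r2 <- data.frame(chrom = "chr1", start = 150, end = 250)
  cons <- consensus_peaks(list(r1, r2))
  # [100,200) + [150,250) merge to [100,250); [1000,1100) has no partner
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 250)
  # disjoint replicates give an empty consensus
  r3 <- data.frame(chrom = "chr1", start = 300, end = 400)
  expect_equal(nrow(consensus_peaks(list(r1, r3))), 0L)
  expect_warning(consensus_peaks(list(r1, r1[0, ])), "empty")
  expect_error(consensus_peaks(list(r1)), "two")
})

test_that("consensus equals the brute-force all-pairs overlap filter", {
  set.seed(31)
  r1 <- rand_intervals(500)
  r2 <- rand_intervals(500)
  cons <- consensus_peaks(list(r1, r2))
  ov <- brute_overlaps(r1, r2)
  spans <- do.call(rbind, lapply(unique(ov$query_idx), function(i) {
    js <- ov$subject_idx[ov$query_idx == i]
    data.frame(chrom = r1$chrom[i],
               start = min(r1$start[i], r2$start[js]),
               end = max(r1$end[i], r2$end[js]))
  }))
  # merge overlapping oracle spans the same way (sweep line)
  spans <- spans[order(spans$chrom, spans$start), ]
  merged <- list()
  for (i in seq_len(nrow(spans))) {
    last <- if (length(merged) > 0) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chrom == spans$chrom[i] &&
        spans$start[i] <= last$end) {
      merged[[length(merged)]]$end <- max(last$end, spans$end[i])
    } else {
      merged[[length(merged) + 1]] <- spans[i, ]
    }
  }
  oracle <- do.call(rbind, merged)
  rownames(oracle) <- NULL
  rownames(cons) <- NULL
  expect_equal(cons, oracle)
})

test_that("fold gate and Poisson gate must both hold for a DAR call", {
  regions <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                        end = c(400, 1400, 2400),
                        region_id = c("r1", "r2", "r3"))
  # library totals match, so normalized counts equal raw counts at
  # scale = total: lambda floors and tails are exactly interpretable
  counts <- cbind(ref = c(10, 100, 890), trt = c(40, 130, 830))
  res <- poisson_differential(regions, counts, c("ref", "trt"),
                              "ref", "trt", scale = 1000)
  # fold 4 with P(X >= 40 | 10) << 1e-4 -> more accessible
  expect_true(res$is_dar[1])
  expect_equal(res$direction[1], "more_accessible")
  expect_equal(res$p[1], pois_tail_kahan(40, 10), tolerance = 1e-12)
  # fold 1.3 fails the fold gate no matter how small the tail p
  expect_false(res$is_dar[2])
  expect_lt(res$p[2], 0.01)
  expect_false(res$is_dar[3])
})

test_that("equal normalized counts are never DARs", {
  regions <- data.frame(chrom = "chr1", start = c(0, 500),
                        end = c(400, 900), region_id = c("r1", "r2"))
  counts <- cbind(a = c(200, 800), b = c(200, 800))
  res <- poisson_differential(regions, counts, c("a", "b"), "a", "b")
  expect_equal(res$fold, c(1, 1))
  expect_false(any(res$is_dar))
})

test_that("swapping conditions mirrors calls and inverts the fold", {
  set.seed(4)
  n <- 200
  regions <- data.frame(chrom = "chr1", start = seq(0, by = 500, length.out = n),
                        end = seq(400, by = 500, length.out = n),
                        region_id = paste0("r", 1:n))
  counts <- cbind(a1 = rnbinom(n, mu = 300, size = 100),
                  a2 = rnbinom(n, mu = 300, size = 100),
                  b1 = rnbinom(n, mu = c(rep(900, 30), rep(300, n - 30)),
                               size = 100),
                  b2 = rnbinom(n, mu = c(rep(900, 30), rep(300, n - 30)),
                               size = 100))
  cond <- c("a", "a", "b", "b")
  fw <- poisson_differential(regions, counts, cond, "a", "b")
  bw <- poisson_differential(regions, counts, cond, "b", "a")
  expect_equal(fw$fold, 1 / bw$fold, tolerance = 1e-12)
  expect_equal(fw$is_dar, bw$is_dar)
  map <- c(more_accessible = "less_accessible",
           less_accessible = "more_accessible", none = "none")
  expect_equal(unname(map[fw$direction]), bw$direction)
})

test_that("per-condition scaling leaves all calls unchanged", {
  set.seed(5)
  n <- 150
  regions <- data.frame(chrom = "chr1",
                        start = seq(0, by = 500, length.out = n),
                        end = seq(400, by = 500, length.out = n),
                        region_id = paste0("r", 1:n))
  counts <- cbind(a1 = rnbinom(n, mu = 400, size = 200),
                  a2 = rnbinom(n, mu = 400, size = 200),
                  b1 = rnbinom(n, mu = 500, size = 200),
                  b2 = rnbinom(n, mu = 500, size = 200))
  cond <- c("a", "a", "b", "b")
  r1 <- poisson_differential(regions, counts, cond, "a", "b")
  counts2 <- counts
  counts2[, cond == "b"] <- counts2[, cond == "b"] * 7L
  r2 <- poisson_differential(regions, counts2, cond, "a", "b")
  expect_equal(r1$fold, r2$fold, tolerance = 1e-12)
  expect_equal(r1$is_dar, r2$is_dar)
  expect_equal(r1$direction, r2$direction)
})

test_that("Poisson tails agree with compensated summation to 1e-12", {
  for (lambda in c(0.5, 1, 10, 100, 1000, 10000)) {
    for (k in unique(ceiling(lambda * c(0.2, 0.8, 1, 1.5, 2.5)))) {
      p_pkg <- ppois(k - 1, lambda, lower.tail = FALSE)
      p_oracle <- pois_tail_kahan(k, lambda)
      if (p_oracle > 1e-300) {
        expect_lt(abs(p_pkg - p_oracle) / p_oracle, 1e-12)
      }
    }
  }
})

test_that("zero-library and empty-region inputs are rejected", {
  regions <- data.frame(chrom = "chr1", start = 0, end = 400,
                        region_id = "r1")
  expect_error(poisson_differential(regions[0, ], matrix(0, 0, 2),
                                    c("a", "b"), "a", "b"), "empty")
  expect_error(poisson_differential(regions, cbind(a = 0L, b = 5L),
                                    c("a", "b"), "a", "b"), "zero total")
})

test_that("planted fold-2 DARs are recovered and stable regions stay quiet", {
  cfg <- synthetic_config(
    n_regions = 1000L,
    conditions_accessibility = c("control", "HG"),
    dar_classes = c(hg_up = 50L, hg_down = 50L),
    deg_classes = integer(0),
    mean_count_range_accessibility = c(200, 600), seed = 3L)
  regions <- data.frame(region_id = sprintf("r%04d", 1:1000),
                        chrom = "chr1",
                        start = seq(0, by = 1000, length.out = 1000),
                        end = seq(400, by = 1000, length.out = 1000))
  sim <- simulate_accessibility(cfg, regions)
  res <- poisson_differential(regions, sim$counts,
                              sim$samples$condition, "control", "HG")
  truth_dar <- sim$truth$lfc_HG != 0
  sens <- mean(res$is_dar[truth_dar])
  false_rate <- mean(res$is_dar[!truth_dar])
  expect_gte(sens, 0.9)
  expect_lte(false_rate, 1e-3)
  # recovered directions match the planted sign
  hit <- res$is_dar & truth_dar
  expect_true(all((res$direction[hit] == "more_accessible") ==
                    (sim$truth$lfc_HG[hit] > 0)))
})
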