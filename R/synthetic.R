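# Synthetic-study generator. Produces a fully self-consistent miniature
# study — genome, TAD partition, gene models, candidate enhancer regions,
# NB-distributed expression and accessibility counts with planted
# differential classes, histone-mark peaks, sequences with planted bZIP-core
# occurrences, and gene sets — with a ground-truth table for every feature,
# so each pipeline stage can be benchmarked against known truth.

# evaluate `code` under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

# NB sampler in the mean/dispersion parameterization (Var = mu + a mu^2)
rnb <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# closed vocabularies for planted classes
DEG_CLASSES <- c("shared_up", "shared_down",
                 "shared_up_sf_restored", "shared_down_sf_restored",
                 "shared_up_oe_restored", "shared_down_oe_restored",
                 "hg_unique_up", "hg_unique_down",
                 "memory_unique_up", "memory_unique_down")
DAR_CLASSES <- c("hg_up", "hg_up_enhancer", "hg_down",
                 "persistent_up", "persistent_up_enhancer", "persistent_down",
                 "sf_restored_up", "sf_restored_up_enhancer")

#' Configuration of a synthetic glucose-memory study
#'
#' Defaults define a miniature two-chromosome study: 7 expression arms
#' (control, HG, memory, memory+SF, HG+SF, NRF2-OE under HG and memory) with
#' 3 replicates each, 4 accessibility arms with 2 replicates each, TADs
#' tiling each chromosome, genes with strand-aware promoters, and candidate
#' enhancer regions placed only in non-promoter (intronic/intergenic) space.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_tads_per_chrom TADs per chromosome (uniform tiling).
#' @param n_genes,n_regions total genes / candidate enhancer regions.
#' @param n_samples_expression,n_samples_accessibility replicates per
#'   condition.
#' @param conditions_expression,conditions_accessibility condition labels;
#'   `control` must be first.
#' @param deg_classes named integer vector of planted DEG class sizes
#'   (names from the closed vocabulary; see Details).
#' @param deg_lfc planted |log2 fold change| for DEG classes.
#' @param dar_classes named integer vector of planted DAR class sizes.
#' @param dar_lfc planted |log2 fold change| for DAR classes (1 = fold 2).
#' @param nb_dispersion_expression,nb_dispersion_accessibility NB dispersion
#'   alpha (variance mu + alpha mu^2); must be positive.
#' @param mean_count_range_expression,mean_count_range_accessibility range
#'   of per-feature baseline means.
#' @param gene_length_range range of gene span lengths (bp).
#' @param region_width candidate enhancer region width (bp).
#' @param consensus planted motif consensus (IUPAC S allowed for C/G).
#' @param p_target probability that a target sequence receives an embedded
#'   motif occurrence.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#'
#' @details DEG class labels combine a base pattern (`shared`, `hg_unique`,
#' `memory_unique`), a direction (`up`/`down`) and an optional restoration
#' tag (`sf_restored`, `oe_restored`). `shared` classes carry the same
#' planted log2FC in HG and memory; restoration tags zero the planted
#' effect in the corresponding intervention arm(s). DAR classes follow the
#' same scheme (`hg_*` = HG only, `persistent_*` = HG + memory + memory_SF,
#' `sf_restored_*` = HG + memory but zero in memory_SF); the `_enhancer`
#' suffix marks regions that will be co-covered by H3K4me1 and H3K27ac
#' peaks.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_chroms = 2L,
    chrom_length = 1500000L,
    n_tads_per_chrom = 8L,
    n_genes = 600L,
    n_regions = 800L,
    n_samples_expression = 3L,
    n_samples_accessibility = 2L,
    conditions_expression = c("control", "HG", "memory", "memory_SF",
                              "HG_SF", "OE_HG", "OE_memory"),
    conditions_accessibility = c("control", "HG", "memory", "memory_SF"),
    deg_classes = c(shared_up = 15L, shared_down = 9L,
                    shared_up_sf_restored = 20L,
                    shared_down_sf_restored = 15L,
                    shared_up_oe_restored = 22L,
                    shared_down_oe_restored = 17L,
                    hg_unique_up = 20L, hg_unique_down = 13L,
                    memory_unique_up = 15L, memory_unique_down = 10L),
    deg_lfc = 2,
    dar_classes = c(hg_up = 20L, hg_up_enhancer = 12L, hg_down = 4L,
                    persistent_up = 6L, persistent_up_enhancer = 6L,
                    persistent_down = 2L,
                    sf_restored_up = 18L, sf_restored_up_enhancer = 14L),
    dar_lfc = 1,
    nb_dispersion_expression = 0.05,
    nb_dispersion_accessibility = 0.005,
    mean_count_range_expression = c(50, 500),
    mean_count_range_accessibility = c(200, 600),
    gene_length_range = c(600, 1500),
    region_width = 400L,
    consensus = "TGASTCA",
    p_target = 0.8,
    seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    n_tads_per_chrom = as.integer(n_tads_per_chrom),
    n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
    n_samples_expression = as.integer(n_samples_expression),
    n_samples_accessibility = as.integer(n_samples_accessibility),
    conditions_expression = conditions_expression,
    conditions_accessibility = conditions_accessibility,
    deg_classes = deg_classes, deg_lfc = deg_lfc,
    dar_classes = dar_classes, dar_lfc = dar_lfc,
    nb_dispersion_expression = nb_dispersion_expression,
    nb_dispersion_accessibility = nb_dispersion_accessibility,
    mean_count_range_expression = mean_count_range_expression,
    mean_count_range_accessibility = mean_count_range_accessibility,
    gene_length_range = as.integer(gene_length_range),
    region_width = as.integer(region_width),
    consensus = toupper(consensus), p_target = p_target,
    seed = as.integer(seed))
  if (cfg$n_tads_per_chrom < 1) stop("need at least one TAD per chromosome")
  if (sum(cfg$deg_classes) > cfg$n_genes) {
    stop("planted DEG class sizes exceed n_genes")
  }
  if (sum(cfg$dar_classes) > cfg$n_regions) {
    stop("planted DAR class sizes exceed n_regions")
  }
  bad_deg <- setdiff(names(cfg$deg_classes), DEG_CLASSES)
  if (length(bad_deg) > 0) {
    stop("unknown DEG class label(s): ", paste(bad_deg, collapse = ", "))
  }
  bad_dar <- setdiff(names(cfg$dar_classes), DAR_CLASSES)
  if (length(bad_dar) > 0) {
    stop("unknown DAR class label(s): ", paste(bad_dar, collapse = ", "))
  }
  if (cfg$deg_lfc <= 0 || cfg$dar_lfc <= 0) {
    stop("planted effect sizes for up classes must be positive")
  }
  if (cfg$nb_dispersion_expression <= 0 ||
      cfg$nb_dispersion_accessibility <= 0) {
    stop("NB dispersion must be positive")
  }
  bad_chr <- setdiff(strsplit(cfg$consensus, "")[[1]],
                     c("A", "C", "G", "T", "S"))
  if (length(bad_chr) > 0) {
    stop("consensus has characters outside ACGT(S): ",
         paste(unique(bad_chr), collapse = ""))
  }
  if (cfg$p_target < 0 || cfg$p_target > 1) stop("p_target must be in [0,1]")
  if (!"control" %in% cfg$conditions_expression) {
    stop("conditions_expression must include 'control'")
  }
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

#' Simulate the genome layout: chromosomes, TADs, genes, enhancer regions
#'
#' TADs tile each chromosome back-to-back (half-open), so every position —
#' in particular every gene TSS and every candidate enhancer — lies in
#' exactly one TAD. Genes are laid out in per-chromosome slots with a
#' strand-aware promoter window (TSS-1000..TSS+100) that candidate enhancer
#' regions are guaranteed not to overlap; regions never straddle a TAD
#' boundary.
#'
#' @param config a [synthetic_config()].
#' @return list: `chroms` (chrom, length), `tads` (BED-like + `tad_id`),
#'   `genes` (`gene_id`, `chrom`, `strand`, `tss`, `start`, `end`),
#'   `exons` (per-gene exon intervals), `regions` (`region_id` + interval).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    chroms <- data.frame(chrom = paste0("chr", seq_len(config$n_chroms)),
                         length = config$chrom_length,
                         stringsAsFactors = FALSE)
    tads <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
      b <- floor(seq(0, config$chrom_length,
                     length.out = config$n_tads_per_chrom + 1))
      data.frame(chrom = chroms$chrom[ci], start = b[-length(b)],
                 end = b[-1],
                 tad_id = sprintf("tad_%s_%02d", chroms$chrom[ci],
                                  seq_len(config$n_tads_per_chrom)),
                 stringsAsFactors = FALSE)
    }))
    # genes spread over chromosomes as evenly as possible, one per slot
    per_chrom <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
    extra <- config$n_genes %% config$n_chroms
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    regions_per_slot <- ceiling(config$n_regions / config$n_genes)
    slot_w <- config$chrom_length %/% max(per_chrom)
    glen_max <- max(config$gene_length_range)
    need <- 1200L + glen_max + 1050L + 100L +
      regions_per_slot * (config$region_width + 100L)
    if (slot_w < need) {
      stop("infeasible packing: slot width ", slot_w, " bp < required ",
           need, " bp; reduce n_genes/n_regions/gene_length_range or ",
           "increase chrom_length")
    }
    tad_bounds <- floor(seq(0, config$chrom_length,
                            length.out = config$n_tads_per_chrom + 1))
    genes <- list()
    exons <- list()
    regions <- list()
    gid <- 0L
    rid <- 0L
    n_regions_left <- config$n_regions
    for (ci in seq_len(config$n_chroms)) {
      for (si in seq_len(per_chrom[ci])) {
        gid <- gid + 1L
        s <- (si - 1L) * slot_w
        glen <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
        gstart <- s + 1200L
        gend <- gstart + glen
        strand <- sample(c("+", "-"), 1)
        tss <- if (strand == "+") gstart else gend - 1L
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene_%04d", gid), chrom = chroms$chrom[ci],
          strand = strand, tss = tss, start = gstart, end = gend,
          stringsAsFactors = FALSE)
        # 2-4 exons: random internal cuts, alternating exon/intron
        n_ex <- sample(2:4, 1)
        cuts <- sort(sample(seq(gstart + 50L, gend - 50L, by = 10L),
                            2L * (n_ex - 1L)))
        bounds <- c(gstart, cuts, gend)
        ex_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ex_end <- bounds[seq(2, length(bounds), by = 2)]
        exons[[gid]] <- data.frame(chrom = chroms$chrom[ci],
                                   start = ex_start, end = ex_end,
                                   gene_id = sprintf("gene_%04d", gid),
                                   stringsAsFactors = FALSE)
        # candidate enhancer regions: intergenic zone after the gene and
        # its downstream promoter reserve, never crossing a TAD boundary
        n_here <- min(regions_per_slot, n_regions_left)
        if (n_here > 0) {
          zone_lo <- gend + 1050L
          zone_hi <- s + slot_w - 50L
          sub_w <- (zone_hi - zone_lo) %/% regions_per_slot
          for (k in seq_len(n_here)) {
            rid <- rid + 1L
            n_regions_left <- n_regions_left - 1L
            lo <- zone_lo + (k - 1L) * sub_w
            hi <- lo + sub_w
            # segments of the sub-slot that avoid TAD boundaries
            inner <- tad_bounds[tad_bounds > lo & tad_bounds < hi]
            seg <- data.frame(lo = c(lo, inner), hi = c(inner, hi))
            seg <- seg[seg$hi - seg$lo >= config$region_width, , drop = FALSE]
            if (nrow(seg) == 0) {
              stop("infeasible packing: no boundary-free placement for a ",
                   "region of ", config$region_width, " bp")
            }
            avail <- seg$hi - seg$lo - config$region_width + 1L
            pick <- sample.int(nrow(seg), 1, prob = avail)
            start <- seg$lo[pick] +
              sample.int(avail[pick], 1) - 1L
            regions[[rid]] <- data.frame(
              region_id = sprintf("region_%04d", rid),
              chrom = chroms$chrom[ci], start = start,
              end = start + config$region_width, stringsAsFactors = FALSE)
          }
        }
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    regions <- do.call(rbind, regions)
    # construction guarantees; fail loudly if violated
    pw <- promoter_windows(genes)
    if (nrow(overlap_query(regions, pw)) > 0) {
      stop("internal error: candidate region overlaps a promoter window")
    }
    list(chroms = chroms, tads = tads, genes = genes, exons = exons,
         regions = regions)
  })
}

# planted log2FC per expression condition for one class label
deg_class_lfc <- function(class, conditions, lfc) {
  dir <- ifelse(grepl("down", class), -1,
                ifelse(grepl("up", class), 1, 0))
  in_hg <- grepl("^(shared|hg_unique)", class)
  in_mem <- grepl("^(shared|memory_unique)", class)
  sf_rest <- grepl("sf_restored", class)
  oe_rest <- grepl("oe_restored", class)
  base <- c(control = 0,
            HG = dir * lfc * in_hg,
            memory = dir * lfc * in_mem,
            HG_SF = if (sf_rest) 0 else dir * lfc * in_hg,
            memory_SF = if (sf_rest) 0 else dir * lfc * in_mem,
            OE_HG = if (oe_rest) 0 else dir * lfc * in_hg,
            OE_memory = if (oe_rest) 0 else dir * lfc * in_mem)
  out <- base[conditions]
  out[is.na(out)] <- 0
  names(out) <- conditions
  out
}

# planted log2FC per accessibility condition for one class label
dar_class_lfc <- function(class, conditions, lfc) {
  dir <- ifelse(grepl("down", class), -1,
                ifelse(grepl("up", class), 1, 0))
  in_hg <- grepl("^(hg|persistent|sf_restored)", class)
  in_mem <- grepl("^(persistent|sf_restored)", class)
  persists <- grepl("^persistent", class)
  base <- c(control = 0,
            HG = dir * lfc * in_hg,
            memory = dir * lfc * in_mem,
            memory_SF = if (persists) dir * lfc else 0)
  out <- base[conditions]
  out[is.na(out)] <- 0
  names(out) <- conditions
  out
}

# assign class labels to feature ids: `sizes` named counts, rest "none"
assign_classes <- function(ids, sizes) {
  cls <- rep("none", length(ids))
  if (sum(sizes) > 0) {
    pick <- sample(seq_along(ids), sum(sizes))
    cls[pick] <- rep(names(sizes), times = sizes)
  }
  cls
}

#' Simulate NB expression counts with planted DEG classes
#'
#' Counts for gene g in sample (condition c, replicate r) are drawn
#' NB(mean = s_r * mu_g * 2^lfc_{g,c}, dispersion alpha), with per-sample
#' factors s_r ~ U(0.8, 1.2) and baseline means mu_g uniform in
#' `mean_count_range_expression`. Planted classes realize the study's set
#' structure (shared / unique / restored); the truth table records each
#' gene's class and planted log2FC per condition.
#'
#' @param config a [synthetic_config()].
#' @param genes data.frame with at least `gene_id` (e.g. from
#'   [simulate_genome()]).
#' @return list: `counts` (genes x samples integer matrix), `samples`
#'   (`sample_id`, `condition`, `replicate`, `size_factor`), `truth`
#'   (`feature`, `class`, `base_mean`, one `lfc_<condition>` column per
#'   condition).
#' @export
simulate_expression_counts <- function(config, genes) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$nb_dispersion_expression <= 0) {
    stop("NB dispersion must be positive")
  }
  ids <- genes$gene_id
  if (sum(config$deg_classes) > length(ids)) {
    stop("planted DEG class sizes exceed the number of genes")
  }
  with_seed(config$seed + 1L, {
    conds <- config$conditions_expression
    n_rep <- config$n_samples_expression
    samples <- data.frame(
      sample_id = paste0(rep(conds, each = n_rep), "_r",
                         rep(seq_len(n_rep), length(conds))),
      condition = rep(conds, each = n_rep),
      replicate = rep(seq_len(n_rep), length(conds)),
      size_factor = round(stats::runif(length(conds) * n_rep, 0.8, 1.2), 4),
      stringsAsFactors = FALSE)
    cls <- assign_classes(ids, config$deg_classes)
    mu <- stats::runif(length(ids), config$mean_count_range_expression[1],
                       config$mean_count_range_expression[2])
    lfc <- t(vapply(cls, deg_class_lfc, numeric(length(conds)),
                    conditions = conds, lfc = config$deg_lfc))
    colnames(lfc) <- conds
    counts <- matrix(0L, nrow = length(ids), ncol = nrow(samples),
                     dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      m <- samples$size_factor[j] * mu * 2^lfc[, samples$condition[j]]
      counts[, j] <- rnb(length(ids), m, config$nb_dispersion_expression)
    }
    truth <- data.frame(feature = ids, class = cls, base_mean = mu,
                        stringsAsFactors = FALSE)
    for (cn in conds) truth[[paste0("lfc_", cn)]] <- lfc[, cn]
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate accessibility counts, replicate peaks and histone-mark peaks
#'
#' Region counts follow the same NB scheme as expression (dispersion
#' `nb_dispersion_accessibility`); planted DAR classes have |log2 fold| =
#' `dar_lfc` (fold 2 by default). Each replicate gets a peak BED (the
#' regions with a small coordinate jitter plus replicate-specific noise
#' peaks that the consensus step should remove). Regions whose class carries
#' the `_enhancer` suffix are covered by one H3K4me1 and one H3K27ac
#' interval; other regions get at most one mark.
#'
#' @param config a [synthetic_config()].
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`.
#' @return list: `counts`, `samples`, `truth` (with `is_enhancer`),
#'   `peaks` (named list of per-sample interval data.frames), `k4me1`,
#'   `k27ac` (mark interval data.frames).
#' @export
simulate_accessibility <- function(config, regions) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(regions) || nrow(regions) == 0) stop("region list is empty")
  if (config$nb_dispersion_accessibility <= 0) {
    stop("NB dispersion must be positive")
  }
  with_seed(config$seed + 2L, {
    conds <- config$conditions_accessibility
    n_rep <- config$n_samples_accessibility
    samples <- data.frame(
      sample_id = paste0(rep(conds, each = n_rep), "_r",
                         rep(seq_len(n_rep), length(conds))),
      condition = rep(conds, each = n_rep),
      replicate = rep(seq_len(n_rep), length(conds)),
      stringsAsFactors = FALSE)
    ids <- regions$region_id
    cls <- assign_classes(ids, config$dar_classes)
    mu <- stats::runif(length(ids),
                       config$mean_count_range_accessibility[1],
                       config$mean_count_range_accessibility[2])
    lfc <- t(vapply(cls, dar_class_lfc, numeric(length(conds)),
                    conditions = conds, lfc = config$dar_lfc))
    colnames(lfc) <- conds
    counts <- matrix(0L, nrow = length(ids), ncol = nrow(samples),
                     dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      m <- mu * 2^lfc[, samples$condition[j]]
      counts[, j] <- rnb(length(ids), m,
                         config$nb_dispersion_accessibility)
    }
    # per-replicate peak calls: jittered regions + replicate-unique noise
    peaks <- stats::setNames(vector("list", nrow(samples)),
                             samples$sample_id)
    chrom_len <- config$chrom_length
    for (j in seq_len(nrow(samples))) {
      jit_l <- sample(0:30, length(ids), replace = TRUE)
      jit_r <- sample(0:30, length(ids), replace = TRUE)
      pk <- data.frame(chrom = regions$chrom,
                       start = pmax(0L, regions$start - jit_l),
                       end = pmin(chrom_len, regions$end + jit_r),
                       name = ids, stringsAsFactors = FALSE)
      n_noise <- max(5L, length(ids) %/% 20L)
      np_start <- sample.int(chrom_len - 300L, n_noise)
      noise <- data.frame(chrom = sample(unique(regions$chrom), n_noise,
                                         replace = TRUE),
                          start = np_start, end = np_start + 250L,
                          name = paste0("noise_", samples$sample_id[j], "_",
                                        seq_len(n_noise)),
                          stringsAsFactors = FALSE)
      clash <- unique(overlap_query(
        noise, data.frame(chrom = pk$chrom, start = pmax(0L, pk$start - 60L),
                          end = pk$end + 60L))$query_idx)
      if (length(clash) > 0) noise <- noise[-clash, , drop = FALSE]
      pk <- rbind(pk, noise)
      peaks[[j]] <- pk[order(pk$chrom, pk$start), , drop = FALSE]
    }
    # histone marks: enhancer-class regions carry both, others at most one
    is_enh <- grepl("_enhancer$", cls)
    n_enh <- sum(is_enh)
    mark_track <- function(prefix, pad_range) {
      if (n_enh == 0) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          stringsAsFactors = FALSE))
      }
      pad <- sample(pad_range, n_enh * 2, replace = TRUE)
      data.frame(chrom = regions$chrom[is_enh],
                 start = pmax(0L, regions$start[is_enh] -
                                pad[seq_len(n_enh)]),
                 end = regions$end[is_enh] + pad[n_enh + seq_len(n_enh)],
                 name = paste0(prefix, "_", seq_len(n_enh)),
                 stringsAsFactors = FALSE)
    }
    k4 <- mark_track("k4me1", 20:80)
    k27 <- mark_track("k27ac", 10:60)
    # K4me1-only marks on a third of the non-enhancer planted DARs
    single <- which(!is_enh & cls != "none")
    single <- single[stats::runif(length(single)) < 1 / 3]
    if (length(single) > 0) {
      k4 <- rbind(k4, data.frame(
        chrom = regions$chrom[single], start = regions$start[single],
        end = regions$end[single],
        name = paste0("k4me1_only_", seq_along(single)),
        stringsAsFactors = FALSE))
    }
    truth <- data.frame(feature = ids, class = cls, is_enhancer = is_enh,
                        base_mean = mu, stringsAsFactors = FALSE)
    for (cn in conds) truth[[paste0("lfc_", cn)]] <- lfc[, cn]
    list(counts = counts, samples = samples, truth = truth, peaks = peaks,
         k4me1 = k4[order(k4$chrom, k4$start), , drop = FALSE],
         k27ac = k27[order(k27$chrom, k27$start), , drop = FALSE])
  })
}

# draw a concrete word from the consensus (S -> C or G)
draw_consensus_word <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  chars[chars == "S"] <- sample(c("C", "G"), sum(chars == "S"),
                                replace = TRUE)
  paste(chars, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate genome sequences with planted motif occurrences
#'
#' Chromosome sequences are uniform-random ACGT. With probability
#' `p_target`, each target — the promoter window of a planted down-DEG and
#' the central window of an enhancer-class region — receives one embedded
#' occurrence of the consensus (default TGA(C/G)TCA). Promoter insertions
#' are placed on the gene's strand so the strand-aware extracted promoter
#' contains the literal word; enhancer insertions go within +/- 43 bp of
#' the region midpoint (inside the +/- 50 bp motif-scan window) on a random
#' strand. Also builds the PFM library: the planted bZIP-core motif plus
#' decoy motifs.
#'
#' @param config a [synthetic_config()].
#' @param genome output of [simulate_genome()].
#' @param expr_truth expression truth table ([simulate_expression_counts()]).
#' @param atac_truth accessibility truth table ([simulate_accessibility()]).
#' @return list: `seqs` (named character, one per chromosome), `motifs`
#'   (PFM list, planted motif first), `embedded` (data.frame of insertion
#'   records).
#' @export
simulate_sequences <- function(config, genome, expr_truth, atac_truth) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 3L, {
    seqs <- stats::setNames(vapply(seq_len(nrow(genome$chroms)), function(i) {
      paste(sample(DNA_BASES, genome$chroms$length[i], replace = TRUE),
            collapse = "")
    }, character(1)), genome$chroms$chrom)
    wlen <- nchar(config$consensus)
    embedded <- list()
    plant <- function(chrom, pos, word) {
      # pos: 0-based start of the insertion
      substr(seqs[[chrom]], pos + 1L, pos + wlen) <<- word
    }
    # promoters of planted down-DEGs
    down_ids <- expr_truth$feature[grepl("down", expr_truth$class)]
    gsel <- genome$genes[genome$genes$gene_id %in% down_ids, , drop = FALSE]
    pw <- promoter_windows(gsel)
    for (i in seq_len(nrow(gsel))) {
      if (stats::runif(1) >= config$p_target) next
      word <- draw_consensus_word(config$consensus)
      if (gsel$strand[i] == "-") word <- revcomp_chr(word)
      pos <- pw$start[i] + sample.int(pw$end[i] - pw$start[i] - wlen, 1)
      plant(as.character(pw$chrom[i]), pos, word)
      embedded[[length(embedded) + 1L]] <- data.frame(
        target_id = gsel$gene_id[i], type = "promoter",
        chrom = pw$chrom[i], pos = pos, stringsAsFactors = FALSE)
    }
    # central windows of enhancer-class regions
    enh_ids <- atac_truth$feature[atac_truth$is_enhancer]
    rsel <- genome$regions[genome$regions$region_id %in% enh_ids, ,
                           drop = FALSE]
    if (nrow(rsel) > 0) {
      mid <- interval_midpoint(rsel)
      for (i in seq_len(nrow(rsel))) {
        if (stats::runif(1) >= config$p_target) next
        word <- draw_consensus_word(config$consensus)
        if (stats::runif(1) < 0.5) word <- revcomp_chr(word)
        pos <- mid[i] - 43L + sample.int(86L - wlen, 1)
        plant(as.character(rsel$chrom[i]), pos, word)
        embedded[[length(embedded) + 1L]] <- data.frame(
          target_id = rsel$region_id[i], type = "enhancer",
          chrom = rsel$chrom[i], pos = pos, stringsAsFactors = FALSE)
      }
    }
    motifs <- list(
      pfm_from_consensus(config$consensus, id = "bZIP_core",
                         name = "bZIP core TGA(C/G)TCA"),
      pfm_from_consensus("AGATAAGA", id = "GATA_like", name = "GATA-like"),
      pfm_from_consensus("CACGTG", id = "Ebox_like", name = "E-box-like"),
      pfm_from_consensus("TGTTTAC", id = "FOX_like", name = "forkhead-like"),
      pfm_from_consensus("GGGGCGGGG", id = "KLF_SP_like",
                         name = "KLF/SP GC-box-like"))
    names(motifs) <- vapply(motifs, `[[`, "", "id")
    list(seqs = seqs, motifs = motifs,
         embedded = if (length(embedded) > 0) do.call(rbind, embedded)
                    else data.frame(target_id = character(),
                                    type = character(), chrom = character(),
                                    pos = integer()))
  })
}

#' Simulate gene-set collections (GMT-style)
#'
#' A "pathway" set is built for each planted DEG base class (60% of the
#' class members plus random fillers), alongside random sets, so
#' over-representation of the planted classes is recoverable.
#'
#' @param config a [synthetic_config()].
#' @param expr_truth expression truth table.
#' @param n_random number of purely random sets.
#' @return named list of character vectors.
#' @export
simulate_gene_sets <- function(config, expr_truth, n_random = 8L) {
  with_seed(config$seed + 4L, {
    ids <- expr_truth$feature
    sets <- list()
    for (cl in unique(expr_truth$class[expr_truth$class != "none"])) {
      members <- expr_truth$feature[expr_truth$class == cl]
      core <- sample(members, max(1L, round(0.6 * length(members))))
      filler <- sample(setdiff(ids, core), 10L)
      sets[[paste0("pathway_", cl)]] <- sample(c(core, filler))
    }
    for (k in seq_len(n_random)) {
      sets[[sprintf("random_set_%02d", k)]] <- sample(ids, 30L)
    }
    sets
  })
}

#' Simulate a complete synthetic study
#'
#' Runs every generator stage under the configuration's seed and optionally
#' writes all artifacts as plain-text files (counts TSV, BED6, FASTA, GMT,
#' JASPAR-style PFM, truth TSVs, YAML config echo).
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory (created if missing).
#' @return list: `config`, `genome`, `expression`, `accessibility`,
#'   `sequences`, `gene_sets`.
#' @export
simulate_study <- function(config = synthetic_config(), dir = NULL) {
  genome <- simulate_genome(config)
  expression <- simulate_expression_counts(config, genome$genes)
  accessibility <- simulate_accessibility(config, genome$regions)
  sequences <- simulate_sequences(config, genome, expression$truth,
                                  accessibility$truth)
  gene_sets <- simulate_gene_sets(config, expression$truth)
  study <- list(config = config, genome = genome, expression = expression,
                accessibility = accessibility, sequences = sequences,
                gene_sets = gene_sets)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(...) file.path(dir, ...)
    write_tsv(genome$chroms, p("chroms.tsv"))
    write_bed(cbind(genome$tads[, c("chrom", "start", "end")],
                    name = genome$tads$tad_id), p("tads.bed"))
    write_gene_table(genome$genes, p("genes.tsv"))
    write_bed(cbind(genome$exons[, c("chrom", "start", "end")],
                    name = genome$exons$gene_id), p("exons.bed"))
    write_bed(cbind(genome$regions[, c("chrom", "start", "end")],
                    name = genome$regions$region_id), p("regions.bed"))
    write_counts(expression$counts, p("expression_counts.tsv"))
    write_tsv(expression$samples, p("expression_samples.tsv"))
    write_tsv(expression$truth, p("truth_expression.tsv"))
    write_counts(accessibility$counts, p("accessibility_counts.tsv"))
    write_tsv(accessibility$samples, p("accessibility_samples.tsv"))
    write_tsv(accessibility$truth, p("truth_accessibility.tsv"))
    for (nm in names(accessibility$peaks)) {
      write_bed(accessibility$peaks[[nm]], p(paste0("peaks_", nm, ".bed")))
    }
    write_bed(accessibility$k4me1, p("k4me1.bed"))
    write_bed(accessibility$k27ac, p("k27ac.bed"))
    write_fasta(sequences$seqs, p("genome.fa"))
    write_pfm(sequences$motifs, p("motifs.pfm"))
    write_gmt(gene_sets, p("gene_sets.gmt"))
    yaml::write_yaml(unclass(config), p("config.yaml"))
  }
  study
}
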