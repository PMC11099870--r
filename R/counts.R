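# Count-matrix statistics: median-of-ratios normalization, a moment/Wald
# negative-binomial contrast with the study's DEG thresholds, and Fisher
# over-representation of gene sets.

#' Median-of-ratios size factors
#'
#' For each sample j, \eqn{s_j} is the median over features (restricted to
#' features with positive counts in every sample) of the ratio between the
#' sample's count and the feature's geometric mean across samples. Factors
#' are then rescaled to have geometric mean 1.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) < 1) stop("need at least one sample")
  eligible <- rowSums(counts > 0) == ncol(counts)
  if (!any(eligible)) {
    stop("no feature has positive counts in every sample; a pseudo-",
         "reference fallback is not applied silently - filter or supply ",
         "size factors explicitly")
  }
  lg <- log(counts[eligible, , drop = FALSE])
  ratios <- exp(lg - rowMeans(lg))
  sf <- apply(ratios, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial Wald contrast between two conditions
#'
#' Counts are normalized by size factors (median-of-ratios over the two
#' groups unless supplied). A single moment dispersion
#' \eqn{\hat\alpha = \mathrm{median}_g \max(0, (\hat v_g - \bar y_g)/\bar y_g^2)}
#' is estimated from the within-group pooled variance and mean of the
#' normalized counts. The effect is
#' \eqn{\log_2 FC = \log_2((\hat\mu_B + c)/(\hat\mu_A + c))} with
#' pseudo-count c = 0.5, tested with a Wald z-statistic using
#' \eqn{SE^2 = (1/\ln 2)^2 [ (1/\hat\mu_A + \hat\alpha)/n_A +
#' (1/\hat\mu_B + \hat\alpha)/n_B ]} and a two-sided normal p-value.
#' Benjamini-Hochberg adjustment is applied over tested features; features
#' with zero counts in all samples of the contrast are reported with
#' p = 1, log2FC = 0 and `padj = NA` and excluded from the adjustment.
#'
#' A feature is called differential (`is_deg`) when `padj < padj_cutoff`
#' and `|log2FC| > lfc_cutoff` (strict inequalities; defaults 0.05 and 0.5).
#'
#' @param counts integer matrix, features x samples (rownames = feature ids).
#' @param condition character/factor vector, one label per sample column.
#' @param reference,treatment the two condition labels to contrast
#'   (log2FC is treatment over reference).
#' @param size_factors optional per-sample factors for the selected samples
#'   in column order; computed from the two groups when `NULL`.
#' @param dispersion optional fixed dispersion alpha; estimated when `NULL`.
#' @param padj_cutoff,lfc_cutoff DEG thresholds.
#' @param pseudo fold-change pseudo-count.
#' @return data.frame (one row per feature): `feature`, `base_mean_ref`,
#'   `base_mean_trt`, `log2fc`, `p`, `padj`, `is_deg`, `direction`
#'   (up/down/none), plus the estimated `dispersion` as an attribute.
#' @export
nb_wald_contrast <- function(counts, condition, reference, treatment,
                             size_factors = NULL, dispersion = NULL,
                             padj_cutoff = 0.05, lfc_cutoff = 0.5,
                             pseudo = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("condition must have one label per sample column")
  }
  for (lab in c(reference, treatment)) {
    if (!lab %in% condition) stop("condition label not found: ", lab)
  }
  sel <- condition %in% c(reference, treatment)
  k <- counts[, sel, drop = FALSE]
  grp <- condition[sel]
  n_a <- sum(grp == reference)
  n_b <- sum(grp == treatment)
  if (n_a < 2 || n_b < 2) stop("need >= 2 replicates per group")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(k)
  if (length(size_factors) != ncol(k) || any(size_factors <= 0)) {
    stop("size_factors must be positive, one per selected sample")
  }
  y <- sweep(k, 2, size_factors, "/")
  ya <- y[, grp == reference, drop = FALSE]
  yb <- y[, grp == treatment, drop = FALSE]
  m_a <- rowMeans(ya)
  m_b <- rowMeans(yb)
  if (is.null(dispersion)) {
    v_pool <- ((n_a - 1) * apply(ya, 1, stats::var) +
                 (n_b - 1) * apply(yb, 1, stats::var)) / (n_a + n_b - 2)
    m_pool <- (n_a * m_a + n_b * m_b) / (n_a + n_b)
    phi <- pmax(0, (v_pool - m_pool) / m_pool^2)
    ok <- is.finite(phi) & m_pool > 0
    dispersion <- if (any(ok)) stats::median(phi[ok]) else 0
  }
  if (dispersion < 0) stop("dispersion must be non-negative")
  lfc <- log2((m_b + pseudo) / (m_a + pseudo))
  se2 <- (1 / log(2))^2 *
    ((1 / m_a + dispersion) / n_a + (1 / m_b + dispersion) / n_b)
  z <- ifelse(is.finite(se2) & se2 > 0, lfc / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  all_zero <- rowSums(k) == 0
  lfc[all_zero] <- 0
  p[all_zero] <- 1
  padj <- rep(NA_real_, nrow(k))
  padj[!all_zero] <- stats::p.adjust(p[!all_zero], method = "BH")
  is_deg <- !is.na(padj) & padj < padj_cutoff & abs(lfc) > lfc_cutoff
  direction <- ifelse(is_deg, ifelse(lfc > 0, "up", "down"), "none")
  out <- data.frame(
    feature = if (is.null(rownames(k))) as.character(seq_len(nrow(k)))
              else rownames(k),
    base_mean_ref = m_a, base_mean_trt = m_b,
    log2fc = lfc, p = p, padj = padj, is_deg = is_deg,
    direction = direction, row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "dispersion") <- dispersion
  out
}

#' DEG ids of a contrast result
#' @param contrast output of [nb_wald_contrast()].
#' @param direction optionally restrict to "up" or "down".
#' @return character vector of feature ids.
#' @export
deg_ids <- function(contrast, direction = NULL) {
  keep <- contrast$is_deg
  if (!is.null(direction)) keep <- keep & contrast$direction == direction
  contrast$feature[keep]
}

#' Gene-set over-representation (one-sided Fisher / hypergeometric)
#'
#' Each gene set is intersected with the universe before testing; the
#' p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)} for k = |query ∩ set| drawn n = |query| times from a
#' universe of size N containing K = |set ∩ universe| successes. A set is
#' flagged enriched when p < `p_cutoff` (BH-adjusted p is also reported).
#'
#' @param query character vector of gene ids (must be contained in
#'   `universe`).
#' @param universe character vector of all testable gene ids.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param p_cutoff enrichment call threshold on the raw p (default 0.05).
#' @return data.frame: `set`, `set_size` (in universe), `overlap`, `p`,
#'   `padj`, `enriched`, ordered as in `gene_sets`.
#' @export
overrepresentation_test <- function(query, universe, gene_sets,
                                    p_cutoff = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe is empty")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    stop("query contains ids outside the universe")
  }
  n_u <- length(universe)
  n_q <- length(query)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(as.character(gene_sets[[nm]])), universe)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p < p_cutoff
  out
}
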