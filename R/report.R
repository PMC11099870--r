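# Set algebra over DEG/DAR identifier sets and the memory report: the
# shared/unique/restored counts and integer percentages that summarize a
# glucose-memory study.

#' Integer percentage, rounded half away from zero
#'
#' @param num,den numerators and denominators (recycled).
#' @return numeric vector of integer-valued percentages; `NA` where the
#'   denominator is 0 or `NA`.
#' @export
pct_int <- function(num, den) {
  x <- 100 * num / den
  out <- sign(x) * floor(abs(x) + 0.5)
  out[is.na(den) | den == 0] <- NA_real_
  out
}

#' Shared and unique feature sets between two contrasts
#'
#' @param a,b character vectors of feature ids (e.g. DEG sets of two
#'   contrasts against the same control).
#' @return list with the shared set, each side's unique set, their sizes and
#'   the integer percentage of each side that is shared.
#' @export
set_algebra <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  shared <- intersect(a, b)
  list(
    shared = shared,
    unique_a = setdiff(a, b),
    unique_b = setdiff(b, a),
    n_a = length(a),
    n_b = length(b),
    n_shared = length(shared),
    pct_shared_of_a = pct_int(length(shared), length(a)),
    pct_shared_of_b = pct_int(length(shared), length(b))
  )
}

#' Restoration of differential calls under an intervention
#'
#' A baseline feature (differential in condition X vs control) is "restored"
#' when it is no longer differential in the intervention contrast
#' (X + treatment vs the same control), and "not restored" when the
#' differential call remains. Direction of the remaining call is not
#' evaluated (see [restoration_directional()] for the stricter variant).
#'
#' @param baseline character vector of feature ids differential in the
#'   baseline contrast.
#' @param intervention character vector of feature ids differential in the
#'   intervention contrast.
#' @return list with the restored / not-restored sets, their sizes, and the
#'   integer percentages remaining and restored (of the baseline).
#' @export
restoration <- function(baseline, intervention) {
  baseline <- unique(as.character(baseline))
  intervention <- unique(as.character(intervention))
  not_restored <- intersect(baseline, intervention)
  restored <- setdiff(baseline, intervention)
  list(
    restored = restored,
    not_restored = not_restored,
    n_baseline = length(baseline),
    n_restored = length(restored),
    n_not_restored = length(not_restored),
    pct_remaining = pct_int(length(not_restored), length(baseline)),
    pct_restored = pct_int(length(restored), length(baseline))
  )
}

#' Direction-aware restoration
#'
#' Like [restoration()], but a feature only counts as "not restored" when it
#' remains differential in the intervention contrast in the same direction
#' as in the baseline contrast.
#'
#' @param baseline named character vector: ids with direction ("up"/"down")
#'   as values, or a data.frame with `feature` and `direction`.
#' @param intervention same format as `baseline`.
#' @return as [restoration()].
#' @export
restoration_directional <- function(baseline, intervention) {
  to_df <- function(x) {
    if (is.data.frame(x)) {
      data.frame(feature = as.character(x$feature),
                 direction = as.character(x$direction))
    } else {
      data.frame(feature = names(x), direction = as.character(x))
    }
  }
  b <- to_df(baseline)
  i <- to_df(intervention)
  key_b <- paste(b$feature, b$direction)
  key_i <- paste(i$feature, i$direction)
  not_restored <- b$feature[key_b %in% key_i]
  restored <- setdiff(b$feature, not_restored)
  list(
    restored = restored,
    not_restored = not_restored,
    n_baseline = nrow(b),
    n_restored = length(restored),
    n_not_restored = length(not_restored),
    pct_remaining = pct_int(length(not_restored), nrow(b)),
    pct_restored = pct_int(length(restored), nrow(b))
  )
}

#' Direction summary of differential-accessibility calls
#'
#' @param results data.frame with logical `is_dar` and `direction`
#'   (`more_accessible` / `less_accessible` / `none`).
#' @return list with total DAR count, counts per direction, and the integer
#'   percentage with increased accessibility (`NA` if there are no DARs).
#' @export
dar_direction_summary <- function(results) {
  dar <- results[results$is_dar, , drop = FALSE]
  n_up <- sum(dar$direction == "more_accessible")
  n_down <- sum(dar$direction == "less_accessible")
  list(n_dar = nrow(dar), n_up = n_up, n_down = n_down,
       percent_up = pct_int(n_up, nrow(dar)))
}

#' Assemble the memory report
#'
#' Gathers the study's set-algebra summaries into one structured,
#' deterministic report object. Every percentage in the report is
#' recomputable from the numerator and denominator stored next to it;
#' [validate_memory_report()] checks exactly that.
#'
#' @param contrasts named list of DE contrast summaries, each a list with at
#'   least `n_deg`, `n_up`, `n_down`.
#' @param shared output of [set_algebra()] on the HG and memory DEG sets
#'   (sets themselves are dropped from the report; sizes are kept).
#' @param shared_directional optional direction-matched [set_algebra()]
#'   output.
#' @param restoration named list of [restoration()] outputs (expression).
#' @param accessibility named list of [dar_direction_summary()] outputs.
#' @param annotation optional named list of [annotation_summary()] outputs.
#' @param daes named list with DAE counts per contrast.
#' @param linkage named list of [concordance_summary()] outputs.
#' @param dar_restoration named list of [restoration()] outputs (regions).
#' @param motifs optional named list of motif-enrichment head rows.
#' @param ora optional over-representation result data.frame.
#' @param config optional configuration echo (thresholds, seeds).
#' @return object of class `memory_report` (a named list).
#' @export
build_report <- function(contrasts = NULL, shared = NULL,
                         shared_directional = NULL, restoration = NULL,
                         accessibility = NULL, annotation = NULL,
                         daes = NULL, linkage = NULL, dar_restoration = NULL,
                         motifs = NULL, ora = NULL, config = NULL) {
  strip_sets <- function(x) {
    if (is.null(x)) return(NULL)
    x[setdiff(names(x), c("shared", "unique_a", "unique_b", "restored",
                          "not_restored"))]
  }
  rep <- list(
    config = config,
    expression = list(
      contrasts = contrasts,
      shared = strip_sets(shared),
      shared_directional = strip_sets(shared_directional),
      restoration = lapply(restoration, strip_sets)
    ),
    accessibility = list(
      direction = accessibility,
      annotation = annotation,
      daes = daes,
      restoration = lapply(dar_restoration, strip_sets)
    ),
    linkage = linkage,
    motifs = motifs,
    ora = ora
  )
  class(rep) <- c("memory_report", "list")
  rep
}

#' Check the internal consistency of a memory report
#'
#' Recomputes every percentage from the stored numerator/denominator pair
#' and checks the conservation identities (restored + not restored =
#' baseline; shared + unique = total; direction counts <= DAR total).
#'
#' @param report a `memory_report`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_memory_report <- function(report) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("memory report invalid: ", msg)
  same_pct <- function(p, num, den) {
    isTRUE(all.equal(p, pct_int(num, den))) ||
      (is.na(p) && (den == 0 || is.na(den)))
  }
  sh <- report$expression$shared
  if (!is.null(sh)) {
    chk(same_pct(sh$pct_shared_of_a, sh$n_shared, sh$n_a), "shared % of A")
    chk(same_pct(sh$pct_shared_of_b, sh$n_shared, sh$n_b), "shared % of B")
    chk(sh$n_shared <= min(sh$n_a, sh$n_b), "shared exceeds a side")
  }
  for (nm in names(report$expression$restoration)) {
    r <- report$expression$restoration[[nm]]
    chk(r$n_restored + r$n_not_restored == r$n_baseline,
        paste0("restoration conservation (", nm, ")"))
    chk(same_pct(r$pct_remaining, r$n_not_restored, r$n_baseline),
        paste0("pct_remaining (", nm, ")"))
    chk(same_pct(r$pct_restored, r$n_restored, r$n_baseline),
        paste0("pct_restored (", nm, ")"))
  }
  for (nm in names(report$accessibility$direction)) {
    d <- report$accessibility$direction[[nm]]
    chk(d$n_up + d$n_down <= d$n_dar, paste0("direction counts (", nm, ")"))
    chk(same_pct(d$percent_up, d$n_up, d$n_dar),
        paste0("percent_up (", nm, ")"))
  }
  for (nm in names(report$accessibility$restoration)) {
    r <- report$accessibility$restoration[[nm]]
    chk(r$n_restored + r$n_not_restored == r$n_baseline,
        paste0("DAR restoration conservation (", nm, ")"))
  }
  for (nm in names(report$linkage)) {
    l <- report$linkage[[nm]]
    chk(l$n_concordant <= l$n_daes_with_target,
        paste0("concordant > linked (", nm, ")"))
    chk(same_pct(l$percent_concordant, l$n_concordant, l$n_daes_with_target),
        paste0("percent_concordant (", nm, ")"))
  }
  invisible(TRUE)
}

#' Serialize a memory report to canonical JSON text
#'
#' The serialization is deterministic (fixed field order, full precision),
#' so byte-identical reports certify identical analyses.
#'
#' @param report a `memory_report`.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
write_report <- function(report, path = NULL) {
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                        pretty = TRUE, null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' MD5 hash of a report's canonical serialization
#' @param report a `memory_report`.
#' @return character MD5 digest.
#' @export
report_hash <- function(report) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_report(report, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.memory_report <- function(x, ...) {
  cat("Glucose-memory study report\n")
  sh <- x$expression$shared
  if (!is.null(sh)) {
    cat(sprintf("  DEGs: %d (A) / %d (B); shared %d (%s%% of A, %s%% of B)\n",
                sh$n_a, sh$n_b, sh$n_shared,
                format(sh$pct_shared_of_a), format(sh$pct_shared_of_b)))
  }
  for (nm in names(x$expression$restoration)) {
    r <- x$expression$restoration[[nm]]
    cat(sprintf("  %s: %d of %d DEGs remained (%s%%); %s%% restored\n",
                nm, r$n_not_restored, r$n_baseline,
                format(r$pct_remaining), format(r$pct_restored)))
  }
  for (nm in names(x$accessibility$direction)) {
    d <- x$accessibility$direction[[nm]]
    cat(sprintf("  %s: %d DARs, %d up (%s%%)\n", nm, d$n_dar, d$n_up,
                format(d$percent_up)))
  }
  for (nm in names(x$linkage)) {
    l <- x$linkage[[nm]]
    cat(sprintf("  %s: %d DAEs with target, %d concordant (%s%%)\n",
                nm, l$n_daes_with_target, l$n_concordant,
                format(l$percent_concordant)))
  }
  invisible(x)
}
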