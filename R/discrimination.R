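# Four-level pairwise informativeness classification and panel summaries.
#
# For every unordered strain pair at one locus the marker is scored as:
#   1 informative          - both amplified, patterns distinct
#   2 partially informative - amplified in exactly one of the two
#   3 identical patterns    - both amplified, patterns identical
#   4 non-informative       - no amplification in either
# Levels 1 and 2 together constitute "positive discrimination". Level 3,
# although grouped with level 2 as "partially informative" in prose, is not
# counted as positive (the printed arithmetic is positive = distinct +
# one-sided). Percentages are reported on both bases in use: over all
# pairs, and over positive pairs.

INFO_LEVEL_LABELS <- c(`1` = "informative (distinct patterns)",
                       `2` = "partial (amplified in one)",
                       `3` = "identical patterns",
                       `4` = "non-informative (no amplification)")

get_pattern <- function(fp, locus) {
  p <- fp$patterns[[locus]]
  if (is.null(p)) {
    msb_stop(sprintf("locus '%s' missing from fingerprint of strain '%s'",
                     locus, fp$strain_name), "msb_missing_data_error")
  }
  p
}

#' Classify one strain pair at one locus
#'
#' @param a,b `strain_fingerprint` objects; the locus must be present in
#'   both (as amplified or as an explicit no-amplification) — a missing
#'   locus is missing data, not level 4.
#' @param locus Locus identifier.
#' @param resolution_bp Gel resolution used for pattern comparison.
#' @return Integer informativeness level in 1:4 (see module description).
#' @export
classify_pair <- function(a, b, locus, resolution_bp = 2L) {
  pa <- get_pattern(a, locus)
  pb <- get_pattern(b, locus)
  amp_a <- pa$state == "amplified"
  amp_b <- pb$state == "amplified"
  if (!amp_a && !amp_b) return(4L)
  if (xor(amp_a, amp_b)) return(2L)
  if (patterns_equal(pa, pb, resolution_bp)) 3L else 1L
}

strain_pairs <- function(strains) {
  if (length(strains) < 2L) {
    msb_stop("a panel needs at least 2 strains", "msb_spec_error")
  }
  utils::combn(strains, 2L)
}

#' Discrimination summary of a panel at one locus
#'
#' Classifies all unordered strain pairs of a panel at one locus and
#' tabulates the four informativeness levels, the positive-discrimination
#' count (levels 1 + 2) and percentages over both bases (all pairs;
#' positive pairs).
#'
#' @param panel Named list of `strain_fingerprint` objects.
#' @param locus Locus identifier.
#' @param resolution_bp Gel resolution in bp.
#' @return An object of class `discrimination_summary`.
#' @export
summarize_discrimination <- function(panel, locus, resolution_bp = 2L) {
  pairs <- strain_pairs(names(panel))
  levels <- apply(pairs, 2L, function(pr) {
    classify_pair(panel[[pr[1L]]], panel[[pr[2L]]], locus, resolution_bp)
  })
  counts <- vapply(1:4, function(l) sum(levels == l), integer(1))
  names(counts) <- as.character(1:4)
  n_pairs <- ncol(pairs)
  positive <- counts[["1"]] + counts[["2"]]
  structure(list(
    locus_name = locus,
    n_strains = length(panel),
    n_pairs = n_pairs,
    counts = counts,
    positive = positive,
    pct_of_all = 100 * counts / n_pairs,
    positive_pct_of_all = 100 * positive / n_pairs,
    pct_of_positive = if (positive > 0) 100 * counts[c("1", "2")] / positive
                      else stats::setNames(c(NA_real_, NA_real_), c("1", "2")),
    resolution_bp = resolution_bp
  ), class = "discrimination_summary")
}

#' @export
print.discrimination_summary <- function(x, ...) {
  cat(sprintf("Discrimination summary - locus %s\n", x$locus_name))
  cat(sprintf("  %d strains, %d pairs, resolution %d bp\n",
              x$n_strains, x$n_pairs, x$resolution_bp))
  for (l in as.character(1:4)) {
    cat(sprintf("  level %s  %-36s %3d pairs (%.1f%% of all)\n",
                l, INFO_LEVEL_LABELS[[l]], x$counts[[l]], x$pct_of_all[[l]]))
  }
  cat(sprintf("  positive discrimination (1+2): %d pairs (%.1f%% of all)\n",
              x$positive, x$positive_pct_of_all))
  if (!is.na(x$pct_of_positive[["1"]])) {
    cat(sprintf("    of positive: %.1f%% distinct patterns, %.1f%% one-sided\n",
                x$pct_of_positive[["1"]], x$pct_of_positive[["2"]]))
  }
  invisible(x)
}

#' @export
as.data.frame.discrimination_summary <- function(x, ...) {
  data.frame(locus = x$locus_name, n_strains = x$n_strains,
             n_pairs = x$n_pairs,
             informative = x$counts[["1"]], one_sided = x$counts[["2"]],
             identical = x$counts[["3"]], no_amplification = x$counts[["4"]],
             positive = x$positive,
             positive_pct = x$positive_pct_of_all,
             stringsAsFactors = FALSE)
}

#' Per-pair classification across several loci
#'
#' Classifies every unordered pair at each locus and derives the best
#' (numerically smallest) level per pair. A pair is "resolved" iff its best
#' level is 1 or 2 — some marker positively discriminates it.
#'
#' @param panel Named list of `strain_fingerprint` objects.
#' @param loci Loci to use; defaults to the loci of the first fingerprint.
#' @param resolution_bp Gel resolution in bp.
#' @return A data.frame with one row per pair: `strain_a`, `strain_b`, one
#'   integer column per locus, `best`, `resolved`.
#' @export
combined_matrix <- function(panel, loci = NULL, resolution_bp = 2L) {
  if (is.null(loci)) loci <- names(panel[[1L]]$patterns)
  pairs <- strain_pairs(names(panel))
  res <- data.frame(strain_a = pairs[1L, ], strain_b = pairs[2L, ],
                    stringsAsFactors = FALSE)
  for (l in loci) {
    res[[l]] <- apply(pairs, 2L, function(pr) {
      classify_pair(panel[[pr[1L]]], panel[[pr[2L]]], l, resolution_bp)
    })
  }
  res$best <- do.call(pmin, res[loci])
  res$resolved <- res$best %in% c(1L, 2L)
  res
}

#' Identify a strain against a reference panel
#'
#' Scores each reference by the fraction of shared loci at which query and
#' reference have identical state and pattern (exact pattern identity at
#' the gel resolution; no partial band credit). Returns the full ranking,
#' ties broken alphabetically by strain name.
#'
#' @param query A `strain_fingerprint`.
#' @param references Named list of `strain_fingerprint` objects.
#' @param loci Loci to consider (default: loci of the query).
#' @param resolution_bp Gel resolution in bp.
#' @return A data.frame `strain`, `score`, `n_shared_loci`, ranked by
#'   decreasing score.
#' @export
identify_strain <- function(query, references, loci = NULL,
                            resolution_bp = 2L) {
  if (length(references) < 1L) {
    msb_stop("at least one reference fingerprint is required", "msb_spec_error")
  }
  if (is.null(loci)) loci <- names(query$patterns)
  rows <- lapply(names(references), function(s) {
    ref <- references[[s]]
    shared <- intersect(intersect(loci, names(query$patterns)),
                        names(ref$patterns))
    if (length(shared) == 0L) {
      return(data.frame(strain = s, score = NA_real_, n_shared_loci = 0L,
                        stringsAsFactors = FALSE))
    }
    hits <- vapply(shared, function(l) {
      classify_pair(query, ref, l, resolution_bp) %in% c(3L, 4L)
    }, logical(1))
    data.frame(strain = s, score = mean(hits),
               n_shared_loci = length(shared), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$score))) {
    msb_stop("query shares no loci with any reference", "msb_no_evidence_error")
  }
  out <- out[order(-out$score, out$strain, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
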