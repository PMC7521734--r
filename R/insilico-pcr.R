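# In-silico PCR: locate primer binding sites on a template and predict the
# amplicons a primer pair would produce.
#
# The binding model is the minimal substitution-only contract used by
# in-silico PCR tools: a primer binds where it matches with at most
# `max_mismatches` substitutions AND its 3'-most `three_prime_exact_bases`
# bases match exactly (extension is initiated at the 3' end, so mismatches
# there abolish amplification). No indels in the primer alignment. Amplicon
# sizes include both primer footprints, matching how PCR product sizes are
# reported on gels.

#' Construct a primer pair
#'
#' @param locus_name Locus identifier.
#' @param forward,reverse Primer sequences written 5'->3'; the reverse
#'   primer anneals to the complement of the forward strand. Both must be
#'   at least 15 bases.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(locus_name, forward, reverse) {
  forward <- check_dna(forward, "forward primer")
  reverse <- check_dna(reverse, "reverse primer")
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    msb_stop("primers must be at least 15 bases long", "msb_spec_error")
  }
  structure(list(locus_name = as.character(locus_name),
                 forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("Primer pair '%s'\n  F 5'-%s-3' (%d nt)\n  R 5'-%s-3' (%d nt)\n",
              x$locus_name, x$forward, nchar(x$forward),
              x$reverse, nchar(x$reverse)))
  invisible(x)
}

# Mismatch count of `primer` against every offset of `template_chars`,
# vectorised over offsets (one pass per primer base).
mismatch_profile <- function(template_chars, primer_chars) {
  n <- length(template_chars)
  p <- length(primer_chars)
  n_off <- n - p + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (i in seq_len(p)) {
    mm <- mm + (template_chars[i:(i + n_off - 1L)] != primer_chars[i])
  }
  mm
}

#' Find primer binding sites on a template
#'
#' Scans both strands of `template` for positions where `primer` binds
#' under the substitution-only, 3'-anchored model. On the minus strand the
#' primer's reverse complement is matched on the forward strand, with the
#' exact-match anchor at the start of the footprint (the primer's 3' end).
#'
#' @param template DNA string.
#' @param template_id Identifier copied into the output.
#' @param primer Primer sequence, 5'->3'.
#' @param max_mismatches Maximum substitutions tolerated (default 2).
#' @param three_prime_exact_bases 3'-terminal bases that must match exactly
#'   (default 3).
#' @return A data.frame with columns `template_id`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (0-based half-open, forward strand), `mismatches`,
#'   sorted by start then strand (`+` first).
#' @export
find_primer_sites <- function(template, template_id, primer,
                              max_mismatches = 2L,
                              three_prime_exact_bases = 3L) {
  template <- check_dna(template, "template")
  primer <- check_dna(primer, "primer")
  p <- nchar(primer)
  if (p >= nchar(template)) {
    msb_stop("primer must be shorter than the template", "msb_spec_error")
  }
  tc <- strsplit(template, "", fixed = TRUE)[[1]]
  site_scan <- function(query, strand) {
    qc <- strsplit(query, "", fixed = TRUE)[[1]]
    mm <- mismatch_profile(tc, qc)
    # anchor: on '+' the primer 3' end is the footprint end; on '-' it is
    # the footprint start (query is the primer's reverse complement there)
    anchor_idx <- if (strand == "+") {
      seq.int(p - three_prime_exact_bases + 1L, p)
    } else {
      seq_len(three_prime_exact_bases)
    }
    anchored <- rep(TRUE, length(mm))
    for (i in anchor_idx) {
      anchored <- anchored & (tc[i:(i + length(mm) - 1L)] == qc[i])
    }
    hits <- which(mm <= max_mismatches & anchored)
    if (length(hits) == 0L) return(NULL)
    data.frame(template_id = template_id, strand = strand,
               start = hits - 1L, end = hits - 1L + p,
               mismatches = mm[hits], stringsAsFactors = FALSE)
  }
  res <- rbind(site_scan(primer, "+"), site_scan(revcomp(primer), "-"))
  if (is.null(res)) {
    res <- data.frame(template_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict PCR amplicons on a template
#'
#' Every combination of a plus-strand site and a minus-strand site fully
#' downstream of it, formed from either primer of the pair (self-pairing is
#' degenerate but real PCR behaviour), yields one amplicon, provided the
#' product is no longer than `max_product_bp`. Identical intervals are
#' collapsed. An empty result models "no amplification".
#'
#' @inheritParams find_primer_sites
#' @param pair A [primer_pair()].
#' @param max_product_bp Maximum product length (default 2000).
#' @return A data.frame with columns `template_id`, `locus_name`, `start`,
#'   `end`, `length_bp`, `sequence`, sorted by start then length.
#' @export
amplify <- function(template, template_id, pair,
                    max_mismatches = 2L, three_prime_exact_bases = 3L,
                    max_product_bp = 2000L) {
  stopifnot(inherits(pair, "primer_pair"))
  template <- check_dna(template, "template")
  sites <- rbind(
    find_primer_sites(template, template_id, pair$forward,
                      max_mismatches, three_prime_exact_bases),
    find_primer_sites(template, template_id, pair$reverse,
                      max_mismatches, three_prime_exact_bases)
  )
  fwd <- sites[sites$strand == "+", , drop = FALSE]
  rev_ <- sites[sites$strand == "-", , drop = FALSE]
  empty <- data.frame(template_id = character(), locus_name = character(),
                      start = integer(), end = integer(),
                      length_bp = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (nrow(fwd) == 0L || nrow(rev_) == 0L) return(empty)
  combos <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev_)))
  starts <- fwd$start[combos$f]
  ends <- rev_$end[combos$r]
  ok <- rev_$start[combos$r] >= fwd$end[combos$f] &
    (ends - starts) <= max_product_bp
  if (!any(ok)) return(empty)
  amp <- data.frame(template_id = template_id,
                    locus_name = pair$locus_name,
                    start = starts[ok], end = ends[ok],
                    stringsAsFactors = FALSE)
  amp <- amp[!duplicated(amp[, c("start", "end")]), , drop = FALSE]
  amp$length_bp <- amp$end - amp$start
  amp$sequence <- substring(template, amp$start + 1L, amp$end)
  amp <- amp[order(amp$start, amp$length_bp), , drop = FALSE]
  rownames(amp) <- NULL
  amp
}

#' Amplify a primer pair across several templates
#'
#' Runs [amplify()] per template and pools the results — a single primer
#' pair can produce products from several templates (two alleles per locus,
#' or a duplicated locus).
#'
#' @param templates Named character vector of DNA templates (names are
#'   template ids).
#' @inheritParams amplify
#' @export
amplify_templates <- function(templates, pair, max_mismatches = 2L,
                              three_prime_exact_bases = 3L,
                              max_product_bp = 2000L) {
  if (is.null(names(templates)) || any(names(templates) == "")) {
    msb_stop("templates must be a named character vector", "msb_spec_error")
  }
  res <- lapply(names(templates), function(id) {
    amplify(templates[[id]], id, pair, max_mismatches,
            three_prime_exact_bases, max_product_bp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Repeat count inside an amplicon
#'
#' Unit count of the largest tract of the given canonical motif inside an
#' amplicon sequence — the "number of repeats" annotated next to a PCR
#' product size.
#'
#' @param amplicon_seq Amplicon DNA sequence.
#' @param motif Repeat unit (any rotation/strand; canonicalised
#'   internally).
#' @param min_units Minimum units for a tract to count (default 5).
#' @return Integer unit count; 0 when no tract of that motif is present.
#' @export
amplicon_repeat_count <- function(amplicon_seq, motif, min_units = 5L) {
  canon <- canonical_motif(motif)
  tr <- find_repeats(amplicon_seq, "amplicon",
                     unit_lengths = nchar(canon), min_units = min_units)
  tr <- tr[tr$motif == canon, , drop = FALSE]
  if (nrow(tr) == 0L) return(0L)
  max(tr$unit_count)
}
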