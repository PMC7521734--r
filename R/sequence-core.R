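# Tandem-repeat motif handling and repeat-tract detection.
#
# Microsatellites are tandem repeats of short (1-6 bp) motifs whose unit
# count varies between strains. A motif written on either strand and in any
# phase denotes the same microsatellite ((CA)n and (TG)n are one locus), so
# motifs are normalised to a canonical representative before comparison.
# Coordinates throughout are 0-based, half-open, on the forward strand.

all_rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n) - 1L, function(i) {
    paste0(substr(unit, i + 1L, n), substr(unit, 1L, i))
  }, character(1))
}

#' Canonical form of a repeat motif
#'
#' Two motif strings denote the same microsatellite if one is a rotation of
#' the other or of its reverse complement (a repeat read on the opposite
#' strand or in a shifted phase). The canonical form is the lexicographically
#' smallest member of that equivalence class, e.g. `canonical_motif("TG")`
#' is `"AC"`.
#'
#' @param unit Repeat unit, 1-6 bases over `{A,C,G,T}`, primitive (not
#'   itself a repetition of a shorter unit; `"TGTG"` is rejected, its unit
#'   is `"TG"`).
#' @return The canonical motif string.
#' @examples
#' canonical_motif("TG")   # "AC"
#' canonical_motif("CAG")  # "AGC"
#' @export
canonical_motif <- function(unit) {
  unit <- check_dna(unit, "motif unit")
  if (nchar(unit) > 6L) {
    msb_stop("motif unit longer than 6 bases", "msb_motif_error")
  }
  if (!is_primitive_unit(unit)) {
    msb_stop(sprintf("motif unit '%s' is a repetition of a shorter unit", unit),
             "msb_motif_error")
  }
  min(c(all_rotations(unit), all_rotations(revcomp(unit))))
}

#' Count mismatches between two aligned sequences
#'
#' Position-wise mismatch count between two already-aligned, gap-free
#' sequences of equal length (e.g. the 9 mismatches over 657 bp that
#' separate two mitochondrial haplotypes). Case-insensitive.
#'
#' @param a,b DNA strings of equal length.
#' @return Integer number of differing positions.
#' @export
hamming_mismatches <- function(a, b) {
  a <- check_dna(a, "sequence a")
  b <- check_dna(b, "sequence b")
  if (nchar(a) != nchar(b)) {
    msb_stop("sequences have unequal lengths", "msb_length_error")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(ca != cb)
}

# Scan the block sequence starting at a given phase and return the longest
# valid tract prefix: perfect units match the first block; an interruption is
# one whole mismatched unit, allowed at most `max_interrupted` times and only
# when flanked on both sides by >= 2 perfect units within the tract.
scan_tract <- function(perfect, max_interrupted) {
  nb <- length(perfect)
  best_m <- 0L
  n_int <- 0L
  last_int <- -10L
  for (t in seq_len(nb) - 1L) {
    if (perfect[t + 1L]) {
      if (t >= last_int + 2L) best_m <- t + 1L
    } else {
      ok <- n_int < max_interrupted &&
        t >= 2L && t >= last_int + 3L &&
        perfect[t] && perfect[t - 1L]
      if (!ok) break
      n_int <- n_int + 1L
      last_int <- t
    }
  }
  if (best_m == 0L) return(NULL)
  used <- perfect[seq_len(best_m)]
  list(m = best_m, unit_count = sum(used), interrupted = sum(!used))
}

#' Find microsatellite repeat tracts in a sequence
#'
#' Reports all maximal tandem-repeat tracts whose perfectly matching unit
#' count reaches `min_units`. Up to `max_interrupted_units` single-unit
#' interruptions are tolerated per tract (a whole mismatched unit, e.g. an
#' AA unit inside a CA run), each flanked on both sides by at least two
#' perfect units. Tracts reported under rotated phases of the same run are
#' collapsed to the leftmost maximal extent; motifs are reported in
#' canonical form.
#'
#' @param sequence DNA string (case-insensitive; characters outside
#'   `{A,C,G,T}` are rejected, not skipped).
#' @param sequence_id Identifier copied into the output.
#' @param unit_lengths Integer vector of repeat-unit lengths to search
#'   (1-6). Default `2` (dinucleotide repeats, the TG/AT loci this design
#'   targets).
#' @param min_units Minimum number of perfect units (>= 2). Default 5.
#' @param max_interrupted_units Maximum interruptions per tract. Default 1.
#' @return A data.frame with columns `sequence_id`, `start`, `end`
#'   (0-based half-open), `motif` (canonical), `unit_count`,
#'   `interrupted_units`, `perfect`, sorted by `start`.
#' @examples
#' find_repeats(paste0("AAA", strrep("TG", 8), "CCC"))
#' @export
find_repeats <- function(sequence, sequence_id = "seq",
                         unit_lengths = 2L, min_units = 5L,
                         max_interrupted_units = 1L) {
  sequence <- check_dna(sequence, "sequence")
  unit_lengths <- sort(unique(as.integer(unit_lengths)))
  if (any(unit_lengths < 1L | unit_lengths > 6L)) {
    msb_stop("unit lengths must be within 1..6", "msb_motif_error")
  }
  min_units <- as.integer(min_units)
  if (min_units < 2L) msb_stop("min_units must be >= 2", "msb_spec_error")
  max_interrupted_units <- as.integer(max_interrupted_units)

  n <- nchar(sequence)
  out <- list()
  for (k in unit_lengths) {
    if (n < k * min_units) next
    starts1 <- seq_len(n - k + 1L)
    kmers <- substring(sequence, starts1, starts1 + k - 1L)
    for (i in starts1) {
      if (i + k * min_units - 1L > n) break
      u <- kmers[i]
      if (!is_primitive_unit(u)) next
      block_pos <- seq.int(i, n - k + 1L, by = k)
      tr <- scan_tract(kmers[block_pos] == u, max_interrupted_units)
      if (is.null(tr) || tr$unit_count < min_units) next
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = sequence_id,
        start = i - 1L,
        end = i - 1L + k * tr$m,
        motif = canonical_motif(u),
        unit_count = tr$unit_count,
        interrupted_units = tr$interrupted,
        perfect = tr$interrupted == 0L,
        k = k,
        stringsAsFactors = FALSE
      )
    }
  }
  finalize_tracts(out)
}

# Shared post-processing: drop tracts contained in a longer tract of the same
# canonical motif, then collapse phase-rotated reports of the same run
# (same motif, start and end each shifted by < unit length) keeping the
# leftmost extent. Used by both the scanner and documented for oracles.
finalize_tracts <- function(tract_list) {
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_count = integer(), interrupted_units = integer(),
                      perfect = logical(), stringsAsFactors = FALSE)
  if (length(tract_list) == 0L) return(empty)
  tr <- do.call(rbind, tract_list)
  tr <- tr[!duplicated(tr[, c("start", "end", "motif")]), , drop = FALSE]
  span <- tr$end - tr$start
  keep <- vapply(seq_len(nrow(tr)), function(j) {
    contained <- tr$motif == tr$motif[j] &
      tr$start <= tr$start[j] & tr$end >= tr$end[j] &
      span > span[j]
    !any(contained)
  }, logical(1))
  tr <- tr[keep, , drop = FALSE]
  tr <- tr[order(tr$start, tr$end, tr$motif), , drop = FALSE]
  keep <- rep(TRUE, nrow(tr))
  for (j in seq_len(nrow(tr))) {
    if (!keep[j]) next
    for (l in seq_len(nrow(tr))) {
      if (l == j || !keep[l]) next
      if (tr$motif[l] == tr$motif[j] &&
          abs(tr$start[l] - tr$start[j]) < tr$k[j] &&
          abs(tr$end[l] - tr$end[j]) < tr$k[j] &&
          (tr$start[l] > tr$start[j] ||
           (tr$start[l] == tr$start[j] && tr$end[l] < tr$end[j]))) {
        keep[l] <- FALSE
      }
    }
  }
  tr <- tr[keep, , drop = FALSE]
  tr$k <- NULL
  rownames(tr) <- NULL
  tr
}
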