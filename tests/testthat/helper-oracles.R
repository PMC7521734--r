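# Independent oracles used to cross-check the scanning implementations:
# an exhaustive-substring tract enumerator, and a primer-site / amplicon
# oracle built on Biostrings::matchPattern. Both are deliberately written
# against the rule definitions, not against the package code paths.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Deterministic primer-free, repeat-poor filler for constructed templates.
rand_dna_fixed <- function(n) substr(strrep("CCATGGTTCAGAGCTA", n %/% 16L + 1L), 1L, n)

# A random sequence with 0-2 planted repeat tracts (possibly interrupted),
# so the repeat-tract comparison exercises non-trivial cases.
rand_repeat_seq <- function(max_len = 200L) {
  n_tracts <- sample(0:2, 1L)
  parts <- rand_dna(sample(5:30, 1L))
  for (i in seq_len(n_tracts)) {
    unit <- sample(c("TG", "AT", "CA", "GA", "CT"), 1L)
    units <- sample(3:15, 1L)
    tract <- strrep(unit, units)
    if (stats::runif(1) < 0.4 && units >= 5L) {
      # plant a single-unit interruption mid-tract
      pos <- sample(3:(units - 2L), 1L)
      bad <- sample(setdiff(c("AA", "CC", "GG", "TT", "AC"), unit), 1L)
      tract <- paste0(strrep(unit, pos - 1L), bad, strrep(unit, units - pos))
    }
    parts <- paste0(parts, tract, rand_dna(sample(5:30, 1L)))
  }
  substr(parts, 1L, max_len)
}

oracle_is_primitive <- function(u) {
  n <- nchar(u)
  if (n == 1L) return(TRUE)
  divs <- seq_len(n - 1L)
  divs <- divs[n %% divs == 0L]
  !any(vapply(divs, function(d) u == strrep(substr(u, 1L, d), n / d),
              logical(1)))
}

# Exhaustive enumeration of all valid tracts, then the maximality and
# phase-collapse rules applied by explicit pairwise filtering.
oracle_find_repeats <- function(s, id = "seq", k_set = 2L, min_units = 5L,
                                max_int = 1L) {
  s <- toupper(s)
  n <- nchar(s)
  found <- list()
  for (k in k_set) {
    starts <- seq_len(max(n - k + 1L, 0L))
    kmers <- substring(s, starts, starts + k - 1L)
    for (i in starts) {
      u <- kmers[i]
      if (!oracle_is_primitive(u)) next
      max_m <- (n - i + 1L) %/% k
      for (m in seq_len(max_m)) {
        blocks <- kmers[seq.int(i, by = k, length.out = m)]
        ints <- which(blocks != u)
        if (length(ints) > max_int) break  # grows monotonically in m
        ok <- all(ints >= 3L & ints <= m - 2L) &&
          (length(ints) < 2L || all(diff(ints) >= 3L)) &&
          !any((ints - 1L) %in% ints)
        # every interruption needs 2 perfect units each side
        ok <- ok && all(vapply(ints, function(j) {
          all(blocks[c(j - 2L, j - 1L, j + 1L, j + 2L)] == u)
        }, logical(1)))
        if (!ok) next
        if (m - length(ints) < min_units) next
        found[[length(found) + 1L]] <- data.frame(
          sequence_id = id, start = i - 1L, end = i - 1L + k * m,
          motif = canonical_motif(u), unit_count = m - length(ints),
          interrupted_units = length(ints),
          perfect = length(ints) == 0L, k = k,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- find_repeats("ACGTACGT", id)[0L, ]
  if (length(found) == 0L) return(empty)
  tr <- do.call(rbind, found)
  tr <- tr[!duplicated(tr[, c("start", "end", "motif")]), , drop = FALSE]
  # maximality: drop tracts strictly contained in another of the same motif
  keep <- rep(TRUE, nrow(tr))
  for (a in seq_len(nrow(tr))) {
    for (b in seq_len(nrow(tr))) {
      if (a == b) next
      if (tr$motif[b] == tr$motif[a] &&
          tr$start[b] <= tr$start[a] && tr$end[b] >= tr$end[a] &&
          (tr$end[b] - tr$start[b]) > (tr$end[a] - tr$start[a])) {
        keep[a] <- FALSE
      }
    }
  }
  tr <- tr[keep, , drop = FALSE]
  # collapse rotated phases of the same run: keep the leftmost extent
  tr <- tr[order(tr$start, tr$end, tr$motif), , drop = FALSE]
  keep <- rep(TRUE, nrow(tr))
  for (a in seq_len(nrow(tr))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(tr))) {
      if (a == b || !keep[b]) next
      if (tr$motif[b] == tr$motif[a] &&
          abs(tr$start[b] - tr$start[a]) < tr$k[a] &&
          abs(tr$end[b] - tr$end[a]) < tr$k[a] &&
          (tr$start[b] > tr$start[a] ||
           (tr$start[b] == tr$start[a] && tr$end[b] < tr$end[a]))) {
        keep[b] <- FALSE
      }
    }
  }
  tr <- tr[keep, , drop = FALSE]
  tr$k <- NULL
  rownames(tr) <- NULL
  tr
}

# Primer-site oracle: candidate positions from Biostrings::matchPattern,
# 3' anchor checked by direct substring comparison.
oracle_primer_sites <- function(template, template_id, primer,
                                max_mm = 2L, anchor = 3L) {
  template <- toupper(template)
  primer <- toupper(primer)
  p <- nchar(primer)
  tpl <- Biostrings::DNAString(template)
  one_strand <- function(query, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(query), tpl,
                                     max.mismatch = max_mm)
    st <- Biostrings::start(hits)
    if (length(st) == 0L) return(NULL)
    mm <- vapply(st, function(s0) {
      sum(strsplit(substring(template, s0, s0 + p - 1L), "")[[1]] !=
            strsplit(query, "")[[1]])
    }, numeric(1))
    anchor_ok <- vapply(st, function(s0) {
      if (strand == "+") {
        substring(template, s0 + p - anchor, s0 + p - 1L) ==
          substring(query, p - anchor + 1L, p)
      } else {
        substring(template, s0, s0 + anchor - 1L) ==
          substring(query, 1L, anchor)
      }
    }, logical(1))
    ok <- anchor_ok & mm <= max_mm
    if (!any(ok)) return(NULL)
    data.frame(template_id = template_id, strand = strand,
               start = st[ok] - 1L, end = st[ok] - 1L + p,
               mismatches = as.integer(mm[ok]), stringsAsFactors = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  res <- rbind(one_strand(primer, "+"), one_strand(rc, "-"))
  if (is.null(res)) {
    res <- find_primer_sites(paste(rep("A", p + 1L), collapse = ""),
                             template_id, strrep("C", p))[0L, ]
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_amplify <- function(template, template_id, pair, max_mm = 2L,
                           anchor = 3L, max_bp = 2000L) {
  sites <- rbind(
    oracle_primer_sites(template, template_id, pair$forward, max_mm, anchor),
    oracle_primer_sites(template, template_id, pair$reverse, max_mm, anchor))
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  out <- list()
  for (a in seq_len(nrow(plus))) {
    for (b in seq_len(nrow(minus))) {
      if (minus$start[b] >= plus$end[a] &&
          minus$end[b] - plus$start[a] <= max_bp) {
        out[[length(out) + 1L]] <- c(plus$start[a], minus$end[b])
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  iv <- unique(do.call(rbind, out))
  iv <- iv[order(iv[, 1L], iv[, 2L] - iv[, 1L]), , drop = FALSE]
  data.frame(start = iv[, 1L], end = iv[, 2L])
}

# Random template (<= 2 kb) with a planted amplifiable locus for a pair.
rand_template <- function(pair) {
  paste0(rand_dna(sample(20:500, 1L)), pair$forward,
         rand_dna(sample(50:600, 1L)), revcomp(pair$reverse),
         rand_dna(sample(20:400, 1L)))
}

# The shipped 9-strain wild-type fixture panel, assembled once per file.
fixture_panel <- function() {
  tab <- read_band_table(system.file("extdata", "bands_fig4_6.tsv",
                                     package = "msbarcode"))
  strains <- readLines(system.file("extdata", "wildtype_strains.txt",
                                   package = "msbarcode"))
  fingerprints_from_table(tab, strains = strains)
}
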