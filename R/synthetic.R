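# Seeded simulator of diploid strain panels with known microsatellite
# genotypes, so every pipeline stage can be tested against ground truth.
#
# The generator emulates the features seen on real strain-typing gels:
# diploid loci (1-2 alleles), an optionally duplicated locus (a second
# genomic copy, up to 4 bands), strain-specific primer-site loss (no
# amplification), fixed indels in the flanks (e.g. a 16 bp deletion private
# to one sub-group), polymerase-slippage stutter producing a modal band
# plus minor satellite bands, and rare mosaic extra alleles at low
# intensity. Stutter operates on whole repeat units (+/- 1 unit per
# amplified molecule) - the minimal model consistent with slippage;
# intensities are relative (modal band = 1) because gels are qualitative.

#' Stutter / mosaicism model
#'
#' @param p_minus,p_plus Probability that an amplified molecule loses /
#'   gains one whole repeat unit (`p_minus + p_plus < 1`). Defaults 0.1 and
#'   0.05: slippage deletes more often than it inserts.
#' @param n_molecules Molecules drawn per amplicon (default 1000).
#' @param mosaic_allele_rate Probability that one extra low-frequency
#'   (mosaic) allele appears at a locus (default 0).
#' @return An object of class `stutter_model`.
#' @export
stutter_model <- function(p_minus = 0.1, p_plus = 0.05,
                          n_molecules = 1000L, mosaic_allele_rate = 0) {
  if (p_minus < 0 || p_plus < 0 || p_minus + p_plus >= 1) {
    msb_stop("need p_minus, p_plus >= 0 and p_minus + p_plus < 1",
             "msb_spec_error")
  }
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) msb_stop("n_molecules must be >= 1", "msb_spec_error")
  if (mosaic_allele_rate < 0 || mosaic_allele_rate > 1) {
    msb_stop("mosaic_allele_rate must be in [0, 1]", "msb_spec_error")
  }
  structure(list(p_minus = p_minus, p_plus = p_plus,
                 n_molecules = n_molecules,
                 mosaic_allele_rate = mosaic_allele_rate),
            class = "stutter_model")
}

#' Synthetic locus specification
#'
#' Describes one strain's genotype at one microsatellite locus: the repeat
#' unit, the flanks carrying the primer sites, 1-2 genomic copies with 1-2
#' allele unit counts each, whether the primer sites are intact in this
#' strain, and an optional fixed deletion in the left flank.
#'
#' @param locus_name Locus identifier.
#' @param motif Repeat unit as written in the template (e.g. `"TG"`).
#' @param primers A [primer_pair()]; the forward primer must occur at the
#'   start of `left_flank`, the reverse complement of the reverse primer at
#'   the end of `right_flank`.
#' @param left_flank,right_flank Flanking DNA containing the primer sites.
#' @param alleles List of 1-2 integer vectors (one per genomic copy), each
#'   of 1-2 repeat unit counts.
#' @param primer_site_intact If `FALSE`, 3 substitutions are planted in the
#'   3' half of each primer site, abolishing amplification.
#' @param fixed_flank_deletion Optional substring deleted from the left
#'   flank in this strain (must occur there exactly once).
#' @return An object of class `synthetic_locus`.
#' @export
synthetic_locus <- function(locus_name, motif, primers,
                            left_flank, right_flank, alleles,
                            primer_site_intact = TRUE,
                            fixed_flank_deletion = NULL) {
  stopifnot(inherits(primers, "primer_pair"))
  motif <- check_dna(motif, "motif")
  left_flank <- check_dna(left_flank, "left flank")
  right_flank <- check_dna(right_flank, "right flank")
  if (!is.list(alleles) || length(alleles) < 1L || length(alleles) > 2L ||
      any(!vapply(alleles, function(a) length(a) %in% 1:2 && all(a >= 1),
                  logical(1)))) {
    msb_stop("alleles must be a list of 1-2 vectors of 1-2 unit counts each",
             "msb_spec_error")
  }
  if (substr(left_flank, 1L, nchar(primers$forward)) != primers$forward) {
    msb_stop("left flank must begin with the forward primer", "msb_spec_error")
  }
  rc <- revcomp(primers$reverse)
  if (substr(right_flank, nchar(right_flank) - nchar(rc) + 1L,
             nchar(right_flank)) != rc) {
    msb_stop("right flank must end with the reverse primer's reverse complement",
             "msb_spec_error")
  }
  if (!is.null(fixed_flank_deletion)) {
    fixed_flank_deletion <- check_dna(fixed_flank_deletion, "flank deletion")
    if (!grepl(fixed_flank_deletion, left_flank, fixed = TRUE)) {
      msb_stop("fixed_flank_deletion does not occur in the left flank",
               "msb_spec_error")
    }
  }
  structure(list(locus_name = locus_name, motif = motif, primers = primers,
                 left_flank = left_flank, right_flank = right_flank,
                 alleles = alleles,
                 primer_site_intact = isTRUE(primer_site_intact),
                 fixed_flank_deletion = fixed_flank_deletion),
            class = "synthetic_locus")
}

# Substitute 3 bases among the given 1-based positions (sampled), each to a
# different base, to kill a primer site.
disrupt_site <- function(seq_chars, positions) {
  pick <- sort(sample(positions, 3L))
  for (p in pick) {
    seq_chars[p] <- sample(setdiff(DNA_BASES, seq_chars[p]), 1L)
  }
  seq_chars
}

#' Build genomic templates for a synthetic locus
#'
#' One template per genomic copy per allele:
#' `left_flank (deletion applied) + motif x unit_count + right_flank`.
#' When `primer_site_intact` is `FALSE`, 3 substitutions are introduced
#' into the 3' half of each primer site of every template. Ground-truth
#' repeat tracts (0-based, half-open) are returned alongside.
#'
#' @param spec A [synthetic_locus()].
#' @param seed Integer seed (drives the disruption substitutions).
#' @return List with `templates` (named character vector), `tracts`
#'   (ground-truth data.frame as from [find_repeats()]) and `true_sizes`
#'   (integer amplicon sizes expected per template).
#' @export
build_templates <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_locus"))
  left <- spec$left_flank
  if (!is.null(spec$fixed_flank_deletion)) {
    left <- sub(spec$fixed_flank_deletion, "", left, fixed = TRUE)
  }
  k <- nchar(spec$motif)
  flen <- nchar(spec$primers$forward)
  rlen <- nchar(spec$primers$reverse)
  templates <- character(0)
  tracts <- list()
  true_sizes <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(spec$alleles)) {
      for (ai in seq_along(spec$alleles[[ci]])) {
        n_units <- spec$alleles[[ci]][ai]
        tpl <- paste0(left, strrep(spec$motif, n_units), spec$right_flank)
        id <- sprintf("%s.copy%d.allele%d", spec$locus_name, ci, ai)
        if (!spec$primer_site_intact) {
          chars <- strsplit(tpl, "", fixed = TRUE)[[1]]
          # forward site at template start; 3' half = its second half
          chars <- disrupt_site(chars, (floor(flen / 2) + 1L):flen)
          # reverse site at template end; primer 3' end maps to the
          # footprint start on the forward strand
          rstart <- length(chars) - rlen + 1L
          chars <- disrupt_site(chars, rstart:(rstart + floor(rlen / 2) - 1L))
          tpl <- paste(chars, collapse = "")
        }
        templates[[id]] <- tpl
        tracts[[length(tracts) + 1L]] <- data.frame(
          sequence_id = id,
          start = nchar(left),
          end = nchar(left) + k * n_units,
          motif = canonical_motif(spec$motif),
          unit_count = n_units,
          interrupted_units = 0L,
          perfect = TRUE,
          stringsAsFactors = FALSE
        )
        true_sizes[[id]] <- nchar(left) + k * n_units + nchar(spec$right_flank)
      }
    }
  })
  list(templates = templates, tracts = do.call(rbind, tracts),
       true_sizes = true_sizes)
}

#' Simulate observed gel bands for one locus
#'
#' Amplifies the templates in silico, then draws `n_molecules` per
#' amplicon with per-molecule unit shifts of -1/0/+1 repeat units at
#' probabilities `(p_minus, 1 - p_minus - p_plus, p_plus)`. Molecule
#' fractions below 0.05 (the detection limit stand-in) are dropped per
#' amplicon; surviving fractions are pooled by size across amplicons and
#' normalised so the modal band has intensity 1. With probability
#' `mosaic_allele_rate` one extra allele (a true size shifted by 2 units)
#' is added at low intensity and flagged `faint`.
#'
#' @param templates Named character vector of templates.
#' @param pair A [primer_pair()].
#' @param motif Repeat unit of the locus (sets the stutter step size).
#' @param stutter A [stutter_model()].
#' @param seed Integer seed.
#' @inheritParams amplify
#' @return A band table (columns `size_bp`, `intensity`, `flags`), sizes
#'   ascending; zero rows when nothing amplifies.
#' @export
simulate_bands <- function(templates, pair, motif,
                           stutter = stutter_model(), seed = 1L,
                           max_mismatches = 2L, three_prime_exact_bases = 3L,
                           max_product_bp = 2000L) {
  stopifnot(inherits(stutter, "stutter_model"))
  k <- nchar(check_dna(motif, "motif"))
  amps <- amplify_templates(templates, pair, max_mismatches,
                            three_prime_exact_bases, max_product_bp)
  if (nrow(amps) == 0L) return(bands(integer(0)))
  with_seed(seed, {
    frac_by_size <- list()
    for (j in seq_len(nrow(amps))) {
      true_size <- amps$length_bp[j]
      draws <- stats::rmultinom(1L, stutter$n_molecules,
                                c(stutter$p_minus,
                                  1 - stutter$p_minus - stutter$p_plus,
                                  stutter$p_plus))[, 1L]
      sizes <- true_size + c(-1L, 0L, 1L) * k
      frac <- draws / stutter$n_molecules
      keep <- frac >= 0.05
      for (m in which(keep)) {
        key <- as.character(sizes[m])
        frac_by_size[[key]] <- (frac_by_size[[key]] %||% 0) + frac[m]
      }
    }
    if (length(frac_by_size) == 0L) return(bands(integer(0)))
    sizes <- as.integer(names(frac_by_size))
    fracs <- unlist(frac_by_size, use.names = FALSE)
    intensity <- fracs / max(fracs)
    flags <- rep("", length(sizes))
    if (stutter$mosaic_allele_rate > 0 &&
        stats::runif(1L) < stutter$mosaic_allele_rate) {
      base_size <- amps$length_bp[sample(nrow(amps), 1L)]
      mosaic_size <- base_size + sample(c(-2L, 2L), 1L) * k
      if (!(mosaic_size %in% sizes) && mosaic_size > 0L) {
        sizes <- c(sizes, mosaic_size)
        intensity <- c(intensity, stats::runif(1L, 0.05, 0.2))
        flags <- c(flags, "faint")
      }
    }
    ord <- order(sizes)
    bands(sizes[ord], pmin(intensity[ord], 1), flags[ord])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a whole strain panel
#'
#' Applies [build_templates()], [amplify()] and [simulate_bands()] per
#' strain and locus, and returns the band table the genotyping pipeline
#' consumes together with the ground-truth fingerprints (built from the
#' true amplicon sizes). Fully reproducible: one global seed, per
#' strain-by-locus sub-seeds derived deterministically from it.
#'
#' @param panel A panel specification as returned by
#'   [read_panel_config()]: list with `primers`, `stutter`,
#'   `resolution_bp` and `strains` (per-strain named lists of
#'   [synthetic_locus()] specs).
#' @param stutter Optional [stutter_model()] overriding the panel's.
#' @param seed Integer global seed.
#' @return List with `band_table` (strain/locus/size_bp/intensity/flags),
#'   `truth` (named list of ground-truth `strain_fingerprint`s),
#'   `true_sizes` (data.frame strain/locus/size_bp) and `templates`
#'   (named character vector, ids `strain|template`).
#' @export
simulate_panel <- function(panel, stutter = NULL, seed = 1L) {
  stutter <- stutter %||% panel$stutter
  stopifnot(inherits(stutter, "stutter_model"))
  resolution_bp <- panel$resolution_bp %||% 2L
  loci <- names(panel$primers)
  rows <- list()
  truth <- list()
  true_size_rows <- list()
  all_templates <- character(0)
  for (strain in names(panel$strains)) {
    truth_patterns <- list()
    for (locus in loci) {
      spec <- panel$strains[[strain]][[locus]]
      sub_seed <- derive_seed(seed, paste(strain, locus, sep = "|"))
      built <- build_templates(spec, seed = sub_seed)
      ids <- paste(strain, names(built$templates), sep = "|")
      tpls <- stats::setNames(built$templates, ids)
      all_templates <- c(all_templates, tpls)
      band_tab <- simulate_bands(built$templates, panel$primers[[locus]],
                                 spec$motif, stutter, seed = sub_seed + 1L)
      if (nrow(band_tab) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          strain = strain, locus = locus, band_tab,
          stringsAsFactors = FALSE)
      }
      if (spec$primer_site_intact) {
        tsz <- sort(unique(unname(built$true_sizes)))
        truth_patterns[[locus]] <- pattern_from_bands(
          locus, bands(tsz), resolution_bp, min_intensity = 0,
          drop_flags = character(0))
        true_size_rows[[length(true_size_rows) + 1L]] <- data.frame(
          strain = strain, locus = locus, size_bp = tsz,
          stringsAsFactors = FALSE)
      } else {
        truth_patterns[[locus]] <- pattern_from_bands(locus, bands(integer(0)),
                                                      resolution_bp)
      }
    }
    truth[[strain]] <- structure(
      list(strain_name = strain, patterns = truth_patterns),
      class = "strain_fingerprint")
  }
  band_table <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(strain = character(), locus = character(),
               size_bp = integer(), intensity = numeric(),
               flags = character(), stringsAsFactors = FALSE)
  rownames(band_table) <- NULL
  list(band_table = band_table, truth = truth,
       true_sizes = do.call(rbind, true_size_rows),
       templates = all_templates)
}
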