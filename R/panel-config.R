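# Structured panel configuration for the synthetic strain simulator.
#
# A panel YAML describes loci (motif, primers, base flank lengths, an
# optional flank insert that some strains carry deleted) and strains
# (per-locus allele unit counts, copy number via nested allele lists,
# primer-site intactness, flank-length adjustments). Flank filler
# sequences are synthesised deterministically from a `flank_seed` recorded
# in the file, so the genomic templates are a pure function of the config:
# the run seed passed to [simulate_panel()] only drives stutter, mosaicism
# and primer-site disruption draws. Fillers are generated repeat-free (no
# homopolymer of 4+, no dinucleotide run of 3+ units) and flank bases
# adjacent to the microsatellite are forced outside the motif alphabet, so
# the planted tract is exactly the ground truth.

# Repeat-free random filler of a given length.
synth_filler <- function(len, seed) {
  if (len < 0L) {
    msb_stop("flank length too small for its primer/insert", "msb_spec_error")
  }
  if (len == 0L) return("")
  with_seed(seed, {
    out <- character(len)
    for (i in seq_len(len)) {
      ok <- DNA_BASES
      if (i >= 4L && out[i - 1L] == out[i - 2L] && out[i - 2L] == out[i - 3L]) {
        ok <- setdiff(ok, out[i - 1L])
      }
      if (i >= 5L && out[i - 1L] == out[i - 3L] && out[i - 2L] == out[i - 4L]) {
        ok <- setdiff(ok, out[i - 2L])
      }
      out[i] <- sample(ok, 1L)
    }
    paste(out, collapse = "")
  })
}

# A base outside the motif alphabet that does not create a 4-homopolymer
# with the 3 preceding bases.
boundary_base <- function(motif, context3) {
  safe <- setdiff(DNA_BASES, strsplit(motif, "", fixed = TRUE)[[1]])
  for (b in safe) {
    if (!(nchar(context3) >= 3L && context3 == strrep(b, 3L))) return(b)
  }
  safe[1L]
}

build_flanks <- function(locus_cfg, pair, left_extra = 0L,
                         with_insert = TRUE, flank_seed = 1L, locus_ord = 1L) {
  motif <- locus_cfg$motif
  fwd <- pair$forward
  rc <- revcomp(pair$reverse)
  insert <- if (with_insert && !is.null(locus_cfg$flank_insert)) {
    locus_cfg$flank_insert
  } else ""
  left_len <- locus_cfg$left_len + as.integer(left_extra)
  fill_len <- left_len - nchar(fwd) - nchar(insert)
  filler <- synth_filler(max(fill_len, 0L), flank_seed + 13L * locus_ord)
  left <- paste0(fwd, insert, filler)
  if (nchar(left) != left_len) {
    msb_stop("left flank length inconsistent with primer/insert",
             "msb_spec_error")
  }
  lb <- boundary_base(motif, substr(left, left_len - 3L, left_len - 1L))
  substr(left, left_len, left_len) <- lb
  right_fill <- synth_filler(locus_cfg$right_len - nchar(rc) - 1L,
                             flank_seed + 13L * locus_ord + 7L)
  right <- paste0(boundary_base(motif, ""), right_fill, rc)
  list(left = left, right = right)
}

#' Read a synthetic panel configuration
#'
#' Parses a panel YAML (see `inst/extdata/paper_like_panel.yaml` for the
#' nine-strain, three-locus panel that mirrors the strain-typing design)
#' into concrete [synthetic_locus()] specs with fully materialised flank
#' sequences.
#'
#' @param path YAML file.
#' @return A panel list with `name`, `resolution_bp`, `stutter`
#'   (a [stutter_model()]), `primers` (named list of [primer_pair()]) and
#'   `strains` (per-strain named lists of [synthetic_locus()]).
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) {
    msb_stop(sprintf("file not found: %s", path), "msb_io_error")
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("flank_seed", "loci", "strains")) {
    if (is.null(cfg[[field]])) {
      msb_stop(sprintf("panel config lacks '%s'", field), "msb_spec_error")
    }
  }
  st <- cfg$stutter %||% list()
  stutter <- stutter_model(st$p_minus %||% 0.1, st$p_plus %||% 0.05,
                           st$n_molecules %||% 1000L,
                           st$mosaic_allele_rate %||% 0)
  primers <- lapply(names(cfg$loci), function(l) {
    primer_pair(l, cfg$loci[[l]]$forward, cfg$loci[[l]]$reverse)
  })
  names(primers) <- names(cfg$loci)
  strains <- lapply(names(cfg$strains), function(s) {
    specs <- lapply(names(cfg$loci), function(l) {
      sc <- cfg$strains[[s]][[l]]
      if (is.null(sc)) {
        msb_stop(sprintf("strain '%s': no spec for locus '%s'", s, l),
                 "msb_spec_error")
      }
      lc <- cfg$loci[[l]]
      deleted <- isTRUE(sc$flank_deletion)
      fl <- build_flanks(lc, primers[[l]],
                         left_extra = sc$left_extra %||% 0L,
                         with_insert = TRUE,
                         flank_seed = cfg$flank_seed,
                         locus_ord = match(l, names(cfg$loci)))
      alleles <- lapply(sc$alleles, as.integer)
      if (deleted && is.null(lc$flank_insert)) {
        msb_stop(sprintf("strain '%s', locus '%s': flank_deletion set but locus has no flank_insert",
                         s, l), "msb_spec_error")
      }
      tryCatch(
        synthetic_locus(l, lc$motif, primers[[l]], fl$left, fl$right,
                        alleles,
                        primer_site_intact = sc$primer_site_intact %||% TRUE,
                        fixed_flank_deletion = if (deleted) lc$flank_insert),
        msb_error = function(e) {
          msb_stop(sprintf("strain '%s', locus '%s': %s", s, l,
                           conditionMessage(e)), "msb_spec_error")
        })
    })
    names(specs) <- names(cfg$loci)
    specs
  })
  names(strains) <- names(cfg$strains)
  list(name = cfg$name %||% "panel",
       resolution_bp = as.integer(cfg$resolution_bp %||% 2L),
       stutter = stutter, primers = primers, strains = strains)
}
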