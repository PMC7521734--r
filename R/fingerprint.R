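# Gel-resolution-aware band patterns and strain fingerprints.
#
# A band pattern is the comparable unit of a fingerprint: the set of
# resolution-merged, filtered band sizes one strain shows at one locus, or
# an explicit "no amplification" state (an informative negative, distinct
# from a locus that was simply never assayed). Bands flagged as faint or as
# part of a stutter smear are excluded by default, because strain
# comparison is done on the reproducible main bands.

BAND_FLAGS <- c("faint", "smear")

#' Construct a band table
#'
#' @param size_bp Integer band sizes (> 0).
#' @param intensity Relative intensities in (0, 1] (modal band = 1).
#' @param flags Character vector of per-band flags, each `""` or a
#'   semicolon-separated subset of `faint`, `smear`.
#' @return A data.frame with columns `size_bp`, `intensity`, `flags`.
#' @export
bands <- function(size_bp, intensity = rep(1, length(size_bp)),
                  flags = rep("", length(size_bp))) {
  size_bp <- as.integer(size_bp)
  if (any(size_bp <= 0L)) msb_stop("band sizes must be > 0", "msb_spec_error")
  if (any(intensity <= 0 | intensity > 1)) {
    msb_stop("band intensities must lie in (0, 1]", "msb_spec_error")
  }
  check_flags(flags)
  data.frame(size_bp = size_bp, intensity = as.numeric(intensity),
             flags = as.character(flags), stringsAsFactors = FALSE)
}

check_flags <- function(flags) {
  parts <- strsplit(as.character(flags), ";", fixed = TRUE)
  bad <- setdiff(unlist(parts), BAND_FLAGS)
  if (length(bad) > 0L) {
    msb_stop(sprintf("unknown band flag(s): %s", paste(bad, collapse = ", ")),
             "msb_io_error")
  }
  invisible(parts)
}

has_flag <- function(flags, which_flags) {
  vapply(strsplit(as.character(flags), ";", fixed = TRUE),
         function(f) any(f %in% which_flags), logical(1))
}

#' Cluster band sizes at a gel resolution
#'
#' Single-linkage clustering of band sizes: two bands co-migrate iff their
#' size difference is strictly below `resolution_bp` (a 2 bp shift is the
#' smallest resolvable difference on the gels this models, so the default
#' resolution is 2). Deterministic and invariant under input order.
#'
#' @param size_bp Integer band sizes.
#' @param resolution_bp Merge resolution in bp (>= 1).
#' @return A list of band classes, each an ascending integer vector of
#'   member sizes; classes sorted ascending. The vector of class
#'   representatives (rounded mean size) is attached as attribute
#'   `"representatives"` and returned by [band_class_representatives()].
#' @examples
#' cluster_bands(c(198, 199, 200), 2)  # one class, representative 199
#' cluster_bands(c(204, 206), 2)       # two classes: 2 bp is resolvable
#' @export
cluster_bands <- function(size_bp, resolution_bp = 2L) {
  resolution_bp <- as.integer(resolution_bp)
  if (resolution_bp < 1L) msb_stop("resolution_bp must be >= 1", "msb_spec_error")
  size_bp <- sort(as.integer(size_bp))
  if (length(size_bp) == 0L) {
    return(structure(list(), representatives = integer(0)))
  }
  breaks <- c(0L, which(diff(size_bp) >= resolution_bp), length(size_bp))
  classes <- lapply(seq_len(length(breaks) - 1L), function(j) {
    size_bp[(breaks[j] + 1L):breaks[j + 1L]]
  })
  reps <- vapply(classes, function(m) as.integer(floor(mean(m) + 0.5)),
                 integer(1))
  structure(classes, representatives = reps)
}

#' @rdname cluster_bands
#' @param classes Result of [cluster_bands()].
#' @export
band_class_representatives <- function(classes) {
  attr(classes, "representatives")
}

#' Band pattern for one strain at one locus
#'
#' Filters the band table (dropping flagged and sub-threshold bands), then
#' clusters the survivors at the gel resolution. A locus that produced any
#' band at all cannot be demoted to "no amplification" by filtering: if
#' filtering removes every band, the strongest filtered band is retained.
#' `state = "no_amplification"` is returned only for an empty band table.
#'
#' @param locus Locus identifier.
#' @param band_tab A band table as from [bands()] (possibly empty).
#' @param resolution_bp Gel resolution in bp (default 2).
#' @param min_intensity Minimum relative intensity retained (default 0.25).
#' @param drop_flags Flags whose bands are excluded (default faint + smear).
#' @return An object of class `band_pattern`: list with `locus_name`,
#'   `state` (`"amplified"` or `"no_amplification"`), and for amplified
#'   patterns `band_classes` (ascending integer representatives).
#' @export
pattern_from_bands <- function(locus, band_tab, resolution_bp = 2L,
                               min_intensity = 0.25,
                               drop_flags = c("faint", "smear")) {
  if (is.null(band_tab) || nrow(band_tab) == 0L) {
    return(structure(list(locus_name = locus, state = "no_amplification",
                          band_classes = integer(0)),
                     class = "band_pattern"))
  }
  check_flags(band_tab$flags)
  drop <- has_flag(band_tab$flags, drop_flags) |
    band_tab$intensity < min_intensity
  kept <- band_tab[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    # amplification happened; keep the strongest of the filtered bands
    strongest <- order(-band_tab$intensity, band_tab$size_bp)[1L]
    kept <- band_tab[strongest, , drop = FALSE]
  }
  classes <- cluster_bands(kept$size_bp, resolution_bp)
  structure(list(locus_name = locus, state = "amplified",
                 band_classes = band_class_representatives(classes)),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  if (x$state == "amplified") {
    cat(sprintf("<%s> bands: %s bp\n", x$locus_name,
                paste(x$band_classes, collapse = ", ")))
  } else {
    cat(sprintf("<%s> no amplification\n", x$locus_name))
  }
  invisible(x)
}

#' Compare two band patterns at a gel resolution
#'
#' Two patterns are equal iff both are amplified with the same number of
#' band classes and each pair of corresponding representatives differs by
#' less than `resolution_bp`, or both are "no amplification". Symmetric;
#' note that equality under a tolerance is not transitive, so equivalence
#' classes must be formed by clustering, never by pairwise closure.
#'
#' @param p,q `band_pattern` objects for the same locus.
#' @param resolution_bp Gel resolution in bp.
#' @return Logical.
#' @export
patterns_equal <- function(p, q, resolution_bp = 2L) {
  stopifnot(inherits(p, "band_pattern"), inherits(q, "band_pattern"))
  if (p$locus_name != q$locus_name) {
    msb_stop(sprintf("patterns are for different loci ('%s' vs '%s')",
                     p$locus_name, q$locus_name), "msb_locus_error")
  }
  if (p$state != q$state) return(FALSE)
  if (p$state == "no_amplification") return(TRUE)
  length(p$band_classes) == length(q$band_classes) &&
    all(abs(p$band_classes - q$band_classes) < resolution_bp)
}

#' Assemble a strain fingerprint from a band table
#'
#' @param strain Strain identifier.
#' @param strain_bands A data.frame with columns `locus`, `size_bp`,
#'   `intensity`, `flags` holding this strain's bands.
#' @param loci Loci to include; a locus with no rows yields an explicit
#'   `no_amplification` pattern. Defaults to the loci present in
#'   `strain_bands`.
#' @inheritParams pattern_from_bands
#' @return An object of class `strain_fingerprint`: list with
#'   `strain_name` and `patterns` (named list of `band_pattern`).
#' @export
fingerprint <- function(strain, strain_bands, loci = NULL,
                        resolution_bp = 2L, min_intensity = 0.25,
                        drop_flags = c("faint", "smear")) {
  if (is.null(loci)) loci <- sort(unique(strain_bands$locus))
  dup <- duplicated(strain_bands[, c("locus", "size_bp")])
  if (any(dup)) {
    msb_stop(sprintf("duplicate band rows for strain '%s'", strain),
             "msb_duplicate_error")
  }
  patterns <- lapply(loci, function(l) {
    pattern_from_bands(l, strain_bands[strain_bands$locus == l, , drop = FALSE],
                       resolution_bp, min_intensity, drop_flags)
  })
  names(patterns) <- loci
  structure(list(strain_name = strain, patterns = patterns),
            class = "strain_fingerprint")
}

#' @export
print.strain_fingerprint <- function(x, ...) {
  cat(sprintf("Strain fingerprint: %s (%d loci)\n",
              x$strain_name, length(x$patterns)))
  for (p in x$patterns) {
    cat("  "); print(p)
  }
  invisible(x)
}

#' Build fingerprints for a whole panel from a band table
#'
#' @param band_table A data.frame with columns `strain`, `locus`,
#'   `size_bp`, `intensity`, `flags` (see [read_band_table()]).
#' @param strains Strains forming the panel. Defaults to the strains
#'   present in the table; pass the full panel explicitly when some panel
#'   members produced no band at any locus.
#' @param loci Loci assayed. Defaults to the loci present in the table. A
#'   strain with no rows at an assayed locus gets an explicit
#'   `no_amplification` pattern; loci outside `loci` are absent from the
#'   fingerprints (missing data, not a negative).
#' @inheritParams pattern_from_bands
#' @return Named list of `strain_fingerprint` objects.
#' @export
fingerprints_from_table <- function(band_table, strains = NULL, loci = NULL,
                                    resolution_bp = 2L, min_intensity = 0.25,
                                    drop_flags = c("faint", "smear")) {
  if (is.null(strains)) strains <- sort(unique(band_table$strain))
  if (is.null(loci)) loci <- sort(unique(band_table$locus))
  fps <- lapply(strains, function(s) {
    fingerprint(s, band_table[band_table$strain == s, , drop = FALSE],
                loci = loci, resolution_bp = resolution_bp,
                min_intensity = min_intensity, drop_flags = drop_flags)
  })
  names(fps) <- strains
  fps
}

# fingerprints -> plain list for JSON serialisation
fingerprint_as_list <- function(fp) {
  lapply(fp$patterns, function(p) {
    if (p$state == "amplified") {
      list(state = p$state, band_classes = p$band_classes)
    } else {
      list(state = p$state)
    }
  })
}

#' Write fingerprints to JSON
#'
#' @param fps Named list of `strain_fingerprint` objects.
#' @param path Output file.
#' @export
write_fingerprints_json <- function(fps, path) {
  out <- lapply(fps, fingerprint_as_list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
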