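# Readers and writers: FASTA (via Biostrings), primer/band/tract TSV,
# run configuration. All tables are tab-separated with a header row;
# readers reject malformed input rather than silently repairing it.

#' Read a multi-record FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header. Duplicate ids are an
#'   error; an empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    msb_stop(sprintf("file not found: %s", path), "msb_io_error")
  }
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    msb_stop("duplicate sequence ids in FASTA", "msb_duplicate_error")
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line wrap width (default 80).
#' @export
write_fasta <- function(sequences, path, width = 80L) {
  set <- Biostrings::DNAStringSet(unlist(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

read_tsv_strict <- function(path, colClasses) {
  if (!file.exists(path)) {
    msb_stop(sprintf("file not found: %s", path), "msb_io_error")
  }
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = NA, check.names = FALSE),
    error = function(e) msb_stop(sprintf("cannot parse %s: %s", path,
                                         conditionMessage(e)), "msb_io_error"))
  missing <- setdiff(names(colClasses), names(tab))
  if (length(missing) > 0L) {
    msb_stop(sprintf("%s: missing column(s): %s", path,
                     paste(missing, collapse = ", ")), "msb_io_error")
  }
  tab
}

#' Read a primer-pair table
#'
#' TSV with columns `locus_name`, `forward`, `reverse`. The shipped
#' fixture `table1_primers.tsv` carries the six pairs of the strain-typing
#' design (16S, beta-actin, COI, ms-c25145, ms-AIP, ms-DMTF1).
#'
#' @param path TSV file.
#' @return Named list of [primer_pair()] objects.
#' @examples
#' primers <- read_primers(system.file("extdata", "table1_primers.tsv",
#'                                     package = "msbarcode"))
#' @export
read_primers <- function(path) {
  tab <- read_tsv_strict(path, c(locus_name = "character",
                                 forward = "character",
                                 reverse = "character"))
  if (nrow(tab) == 0L) {
    msb_stop(sprintf("%s: no primer pairs", path), "msb_io_error")
  }
  pairs <- lapply(seq_len(nrow(tab)), function(i) {
    tryCatch(
      primer_pair(tab$locus_name[i], tab$forward[i], tab$reverse[i]),
      msb_error = function(e) {
        msb_stop(sprintf("%s row %d: %s", path, i, conditionMessage(e)),
                 "msb_io_error")
      })
  })
  stats::setNames(pairs, tab$locus_name)
}

#' Read / write a band table
#'
#' TSV with columns `strain`, `locus`, `size_bp`, `intensity`, `flags`
#' (empty or a semicolon-separated subset of `faint`, `smear`). Unknown
#' flags and duplicate strain-locus-size rows are errors.
#'
#' @param path TSV file.
#' @return A data.frame with those five columns.
#' @export
read_band_table <- function(path) {
  tab <- read_tsv_strict(path, c(strain = "character", locus = "character",
                                 size_bp = "integer", intensity = "numeric",
                                 flags = "character"))
  tab <- tab[, c("strain", "locus", "size_bp", "intensity", "flags")]
  tab$flags[is.na(tab$flags)] <- ""
  tab$strain <- as.character(tab$strain)
  tab$locus <- as.character(tab$locus)
  if (any(is.na(tab$size_bp)) || any(is.na(tab$intensity))) {
    msb_stop(sprintf("%s: non-numeric size_bp or intensity", path),
             "msb_io_error")
  }
  tab$size_bp <- as.integer(tab$size_bp)
  check_flags(tab$flags)
  if (anyDuplicated(tab[, c("strain", "locus", "size_bp")])) {
    msb_stop(sprintf("%s: duplicate strain x locus x size row", path),
             "msb_duplicate_error")
  }
  tab
}

#' @rdname read_band_table
#' @param band_table A band table data.frame.
#' @export
write_band_table <- function(band_table, path) {
  check_flags(band_table$flags)
  utils::write.table(band_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write repeat tracts to TSV
#'
#' @param tracts Output of [find_repeats()].
#' @param path Output file.
#' @export
write_tracts_tsv <- function(tracts, path) {
  utils::write.table(tracts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundle of the pipeline's tunable parameters, serialisable to YAML and
#' round-trippable. Defaults are the package-wide defaults.
#'
#' @param resolution_bp Gel resolution in bp (>= 1).
#' @param max_mismatches Primer mismatch tolerance (>= 0).
#' @param three_prime_exact_bases Exact 3' anchor length (>= 0).
#' @param max_product_bp Maximum PCR product length.
#' @param min_units Minimum repeat units for a tract.
#' @param max_interrupted_units Interruptions tolerated per tract.
#' @param min_intensity Band intensity filter threshold in [0, 1].
#' @param drop_flags Band flags filtered from patterns.
#' @param seed Integer RNG seed.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(resolution_bp = 2L, max_mismatches = 2L,
                       three_prime_exact_bases = 3L, max_product_bp = 2000L,
                       min_units = 5L, max_interrupted_units = 1L,
                       min_intensity = 0.25,
                       drop_flags = c("faint", "smear"), seed = 1L) {
  cfg <- list(resolution_bp = as.integer(resolution_bp),
              max_mismatches = as.integer(max_mismatches),
              three_prime_exact_bases = as.integer(three_prime_exact_bases),
              max_product_bp = as.integer(max_product_bp),
              min_units = as.integer(min_units),
              max_interrupted_units = as.integer(max_interrupted_units),
              min_intensity = as.numeric(min_intensity),
              drop_flags = as.character(drop_flags),
              seed = as.integer(seed))
  if (cfg$resolution_bp < 1L || cfg$max_mismatches < 0L ||
      cfg$three_prime_exact_bases < 0L || cfg$max_product_bp < 1L ||
      cfg$min_units < 2L || cfg$max_interrupted_units < 0L ||
      cfg$min_intensity < 0 || cfg$min_intensity > 1) {
    msb_stop("run_config parameter out of range", "msb_spec_error")
  }
  if (!all(cfg$drop_flags %in% BAND_FLAGS)) {
    msb_stop("unknown drop flag", "msb_spec_error")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
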