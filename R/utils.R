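# Internal helpers shared across modules: structured error conditions,
# DNA string utilities, and seeded-RNG scoping.

DNA_BASES <- c("A", "C", "G", "T")

# All package errors carry a condition subclass so callers (and the CLI) can
# distinguish input errors from bugs. Subclasses used:
#   msb_alphabet_error, msb_motif_error, msb_length_error, msb_locus_error,
#   msb_duplicate_error, msb_missing_data_error, msb_no_evidence_error,
#   msb_spec_error, msb_io_error
msb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "msb_error")))
}

#' @noRd
check_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !is.character(x)) {
    msb_stop(sprintf("%s must be a single character string", what),
             "msb_alphabet_error")
  }
  if (!grepl("^[ACGTacgt]+$", x)) {
    msb_stop(sprintf("%s contains characters outside {A,C,G,T}", what),
             "msb_alphabet_error")
  }
  toupper(x)
}

#' Reverse complement of a DNA string
#'
#' @param x A DNA string over `{A,C,G,T}` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  x <- check_dna(x, "sequence")
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Is a unit primitive, i.e. not a whole-number power of a shorter string?
is_primitive_unit <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), n / d)) {
      return(FALSE)
    }
  }
  TRUE
}

# Evaluate expr with a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed (< 2^31) derived from a base seed and a label,
# so each strain x locus simulation has its own reproducible stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100003L
  as.integer((as.numeric(seed) * 7919 + h * 271 + 12345) %% 2147483647)
}
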