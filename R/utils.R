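#' @keywords internal
"_PACKAGE"

# Canonical internal alphabet is RNA (A/C/G/U); genomes are handled as DNA
# and converted at the boundary.

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Upper-cases the input and maps T to U. Any character outside A/C/G/T/U
#' is a validation error; IUPAC ambiguity codes are deliberately not
#' supported. The operation is idempotent.
#'
#' @param x Character vector of sequences.
#' @return Character vector over \{A,C,G,U\}.
#' @export
#' @examples
#' normalize_rna("acgt")  # "ACGU"
normalize_rna <- function(x) {
  nm <- names(x)
  x <- toupper(as.character(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  names(x) <- nm
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("validation error: sequence contains characters outside ACGTU: ",
         substr(x[bad][1L], 1L, 40L), call. = FALSE)
  }
  if (any(!nzchar(x))) stop("validation error: empty sequence", call. = FALSE)
  x
}

rna_to_dna <- function(x) {
  out <- gsub("U", "T", toupper(x), fixed = TRUE)
  names(out) <- names(x)
  out
}

reverse_string <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Reverse complement in RNA space
#' @param x Character vector of RNA sequences.
#' @return Reverse-complemented RNA sequences.
#' @export
revcomp_rna <- function(x) reverse_string(chartr("ACGU", "UGCA", toupper(x)))

revcomp_dna <- function(x) reverse_string(chartr("ACGT", "TGCA", toupper(x)))

#' Round half-up to a fixed number of decimals
#'
#' Plain decimal rounding with ties going away from zero, as used for all
#' printed percentages (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector (non-negative in all pipeline uses).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a numerator over a denominator, half-up at 2 decimals
#'
#' @param num,den Numerator and denominator (den > 0).
#' @param digits Decimal places (default 2).
#' @return `100 * num / den`, rounded half-up.
#' @export
#' @examples
#' percent(61587749, 74678115)  # 82.47
percent <- function(num, den, digits = 2) {
  if (any(den <= 0)) stop("validation error: percentage denominator must be > 0",
                          call. = FALSE)
  round_half_up(100 * num / den, digits)
}

# Stage logging at INFO so the QC cascade is reconstructible from the log.
mf_log <- function(fmt, ...) {
  if (isTRUE(getOption("mirflow.verbose", TRUE))) {
    message("[INFO] ", sprintf(fmt, ...))
  }
}

# Count (possibly overlapping) occurrences of `pattern` in `subject`,
# both plain character scalars. Used for invariant checks on short strings.
count_occurrences <- function(pattern, subject) {
  n <- nchar(subject); k <- nchar(pattern)
  if (k == 0L || k > n) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (substr(subject, i, i + k - 1L) == pattern) hits <- hits + 1L
  }
  hits
}
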