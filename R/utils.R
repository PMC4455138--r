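# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up in absolute value, matching the
#' way percentages are printed in DGE library-statistics tables (30.575 ->
#' 30.58). Base R's `round()` rounds half to even and cannot reproduce
#' those printed values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @export
#' @examples
#' round_half_up(30.575, 2) # 30.58, where round() gives 30.57 or 30.58
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# percentage of numer/denom, rounded half-up; denom 0 is the caller's error
pct <- function(numer, denom, digits = 2L) {
  if (any(denom == 0)) stop("percentage undefined: zero denominator")
  round_half_up(100 * numer / denom, digits)
}

# stopifnot() with a formatted message
check <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

is_count1 <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

# Coerce a reference to a named character vector of upper-case sequences.
# Accepts a Biostrings::DNAStringSet or a named character vector.
ref_as_character <- function(transcriptome) {
  if (methods::is(transcriptome, "DNAStringSet")) {
    seqs <- as.character(transcriptome)
  } else if (is.character(transcriptome)) {
    seqs <- toupper(transcriptome)
  } else {
    stop("transcriptome must be a DNAStringSet or named character vector")
  }
  check(length(seqs) > 0L, "transcriptome is empty")
  check(!is.null(names(seqs)) && !anyNA(names(seqs)) &&
          !anyDuplicated(names(seqs)), "transcriptome needs unique names")
  seqs
}

REVCOMP_MAP <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement for plain character vectors (ACGT only)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
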