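#' @importFrom Biostrings DNAString DNAStringSet matchPattern
#'   reverseComplement writeXStringSet
#' @importFrom IRanges IRanges reduce
#' @importFrom stats rpois rbinom runif rmultinom median setNames binom.test
#'   chisq.test pbinom p.adjust
#' @importFrom utils write.table read.table head tail
#' @importFrom grDevices png dev.off hcl.colors
#' @importFrom graphics image
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES4 <- c("A", "C", "G", "T")

#' Random DNA string
#'
#' Uniform i.i.d. sequence over A/C/G/T. Consumes the current RNG stream.
#'
#' @param n length in bases
#' @return a single character string of length `n`
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

# Substitute a fraction of sites with a different base (uniform over the
# other three). Operates on a plain character string.
mutate_dna <- function(seq, divergence) {
  if (divergence <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    repl <- vapply(chars[hit], function(b) sample(setdiff(DNA_BASES4, b), 1L),
                   character(1), USE.NAMES = FALSE)
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

# Repeat-like filler: a short seeded monomer tiled to the requested length,
# mimicking tandem/TE-derived sequence rather than random DNA.
repeat_filler <- function(n, monomer_bp = 311L) {
  if (n <= 0) return("")
  monomer <- random_dna(min(monomer_bp, n))
  substr(strrep(monomer, ceiling(n / nchar(monomer))), 1L, n)
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, positive = TRUE) {
  if (length(x) < 1 || any(is.na(x)) || any(x != floor(x)))
    stop_field(field, "must be a whole number")
  if (positive && any(x <= 0)) stop_field(field, "must be positive")
  if (!positive && any(x < 0)) stop_field(field, "must be non-negative")
  invisible(as.integer(x))
}

check_fraction <- function(x, field) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a fraction in [0, 1]")
  invisible(as.numeric(x))
}

# Greatest common divisor (for reducing Mendelian ratios)
gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
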