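#' Fourfold-degenerate codon families
#'
#' Codons whose amino acid is unchanged by any substitution at the third
#' position, under the standard genetic code.
#'
#' @return character vector of fourfold-degenerate codons
#' @keywords internal
fourfold_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  is4 <- vapply(codons, function(cd) {
    variants <- paste0(substr(cd, 1, 2), DNA_BASES4)
    length(unique(gc[variants])) == 1
  }, logical(1))
  codons[is4]
}

#' Codon alignment of a gene pair
#'
#' Two gap-aligned coding sequences of equal length. Codon columns
#' containing a gap are excluded from analysis; after that exclusion the
#' remaining codons must contain no internal stop (standard code; a
#' terminal stop is allowed).
#'
#' @param seq1,seq2 aligned sequences (characters over A/C/G/T/-)
#' @param id gene-pair identifier
#' @return an object of class `codon_alignment`
#' @export
codon_alignment <- function(seq1, seq2, id = "pair") {
  seq1 <- toupper(as.character(seq1)); seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) != nchar(seq2))
    stop("aligned sequences must have equal length")
  if (nchar(seq1) %% 3 != 0)
    stop("alignment length must be a multiple of 3")
  if (grepl("[^ACGT-]", seq1) || grepl("[^ACGT-]", seq2))
    stop("alphabet must be A/C/G/T/-")
  n_codon <- nchar(seq1) %/% 3
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  c1 <- substring(seq1, starts, starts + 2L)
  c2 <- substring(seq2, starts, starts + 2L)
  gap_free <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  stops <- c("TAA", "TAG", "TGA")
  internal <- which(gap_free)
  internal <- internal[internal < n_codon]
  if (any(c1[internal] %in% stops) || any(c2[internal] %in% stops))
    stop("internal stop codon in alignment ", id)
  structure(list(id = id, codon1 = c1, codon2 = c2, gap_free = gap_free),
            class = "codon_alignment")
}

#' Fourfold-degenerate third-codon sites of an alignment
#'
#' A codon position qualifies when both codons are gap-free, agree at
#' positions 1 and 2, and belong to a fourfold-degenerate family (so every
#' third-base substitution is synonymous in both sequences). The
#' permissive mode only requires each codon to be fourfold-degenerate on
#' its own.
#'
#' @param aln a [codon_alignment()]
#' @param require_identical_12 if TRUE (default) the first two codon
#'   positions must be identical between the sequences
#' @return integer vector of qualifying codon indices
#' @export
fourfold_sites <- function(aln, require_identical_12 = TRUE) {
  stopifnot(inherits(aln, "codon_alignment"))
  ff <- fourfold_codons()
  ok <- aln$gap_free & aln$codon1 %in% ff & aln$codon2 %in% ff
  if (require_identical_12)
    ok <- ok & substr(aln$codon1, 1, 2) == substr(aln$codon2, 1, 2)
  which(ok)
}

is_purine <- function(b) b %in% c("A", "G")

#' Raw 4DTv of a codon-aligned gene pair
#'
#' The fraction of fourfold-degenerate third-codon sites at which the two
#' sequences differ by a transversion (purine vs pyrimidine); transitions
#' and identities are not counted. Also reports the purine and pyrimidine
#' frequencies over the fourfold third positions of both sequences, which
#' the HKY-style correction needs.
#'
#' @param aln a [codon_alignment()]
#' @param require_identical_12 passed to [fourfold_sites()]
#' @return an object of class `fourdtv_result` with fields `n_sites`,
#'   `transversions`, `raw`, `piR`, `piY`, `corrected` (NA until
#'   [hky_correct()] is applied), `saturated`
#' @export
raw_4dtv <- function(aln, require_identical_12 = TRUE) {
  sites <- fourfold_sites(aln, require_identical_12)
  if (length(sites) == 0)
    stop("no fourfold-degenerate sites in alignment ", aln$id)
  t1 <- substr(aln$codon1[sites], 3, 3)
  t2 <- substr(aln$codon2[sites], 3, 3)
  tv <- sum(is_purine(t1) != is_purine(t2))
  thirds <- c(t1, t2)
  piR <- mean(is_purine(thirds))
  structure(list(id = aln$id, n_sites = length(sites),
                 transversions = tv, raw = tv / length(sites),
                 piR = piR, piY = 1 - piR,
                 corrected = NA_real_, saturated = NA),
            class = "fourdtv_result")
}

#' HKY-style distance correction of a raw 4DTv
#'
#' Inverts the expected transversion fraction of HKY/TN93-class models,
#' `E[tv] = 2 piR piY (1 - exp(-d / (2 piR piY)))`, giving
#' `d = -2 piR piY log(1 - tv / (2 piR piY))`. When the observed fraction
#' reaches the saturation ceiling `2 piR piY` the distance is undefined
#' and the result is flagged saturated.
#'
#' @param result a `fourdtv_result` from [raw_4dtv()]
#' @return the result with `corrected` and `saturated` filled in
#' @export
hky_correct <- function(result) {
  stopifnot(inherits(result, "fourdtv_result"))
  ceiling2 <- 2 * result$piR * result$piY
  if (ceiling2 <= 0 || result$raw >= ceiling2) {
    result$saturated <- TRUE
    result$corrected <- NA_real_
  } else {
    result$saturated <- FALSE
    result$corrected <- -ceiling2 * log(1 - result$raw / ceiling2)
  }
  result
}

#' Raw and corrected 4DTv in one call
#'
#' @inheritParams raw_4dtv
#' @return a `fourdtv_result` with the correction applied
#' @export
fourdtv <- function(aln, require_identical_12 = TRUE) {
  hky_correct(raw_4dtv(aln, require_identical_12))
}

#' @export
print.fourdtv_result <- function(x, ...) {
  cat(sprintf("4DTv [%s]: %d sites, raw %.4f, corrected %s\n", x$id,
              x$n_sites, x$raw,
              if (isTRUE(x$saturated)) "saturated"
              else sprintf("%.4f", x$corrected)))
  invisible(x)
}

#' Histogram summary of 4DTv values across gene pairs
#'
#' @param results list of `fourdtv_result` objects (or a numeric vector of
#'   values)
#' @param bin_width histogram bin width (default 0.01)
#' @param use corrected (`"corrected"`, default) or `"raw"` values
#' @return a list with `histogram` (data.frame: bin_start, bin_end,
#'   count), `modal_bins` (data.frame rows of the maximal count),
#'   `n_defined`, `n_undefined`
#' @export
distribution_summary <- function(results, bin_width = 0.01,
                                 use = c("corrected", "raw")) {
  use <- match.arg(use)
  vals <- if (is.numeric(results)) results
  else vapply(results, function(r) r[[use]], numeric(1))
  n_undefined <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no defined 4DTv values to summarise")
  bins <- floor(vals / bin_width)
  tab <- table(bins)
  hist <- data.frame(bin_start = as.numeric(names(tab)) * bin_width,
                     count = as.integer(tab))
  hist$bin_end <- hist$bin_start + bin_width
  hist <- hist[order(hist$bin_start), c("bin_start", "bin_end", "count")]
  rownames(hist) <- NULL
  modal <- hist[hist$count == max(hist$count), ]
  list(histogram = hist, modal_bins = modal,
       n_defined = length(vals), n_undefined = n_undefined)
}

#' Simulate a codon-aligned pair at a known transversion distance
#'
#' Builds `n_sites` fourfold-degenerate codons (alanine family) and
#' substitutes third positions so the expected transversion fraction is
#' `2 piR piY (1 - exp(-d / (2 piR piY)))`; transitions are added
#' independently and do not affect the statistic. Useful for parameter
#' recovery checks of [hky_correct()].
#'
#' @param n_sites number of codons
#' @param d true transversion distance
#' @param piR purine frequency at third positions (default 0.5)
#' @param ts_prob independent transition probability per site (default 0.1)
#' @param seed optional seed
#' @return a [codon_alignment()]
#' @export
simulate_hky_pair <- function(n_sites, d, piR = 0.5, ts_prob = 0.1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  piY <- 1 - piR
  p_tv <- 2 * piR * piY * (1 - exp(-d / (2 * piR * piY)))
  third1 <- sample(DNA_BASES4, n_sites, replace = TRUE,
                   prob = c(piR / 2, piY / 2, piR / 2, piY / 2))
  third2 <- third1
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  do_ts <- runif(n_sites) < ts_prob
  third2[do_ts] <- ts_map[third2[do_ts]]
  do_tv <- runif(n_sites) < p_tv
  other_class <- function(b) if (is_purine(b))
    sample(c("C", "T"), 1) else sample(c("A", "G"), 1)
  third2[do_tv] <- vapply(third2[do_tv], other_class, character(1))
  codon_alignment(paste0("GC", third1, collapse = ""),
                  paste0("GC", third2, collapse = ""),
                  id = sprintf("sim_d%.3f", d))
}
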