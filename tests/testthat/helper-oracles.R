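# Independent brute-force oracles used to cross-check the implementation.
# Each is written as a direct, position-by-position computation with no
# shared code with the package internals.

# connected components of a per-base predicate, kept when length > min_run
oracle_runs <- function(pred, min_run) {
  out <- NULL
  i <- 1L
  n <- length(pred)
  while (i <= n) {
    if (pred[i]) {
      j <- i
      while (j < n && pred[j + 1L]) j <- j + 1L
      if (j - i + 1L > min_run)
        out <- rbind(out, c(start = i - 1L, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# exact two-sided binomial p by cumulative summation of point masses
oracle_binom_two_sided <- function(x, n, p) {
  masses <- dbinom(0:n, n, p)
  sum(masses[masses <= masses[x + 1L] * (1 + 1e-7)])
}

# all-positions in-silico PCR scan: forward primer on plus strand, reverse
# primer's reverse complement strictly downstream; then both primers
# swapped (minus-strand orientation). Exact matching only.
oracle_pcr <- function(template, fwd, rev, max_product) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  n <- nchar(template)
  hits <- NULL
  scan1 <- function(a, b, strand) {
    la <- nchar(a); lb <- nchar(b)
    brc <- rc(b)
    a_pos <- which(vapply(seq_len(max(0L, n - la + 1L)), function(i)
      substr(template, i, i + la - 1L) == a, logical(1)))
    b_pos <- which(vapply(seq_len(max(0L, n - lb + 1L)), function(j)
      substr(template, j, j + lb - 1L) == brc, logical(1)))
    for (i in a_pos) for (j in b_pos) {
      if (j < i + la) next
      if (j + lb - i > max_product) next
      hits <<- rbind(hits, data.frame(start = i - 1L, end = j + lb - 1L,
                                      length = j + lb - i,
                                      strand = strand))
    }
  }
  scan1(fwd, rev, "+")
  scan1(rev, fwd, "-")
  if (is.null(hits)) return(data.frame(start = integer(0), end = integer(0),
                                       length = integer(0),
                                       strand = character(0)))
  hits <- unique(hits)
  hits <- hits[order(hits$start, hits$end, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

# fourfold-degenerate site oracle: every third-base substitution of both
# codons must leave the amino acid unchanged, and the two codons must share
# their first two bases
oracle_fourfold_pair <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  all_syn <- function(cd) {
    aa <- gc[[cd]]
    variants <- paste0(substr(cd, 1, 2), c("A", "C", "G", "T"))
    all(vapply(variants, function(v) gc[[v]] == aa, logical(1)))
  }
  substr(c1, 1, 2) == substr(c2, 1, 2) && all_syn(c1) && all_syn(c2)
}

# orientation by explicit enumeration of ordered marker pairs
oracle_orient <- function(pos, cm) {
  n <- length(pos)
  if (n < 3) return("?")
  plus <- 0L; minus <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (cm[i] == cm[j] || pos[i] == pos[j]) next
    agree <- (pos[i] < pos[j]) == (cm[i] < cm[j])
    if (agree) plus <- plus + 1L else minus <- minus + 1L
  }
  if (plus > minus) "+" else if (minus > plus) "-" else "?"
}

# chimera oracle: TRUE iff the LG sequence along the scaffold contains two
# or more contiguous runs of length >= min_support on distinct LGs (after
# discarding under-supported runs)
oracle_chimeric <- function(lg_seq, min_support = 2) {
  runs <- rle(lg_seq)
  kept <- runs$values[runs$lengths >= min_support]
  kept <- rle(kept)$values        # collapse adjacent duplicates
  length(unique(kept)) >= 2
}

# reduce a two-class count ratio to lowest terms
oracle_ratio <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- max(1L, g(a, b))
  c(a %/% d, b %/% d)
}
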