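#' Flag double recombinants as missing
#'
#' A progeny whose genotype flips and flips back within `window_cm` along a
#' linkage group almost certainly carries a genotyping error rather than
#' two crossovers; the middle call is set to missing before aggregation
#' (the graphical-genotyping curation step).
#'
#' @param genotypes marker x progeny character matrix
#' @param seg_type per-marker segregation type (`lmxll`, `nnxnp`, `hkxhk`)
#' @param map data.frame with marker_id, lg, cM (rows matching `genotypes`)
#' @param window_cm flanking distance in cM (default 1)
#' @return the matrix with suspect calls set to NA
#' @export
flag_double_recombinants <- function(genotypes, seg_type, map,
                                     window_cm = 1) {
  for (st in c("lmxll", "nnxnp")) {
    for (lg in unique(map$lg)) {
      rows <- which(seg_type == st & map$lg == lg)
      if (length(rows) < 3) next
      rows <- rows[order(map$cM[rows])]
      cm <- map$cM[rows]
      g <- genotypes[rows, , drop = FALSE]
      for (k in 2:(length(rows) - 1L)) {
        if (cm[k + 1] - cm[k - 1] > window_cm) next
        mid <- g[k, ]; lo <- g[k - 1, ]; hi <- g[k + 1, ]
        bad <- !is.na(mid) & !is.na(lo) & !is.na(hi) &
          lo == hi & mid != lo
        genotypes[rows[k], bad] <- NA_character_
      }
    }
  }
  genotypes
}

#' Aggregate co-segregating markers into haploblocks
#'
#' Markers of the same segregation type (and linkage group and genetic bin,
#' when a map is supplied) whose observed vectors agree on all co-observed
#' progeny -- up to a tolerated conflict fraction -- are merged into one
#' highly informative haploblock. Agreement is assessed up to linkage
#' phase: a marker whose codes are the exact complement of the block
#' consensus (e.g. `lm` against `ll`, or `hh` against `kk`) co-segregates
#' with it and is flipped into the block's phase before joining. The
#' consensus genotype per progeny is the per-marker majority; unresolved
#' ties become missing.
#'
#' @param genotypes marker x progeny character matrix (NA = missing)
#' @param seg_type per-marker segregation type
#' @param map optional data.frame (marker_id, lg, cM) aligned with the
#'   matrix rows; when present, blocks never cross linkage groups or bins
#' @param max_conflict maximum fraction of co-observed progeny allowed to
#'   disagree (default 0: exact co-segregation)
#' @return a list of haploblocks, each with `id`, `members`, `consensus`
#'   (named character vector over progeny), `seg_type`, `lg`, `cM`
#' @export
aggregate_haploblocks <- function(genotypes, seg_type, map = NULL,
                                  max_conflict = 0) {
  m <- nrow(genotypes)
  stopifnot(length(seg_type) == m)
  key <- if (is.null(map)) seg_type
  else paste(seg_type, map$lg, map$cM, sep = "|")
  marker_names <- rownames(genotypes) %||% as.character(seq_len(m))
  majority <- function(votes) apply(votes, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) NA_character_
    else names(tab)[1]
  })
  flip_codes <- function(v, st) {
    swap <- switch(st, lmxll = c(lm = "ll", ll = "lm"),
                   nnxnp = c(nn = "np", np = "nn"),
                   hkxhk = c(hh = "kk", hk = "hk", kk = "hh"))
    out <- unname(swap[v])
    names(out) <- names(v)
    out
  }
  blocks <- list()
  for (k in seq_len(m)) {
    v <- genotypes[k, ]
    placed <- FALSE
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (b$key != key[k]) next
      both <- !is.na(v) & !is.na(b$consensus)
      conflicts <- sum(v[both] != b$consensus[both])
      vf <- flip_codes(v, seg_type[k])
      conflicts_f <- sum(vf[both] != b$consensus[both])
      if (conflicts_f < conflicts) {  # opposite linkage phase
        v_use <- vf; conflicts <- conflicts_f
      } else v_use <- v
      # vacuous agreement (no co-observed progeny) counts as compatible
      if (sum(both) == 0 || conflicts / sum(both) <= max_conflict) {
        b$members <- c(b$members, marker_names[k])
        b$votes <- rbind(b$votes, v_use)
        b$consensus <- majority(b$votes)
        blocks[[bi]] <- b
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      blocks[[length(blocks) + 1L]] <- list(
        key = key[k], members = marker_names[k],
        votes = matrix(v, nrow = 1,
                       dimnames = list(NULL, colnames(genotypes))),
        consensus = v, seg_type = seg_type[k],
        lg = if (is.null(map)) NA_integer_ else map$lg[k],
        cM = if (is.null(map)) NA_real_ else map$cM[k])
    }
  }
  for (bi in seq_along(blocks)) {
    blocks[[bi]]$id <- sprintf("HB%s-%d",
                               ifelse(is.na(blocks[[bi]]$lg), "0",
                                      blocks[[bi]]$lg), bi)
    blocks[[bi]]$key <- NULL
    blocks[[bi]]$votes <- NULL
  }
  blocks
}

#' Recombination fraction between two haploblocks
#'
#' Direct-count estimate over co-informative meioses. Two testcross blocks
#' informative for the same parent (both `lmxll` or both `nnxnp`) are
#' compared progeny by progeny; the phase minimising the recombinant count
#' is chosen, so the estimate is `min(r, 1 - r)` and never exceeds 0.5.
#' Pairs without a shared informative parent (any `hkxhk` involvement or a
#' maternal x paternal pair) have no direct-count estimate and return NA.
#'
#' @param a,b haploblocks from [aggregate_haploblocks()]
#' @param min_n minimum co-informative progeny (default 20); fewer gives NA
#' @return a list `(rf, n)` -- the estimate (NA when undefined) and the
#'   co-informative count
#' @export
pairwise_rf <- function(a, b, min_n = 20) {
  if (a$seg_type != b$seg_type || a$seg_type == "hkxhk")
    return(list(rf = NA_real_, n = 0L))
  va <- a$consensus; vb <- b$consensus
  both <- !is.na(va) & !is.na(vb)
  n <- sum(both)
  if (n < min_n) return(list(rf = NA_real_, n = n))
  mismatch <- sum(va[both] != vb[both])
  list(rf = min(mismatch, n - mismatch) / n, n = n)
}

#' Pairwise recombination-fraction matrix in map order
#'
#' Computes [pairwise_rf()] for every block pair, ordered by (linkage
#' group, cM), giving the symmetric matrix usually drawn as a genome-wide
#' recombination heatmap.
#'
#' @param blocks haploblocks from [aggregate_haploblocks()]
#' @param min_n minimum co-informative progeny per entry
#' @return a list with `rf` (symmetric matrix, zero diagonal, NA where
#'   undefined), `n` (co-informative counts) and `order` (block ids)
#' @export
rf_matrix <- function(blocks, min_n = 20) {
  o <- order(vapply(blocks, function(b) b$lg %||% NA_integer_, numeric(1)),
             vapply(blocks, function(b) b$cM %||% NA_real_, numeric(1)))
  blocks <- blocks[o]
  ids <- vapply(blocks, `[[`, character(1), "id")
  k <- length(blocks)
  rf <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  nn <- matrix(0L, k, k, dimnames = list(ids, ids))
  diag(rf) <- 0
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    est <- pairwise_rf(blocks[[i]], blocks[[j]], min_n)
    rf[i, j] <- rf[j, i] <- est$rf
    nn[i, j] <- nn[j, i] <- est$n
  }
  list(rf = rf, n = nn, order = ids)
}

#' Write an rf matrix as TSV and a heatmap image
#'
#' @param rfm result of [rf_matrix()]
#' @param tsv_path,png_path output paths (either may be NULL to skip)
#' @export
export_rf_matrix <- function(rfm, tsv_path = NULL, png_path = NULL) {
  if (!is.null(tsv_path))
    write.table(rfm$rf, tsv_path, sep = "\t", quote = FALSE,
                col.names = NA)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
    m <- rfm$rf[, rev(seq_len(ncol(rfm$rf))), drop = FALSE]
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "haploblock (map order)",
                    ylab = "haploblock (map order)",
                    main = "pairwise recombination frequency")
  }
  invisible(rfm)
}

#' Detect centromeres as recombination-suppressed regions
#'
#' For each chromosome, consecutive block pairs (in cM order) are scored by
#' physical span over genetic span -- the genetic span floored at
#' `floor_cm` to avoid division blowup -- and the peak pair is extended in
#' both directions while the pair score stays above half the peak. The
#' reported window is the centromere call; a peak below twice the
#' chromosome-average Mb/cM is flagged low-confidence.
#'
#' @param blocks data.frame with columns block_id, chromosome, cM, pos_bp
#'   (physical anchor of each block)
#' @param min_blocks minimum anchored blocks per chromosome (default 4)
#' @param floor_cm genetic-span floor in cM (default 0.5)
#' @return data.frame with one row per callable chromosome: chromosome,
#'   cM_start, cM_end, pos_start, pos_end, n_blocks, suppression_score
#'   (Mb per cM), low_confidence
#' @export
detect_centromere <- function(blocks, min_blocks = 4, floor_cm = 0.5) {
  out <- NULL
  for (ch in sort(unique(blocks$chromosome))) {
    bl <- blocks[blocks$chromosome == ch, ]
    bl <- bl[order(bl$cM, bl$pos_bp), ]
    if (nrow(bl) < min_blocks) {
      warning("chromosome ", ch, ": fewer than ", min_blocks,
              " anchored blocks, no centromere call")
      next
    }
    k <- nrow(bl) - 1L
    score <- numeric(k)
    for (i in seq_len(k)) {
      phys <- abs(bl$pos_bp[i + 1] - bl$pos_bp[i]) / 1e6
      gen <- max(bl$cM[i + 1] - bl$cM[i], floor_cm)
      score[i] <- phys / gen
    }
    peak <- which.max(score)
    lo <- peak; hi <- peak
    while (lo > 1 && score[lo - 1] >= score[peak] / 2) lo <- lo - 1
    while (hi < k && score[hi + 1] >= score[peak] / 2) hi <- hi + 1
    chrom_avg <- (abs(bl$pos_bp[nrow(bl)] - bl$pos_bp[1]) / 1e6) /
      max(bl$cM[nrow(bl)] - bl$cM[1], floor_cm)
    out <- rbind(out, data.frame(
      chromosome = ch, cM_start = bl$cM[lo], cM_end = bl$cM[hi + 1],
      pos_start = min(bl$pos_bp[lo:(hi + 1)]),
      pos_end = max(bl$pos_bp[lo:(hi + 1)]),
      n_blocks = hi - lo + 2L,
      suppression_score = score[peak],
      low_confidence = score[peak] < 2 * chrom_avg))
  }
  out
}
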