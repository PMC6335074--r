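#' Haldane map function
#'
#' Converts a genetic distance in centimorgan to a recombination fraction
#' (`haldane_r`) or back (`haldane_d`), assuming crossovers arrive as a
#' Poisson process without interference.
#'
#' @param d_cM genetic distance in cM
#' @return recombination fraction in [0, 0.5)
#' @export
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' @rdname haldane_r
#' @param r recombination fraction
#' @export
haldane_d <- function(r) -50 * log(1 - 2 * r)

#' Build the true genetic map of a simulated genome
#'
#' Places markers every `marker_spacing_bp` along each chromosome and
#' assigns cM positions by integrating a local recombination rate that is
#' suppressed tenfold over the central fifth of every chromosome (the
#' planted centromere). Each chromosome's genetic length is normalised to
#' `cM_per_chromosome`. A sex-locus marker is appended at the FSR insertion
#' point of the FSR chromosome.
#'
#' @param truth truth list from [simulate_zw_genome()]
#' @param config a [sim_config()]
#' @param cM_per_chromosome genetic length of each chromosome (default
#'   66.4 cM, i.e. a 531-cM genome over eight linkage groups)
#' @return a list with `markers` (data.frame: marker_id, lg, cM, chromosome,
#'   pos_bp on the Z haplotype, pos_w_bp on the W haplotype),
#'   `centromeres` (per-chromosome suppressed interval, bp and cM), and
#'   `sex_locus` (lg, cM, pos_bp)
#' @export
build_genetic_map_truth <- function(truth, config, cM_per_chromosome = 66.4) {
  stopifnot(inherits(config, "sim_config"))
  fc <- config$fsr_chromosome
  ins <- truth$insertion_point
  fsr_len <- truth$fsr_interval$end - truth$fsr_interval$start
  markers <- NULL
  centromeres <- NULL
  for (ci in seq_len(config$n_chromosomes)) {
    L <- config$chromosome_length_bp[ci]
    cen <- c(0.4 * L, 0.6 * L)
    # weight integral: rate 1 outside the centromere, 0.1 inside
    wt_of <- function(pos) {
      pos <- pmin(pmax(pos, 0), L)
      pmin(pos, cen[1]) + 0.1 * pmin(pmax(pos - cen[1], 0), cen[2] - cen[1]) +
        pmax(pos - cen[2], 0)
    }
    total_wt <- wt_of(L)
    cm_of <- function(pos) cM_per_chromosome * wt_of(pos) / total_wt
    pos <- seq(config$marker_spacing_bp, L - 1L,
               by = config$marker_spacing_bp)
    mk <- data.frame(
      marker_id = sprintf("m%d_%03d", ci, seq_along(pos)),
      lg = ci, cM = round(cm_of(pos), 4), chromosome = ci, pos_bp = pos)
    if (ci == fc && fsr_len > 0) {
      mk <- rbind(mk, data.frame(
        marker_id = "sexW", lg = ci, cM = round(cm_of(ins), 4),
        chromosome = ci, pos_bp = ins))
      mk <- mk[order(mk$cM, mk$pos_bp), ]
    }
    mk$pos_w_bp <- mk$pos_bp +
      ifelse(ci == fc & mk$pos_bp >= ins, fsr_len, 0L)
    markers <- rbind(markers, mk)
    centromeres <- rbind(centromeres, data.frame(
      chromosome = ci, start_bp = cen[1], end_bp = cen[2],
      cM_start = round(cm_of(cen[1]), 4), cM_end = round(cm_of(cen[2]), 4)))
  }
  rownames(markers) <- NULL
  sex_row <- markers[markers$marker_id == "sexW", ]
  list(markers = markers, centromeres = centromeres,
       sex_locus = if (nrow(sex_row))
         list(lg = sex_row$lg, cM = sex_row$cM, pos_bp = sex_row$pos_bp)
       else NULL)
}

# Simulate one gamete per progeny for one parent along one linkage group.
# Returns an n_markers x n_progeny matrix of haplotype labels (1 or 2).
simulate_gametes_lg <- function(cM, n) {
  m <- length(cM)
  H <- matrix(0L, m, n)
  H[1, ] <- sample(1:2, n, replace = TRUE)
  if (m > 1) for (k in 2:m) {
    r <- haldane_r(cM[k] - cM[k - 1])
    flip <- rbinom(n, 1L, r) == 1L
    H[k, ] <- ifelse(flip, 3L - H[k - 1, ], H[k - 1, ])
  }
  H
}

#' Simulate a WZ x WZ F1 mapping population
#'
#' Generates one recombinant gamete per parent and progeny along every
#' linkage group, with crossovers placed by the Haldane (no-interference)
#' model on the true cM positions. Both parents are WZ at the sex locus, so
#' progeny sex genotypes segregate 1 WW : 2 WZ : 1 ZZ and a dominant
#' W-linked marker segregates 3:1 present:absent. Markers are coded in
#' outbred-F1 (double pseudo-testcross) classes: `lmxll` (maternal
#' testcross), `nnxnp` (paternal testcross) and `hkxhk` (both parents
#' heterozygous). Missing data and genotyping errors are injected at the
#' configured rates after the error-free matrix is built.
#'
#' Because the FSR has zero genetic width (it is a point insertion on the
#' map), no simulated crossover can fall inside it: loci at the same cM
#' position always co-segregate.
#'
#' @param truth truth list from [simulate_zw_genome()]
#' @param config a [sim_config()]
#' @param map optional map from [build_genetic_map_truth()]; built if NULL
#' @param n number of progeny (default `config$f1_size`)
#' @param seed integer; defaults to `config$rng_seed + 31`
#' @return a list with `genotypes` (marker x progeny character matrix, NA
#'   for missing), `seg_type` (per marker), `sex_genotype` (per progeny:
#'   WW/WZ/ZZ), `maternal_gam`/`paternal_gam` (haplotype-label matrices
#'   before error injection), `map`, and `genotypes_clean` (the error-free
#'   matrix)
#' @export
simulate_f1_population <- function(truth, config, map = NULL,
                                   n = config$f1_size, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% (config$rng_seed + 31L))
  map <- map %||% build_genetic_map_truth(truth, config)
  mk <- map$markers
  m <- nrow(mk)
  seg_type <- sample(c("lmxll", "nnxnp", "hkxhk"), m, replace = TRUE)
  seg_type[mk$marker_id == "sexW"] <- "hkxhk"  # both parents WZ
  # phase: which parental haplotype (1/2) carries the variant allele.
  # Drawn once per genetic bin -- co-located markers sit on the same
  # parental haplotype arrangement -- so a bin's markers co-segregate
  # exactly (up to the whole-bin phase, which aggregation normalises).
  bin <- paste(mk$lg, mk$cM)
  bin_phase_m <- setNames(sample(1:2, length(unique(bin)), replace = TRUE),
                          unique(bin))
  bin_phase_p <- setNames(sample(1:2, length(unique(bin)), replace = TRUE),
                          unique(bin))
  phase_m <- unname(bin_phase_m[bin])
  phase_p <- unname(bin_phase_p[bin])
  sex_idx <- which(mk$marker_id == "sexW")
  if (length(sex_idx)) { phase_m[sex_idx] <- 1L; phase_p[sex_idx] <- 1L }

  mat_gam <- matrix(0L, m, n)
  pat_gam <- matrix(0L, m, n)
  for (ci in unique(mk$lg)) {
    rows <- which(mk$lg == ci)
    mat_gam[rows, ] <- simulate_gametes_lg(mk$cM[rows], n)
    pat_gam[rows, ] <- simulate_gametes_lg(mk$cM[rows], n)
  }

  geno <- matrix(NA_character_, m, n,
                 dimnames = list(mk$marker_id, sprintf("P%04d", seq_len(n))))
  for (k in seq_len(m)) {
    mat_var <- mat_gam[k, ] == phase_m[k]   # maternal gamete carries variant
    pat_var <- pat_gam[k, ] == phase_p[k]
    geno[k, ] <- switch(seg_type[k],
      lmxll = ifelse(mat_var, "lm", "ll"),
      nnxnp = ifelse(pat_var, "np", "nn"),
      hkxhk = c("hh", "hk", "hk", "kk")[1L + mat_var + 2L * pat_var])
  }
  # sexW is hkxhk with h = W: hh=WW, hk=WZ, kk=ZZ
  sex_genotype <- if (length(sex_idx)) {
    c(hh = "WW", hk = "WZ", kk = "ZZ")[geno[sex_idx, ]]
  } else rep(NA_character_, n)
  names(sex_genotype) <- colnames(geno)

  geno_clean <- geno
  if (config$genotyping_error_rate > 0) {
    legal <- list(lmxll = c("lm", "ll"), nnxnp = c("nn", "np"),
                  hkxhk = c("hh", "hk", "kk"))
    err <- which(matrix(runif(m * n) < config$genotyping_error_rate, m, n),
                 arr.ind = TRUE)
    for (j in seq_len(nrow(err))) {
      k <- err[j, 1]
      alt <- setdiff(legal[[seg_type[k]]], geno[k, err[j, 2]])
      geno[k, err[j, 2]] <- sample(alt, 1L)
    }
  }
  if (config$missing_rate > 0)
    geno[matrix(runif(m * n) < config$missing_rate, m, n)] <- NA_character_

  list(genotypes = geno, genotypes_clean = geno_clean, seg_type = seg_type,
       sex_genotype = sex_genotype, maternal_gam = mat_gam,
       paternal_gam = pat_gam, map = map)
}
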