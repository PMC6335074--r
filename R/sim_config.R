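#' Simulation configuration for a synthetic ZW genome
#'
#' Bundles every parameter of the synthetic data generator: a female
#' (W-carrying) and male (Z-only) haplotype pair in which the W differs from
#' the Z by a single inserted female-specific region (FSR) assembled from
#' diverged paralogous gene copies and repeat-like filler; pooled sequencing
#' depths for a female and a male bulk; an outbred WZ x WZ F1 mapping
#' population; a sexed germplasm panel; and a scaffolded fragmentation of the
#' assembly (optionally containing one deliberate chimera).
#'
#' Defaults describe the study conditions the package is calibrated to:
#' eight chromosomes, a 59-kb FSR near the distal end of chromosome 8
#' containing seven genes copied (at 10% divergence) from paralogous donor
#' loci on the same chromosome, female and male pools at 106x and 127x, an
#' F1 of 95 progeny, and a validation panel of 133 females and 128 males.
#' Chromosomes are shrunk to desk scale (200 kb) while the FSR keeps its
#' full 59-kb size so the detection geometry is preserved.
#'
#' @param n_chromosomes number of chromosomes
#' @param chromosome_length_bp chromosome length in bp (scalar, recycled, or
#'   one value per chromosome)
#' @param fsr_length_bp length of the inserted female-specific region (bp);
#'   0 gives a degenerate simulation in which W and Z are identical
#' @param fsr_chromosome index of the chromosome carrying the insertion
#' @param fsr_position insertion point as a fraction of chromosome length
#' @param n_fsr_genes number of gene segments inside the FSR
#' @param paralog_divergence per-site substitution fraction between each FSR
#'   gene and its donor paralog
#' @param repeat_fraction_fsr fraction of the FSR made of repeat-like filler
#' @param pool_depth_f,pool_depth_m fold coverage of the female/male pools
#' @param base_error_rate per-read substitution error rate used by the
#'   pileup simulator
#' @param f1_size number of F1 progeny
#' @param marker_spacing_bp physical spacing of genetic-map markers
#' @param missing_rate per-genotype missing-data rate in the F1 matrix
#' @param genotyping_error_rate per-genotype miscall rate in the F1 matrix
#' @param panel_n_female,panel_n_male sexed germplasm panel composition
#' @param scaffold_n50_target_bp target scaffold size for the fragmenter
#' @param chimera if TRUE the fragmenter emits one chimeric scaffold joining
#'   a piece of the FSR chromosome to a piece of another chromosome
#' @param cross_mapping if TRUE, reads from paralogous copies co-map onto
#'   each other whenever `paralog_divergence < mapping_divergence_cutoff`,
#'   producing ghost signal (inflated depth, apparent variants)
#' @param mapping_divergence_cutoff divergence below which co-mapping occurs
#' @param rng_seed integer seed; identical config + seed gives byte-identical
#'   outputs
#' @return an object of class `sim_config` (a validated named list)
#' @export
sim_config <- function(n_chromosomes = 8,
                       chromosome_length_bp = 200000,
                       fsr_length_bp = 59000,
                       fsr_chromosome = 8,
                       fsr_position = 0.95,
                       n_fsr_genes = 7,
                       paralog_divergence = 0.10,
                       repeat_fraction_fsr = 0.4,
                       pool_depth_f = 106,
                       pool_depth_m = 127,
                       base_error_rate = 0.01,
                       f1_size = 95,
                       marker_spacing_bp = 20000,
                       missing_rate = 0.02,
                       genotyping_error_rate = 0.005,
                       panel_n_female = 133,
                       panel_n_male = 128,
                       scaffold_n50_target_bp = 50000,
                       chimera = TRUE,
                       cross_mapping = FALSE,
                       mapping_divergence_cutoff = 0.05,
                       rng_seed = 1) {
  check_count(n_chromosomes, "n_chromosomes")
  chromosome_length_bp <- rep_len(as.numeric(chromosome_length_bp),
                                  n_chromosomes)
  check_count(chromosome_length_bp, "chromosome_length_bp")
  check_count(fsr_length_bp, "fsr_length_bp", positive = FALSE)
  check_count(fsr_chromosome, "fsr_chromosome")
  if (fsr_chromosome > n_chromosomes)
    stop_field("fsr_chromosome", "exceeds n_chromosomes")
  check_fraction(fsr_position, "fsr_position")
  check_count(n_fsr_genes, "n_fsr_genes")
  check_fraction(paralog_divergence, "paralog_divergence")
  check_fraction(repeat_fraction_fsr, "repeat_fraction_fsr")
  if (pool_depth_f < 0) stop_field("pool_depth_f", "must be non-negative")
  if (pool_depth_m < 0) stop_field("pool_depth_m", "must be non-negative")
  check_fraction(base_error_rate, "base_error_rate")
  check_count(f1_size, "f1_size")
  check_count(marker_spacing_bp, "marker_spacing_bp")
  check_fraction(missing_rate, "missing_rate")
  check_fraction(genotyping_error_rate, "genotyping_error_rate")
  check_count(panel_n_female, "panel_n_female", positive = FALSE)
  check_count(panel_n_male, "panel_n_male", positive = FALSE)
  check_count(scaffold_n50_target_bp, "scaffold_n50_target_bp")
  check_fraction(mapping_divergence_cutoff, "mapping_divergence_cutoff")
  check_count(rng_seed, "rng_seed", positive = FALSE)
  if (fsr_length_bp >= chromosome_length_bp[fsr_chromosome])
    stop_field("fsr_length_bp",
               "must be smaller than the FSR chromosome length")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.integer(chromosome_length_bp),
    fsr_length_bp = as.integer(fsr_length_bp),
    fsr_chromosome = as.integer(fsr_chromosome),
    fsr_position = fsr_position,
    n_fsr_genes = as.integer(n_fsr_genes),
    paralog_divergence = paralog_divergence,
    repeat_fraction_fsr = repeat_fraction_fsr,
    pool_depth_f = pool_depth_f,
    pool_depth_m = pool_depth_m,
    base_error_rate = base_error_rate,
    f1_size = as.integer(f1_size),
    marker_spacing_bp = as.integer(marker_spacing_bp),
    missing_rate = missing_rate,
    genotyping_error_rate = genotyping_error_rate,
    panel_n_female = as.integer(panel_n_female),
    panel_n_male = as.integer(panel_n_male),
    scaffold_n50_target_bp = as.integer(scaffold_n50_target_bp),
    chimera = isTRUE(chimera),
    cross_mapping = isTRUE(cross_mapping),
    mapping_divergence_cutoff = mapping_divergence_cutoff,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ZW simulation config:", x$n_chromosomes, "chromosomes,",
      format(sum(x$chromosome_length_bp), big.mark = ","), "bp genome;",
      "FSR", format(x$fsr_length_bp, big.mark = ","), "bp on chr",
      x$fsr_chromosome, "\n")
  invisible(x)
}
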