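#' Simulate pooled-sequencing depth over a reference
#'
#' Draws per-base Poisson depth for a female (WZ) or male (ZZ) bulk mapped
#' to either the female (W-containing) or male assembly. The rate at each
#' base is `pool_depth * copies / 2`, where `copies` counts how many copies
#' of that base a diploid of the pool's sex carries: inside the planted FSR
#' the female pool runs at half depth (one W per diploid) and the male pool
#' at zero, which is the presence/absence signal the depth scanner exploits.
#' When `config$cross_mapping` is on and `paralog_divergence` is below
#' `mapping_divergence_cutoff`, reads from FSR genes and their donor
#' paralogs co-map, inflating depth at both loci (ghost signal).
#'
#' Which assembly was supplied is inferred from the length of the FSR
#' chromosome (the female assembly carries the insertion).
#'
#' @param reference female or male assembly as a [Biostrings::DNAStringSet]
#' @param truth truth list from [simulate_zw_genome()]
#' @param config a [sim_config()]
#' @param pool_sex `"female"` or `"male"`
#' @param seed integer; defaults to `config$rng_seed` + a pool-specific offset
#' @return a [depth_track()] object
#' @export
simulate_pool_depth <- function(reference, truth, config, pool_sex,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pool_sex <- match.arg(pool_sex, c("female", "male"))
  set.seed(seed %||% (config$rng_seed +
                        if (pool_sex == "female") 11L else 12L))
  d <- if (pool_sex == "female") config$pool_depth_f else config$pool_depth_m
  fc <- config$fsr_chromosome
  fsr <- truth$fsr_interval
  fsr_len <- fsr$end - fsr$start
  widths <- Biostrings::width(reference)
  ref_has_fsr <- fsr_len > 0 &&
    widths[fc] == config$chromosome_length_bp[fc] + fsr_len

  cross <- config$cross_mapping &&
    config$paralog_divergence < config$mapping_divergence_cutoff

  depths <- vector("list", length(reference))
  names(depths) <- names(reference)
  for (ci in seq_along(reference)) {
    lam <- rep(d, widths[ci])
    if (ci == fc && fsr_len > 0) {
      if (ref_has_fsr) {
        idx_fsr <- (fsr$start + 1L):fsr$end
        lam[idx_fsr] <- if (pool_sex == "female") d / 2 else 0
        if (cross) {
          for (g in seq_len(nrow(truth$paralog_map))) {
            pm <- truth$paralog_map[g, ]
            gi <- (pm$w_start + 1L):pm$w_end       # FSR copy (W coords)
            di <- (pm$donor_start + 1L):pm$donor_end  # donor (< insertion pt)
            if (pool_sex == "female") {
              lam[gi] <- 1.5 * d   # 1 W copy + 2 co-mapping donor copies
              lam[di] <- 1.5 * d   # 2 donor copies + 1 co-mapping W copy
            } else {
              lam[gi] <- d         # 2 donor copies co-map; no W
            }
          }
        }
      } else if (cross && pool_sex == "female") {
        # male assembly: the W-specific copies co-map onto the donor loci
        for (g in seq_len(nrow(truth$paralog_map))) {
          pm <- truth$paralog_map[g, ]
          lam[(pm$donor_start + 1L):pm$donor_end] <- 1.5 * d
        }
      }
    }
    depths[[ci]] <- rpois(widths[ci], lam)
  }
  depth_track(depths)
}

#' Simulate allele counts at one pooled site under a copy model
#'
#' Draws a site depth from Poisson(`pool_depth * total_copies / 2`) and
#' allele counts from a multinomial with probabilities proportional to the
#' per-allele copy counts, perturbed by a uniform substitution error: each
#' read is miscalled with probability `error_rate` to one of the other three
#' bases. A site carrying one W-linked allele plus two co-mapping paralog
#' copies therefore converges to the 1:2 allele ratio diagnostic of
#' W-plus-duplicated-paralog sites in a female pool.
#'
#' @param copy_model named non-negative numeric vector of per-allele copy
#'   counts in one diploid (plus any co-mapping copies), e.g. `c(A = 1, G = 2)`
#' @param pool_depth fold coverage of the pool
#' @param error_rate per-read substitution error
#' @param seed optional integer seed
#' @return named integer vector of counts over A, C, G, T
#' @export
simulate_site_pileup <- function(copy_model, pool_depth, error_rate = 0,
                                 seed = NULL) {
  if (!length(copy_model) || any(copy_model < 0) || sum(copy_model) == 0)
    stop("copy_model must have non-negative counts, not all zero")
  if (is.null(names(copy_model)) || !all(names(copy_model) %in% DNA_BASES4))
    stop("copy_model must be named with bases A/C/G/T")
  if (!is.null(seed)) set.seed(seed)
  p <- setNames(numeric(4), DNA_BASES4)
  p[names(copy_model)] <- copy_model / sum(copy_model)
  p_err <- (1 - error_rate) * p + error_rate * (1 - p) / 3
  n <- rpois(1L, pool_depth * sum(copy_model) / 2)
  if (n == 0) return(setNames(integer(4), DNA_BASES4))
  setNames(as.integer(rmultinom(1L, n, p_err)[, 1]), DNA_BASES4)
}

#' Simulate a sexed germplasm panel
#'
#' Assigns sex genotypes to a validation panel: males are ZZ; females are WZ
#' except for a small configurable fraction of viable WW homozygotes.
#'
#' @param config a [sim_config()]
#' @param ww_fraction fraction of females that are WW (default 0.05)
#' @param seed integer; defaults to `config$rng_seed + 23`
#' @return data.frame with columns id, sex, genotype
#' @export
simulate_germplasm_panel <- function(config, ww_fraction = 0.05, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% (config$rng_seed + 23L))
  nf <- config$panel_n_female; nm <- config$panel_n_male
  female_gt <- ifelse(runif(nf) < ww_fraction, "WW", "WZ")
  data.frame(
    id = c(sprintf("F%03d", seq_len(nf)), sprintf("M%03d", seq_len(nm))),
    sex = c(rep("female", nf), rep("male", nm)),
    genotype = c(female_gt, rep("ZZ", nm)))
}
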