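#' Copy model for a candidate sex-linked site
#'
#' Describes how many copies of each allele a diploid of each sex carries at
#' a site, including co-mapping paralog copies. The two stock models cover
#' the patterns seen at W-linked SNPs: `simple_WZ` -- the W allele against
#' one Z-derived copy (expected female fraction 1/2, male 0) -- and
#' `W_plus_duplicated_paralog` -- one W copy co-mapping with a duplicated
#' paralog contributing two copies of the other allele, giving the
#' characteristic 1:2 female allele ratio (expected W fraction 1/3).
#'
#' @param label `"simple_WZ"`, `"W_plus_duplicated_paralog"` or `"custom"`
#' @param female,male named non-negative integer vectors of per-allele copy
#'   counts (required for `"custom"`)
#' @param w_allele,other_allele allele letters used by the stock models
#' @return an object of class `copy_model`
#' @export
copy_model <- function(label = c("simple_WZ", "W_plus_duplicated_paralog",
                                 "custom"),
                       female = NULL, male = NULL,
                       w_allele = "A", other_allele = "G") {
  label <- match.arg(label)
  if (label == "simple_WZ") {
    female <- setNames(c(1, 1), c(w_allele, other_allele))
    male <- setNames(2, other_allele)
  } else if (label == "W_plus_duplicated_paralog") {
    female <- setNames(c(1, 2), c(w_allele, other_allele))
    male <- setNames(2, other_allele)
  } else {
    if (is.null(female) || is.null(male))
      stop("custom copy_model needs `female` and `male` copy counts")
  }
  for (side in list(female, male)) {
    if (any(side < 0) || any(side != floor(side)))
      stop("copy counts must be non-negative integers")
    if (sum(side) == 0) stop("each sex needs at least one positive copy")
  }
  structure(list(label = label, female = female, male = male,
                 w_allele = w_allele),
            class = "copy_model")
}

#' Expected pool allele fraction under a copy model
#'
#' The asymptotic fraction of reads carrying `allele` in a pool of the given
#' sex: copies of the allele over total copies (alleles absent from the
#' model have zero copies).
#'
#' @param model a [copy_model()]
#' @param sex `"female"` or `"male"`
#' @param allele allele letter
#' @return a fraction in [0, 1]
#' @export
expected_allele_fraction <- function(model, sex = c("female", "male"),
                                     allele = model$w_allele) {
  sex <- match.arg(sex)
  copies <- model[[sex]]
  total <- sum(copies)
  if (total == 0) stop("zero total copies for ", sex)
  x <- unname(copies[allele])
  if (length(x) == 0 || is.na(x)) x <- 0
  x / total
}

#' A pooled/individual pileup site
#'
#' @param reference_id,position site location (1-based position)
#' @param ref_allele reference base
#' @param pool_counts list with named count vectors `female` and `male`
#' @param individual_counts optional named list of per-individual count
#'   vectors
#' @param individual_sex optional named character vector of sex labels for
#'   the individuals
#' @param depth_ratio site depth over the genome-wide single-locus
#'   expectation (pool depth); values well above 1 indicate co-mapping
#'   paralogs
#' @return an object of class `pileup_site`
#' @export
pileup_site <- function(reference_id, position, ref_allele,
                        pool_counts, individual_counts = list(),
                        individual_sex = character(0),
                        depth_ratio = NA_real_) {
  stopifnot(all(c("female", "male") %in% names(pool_counts)))
  for (p in pool_counts) if (any(p < 0)) stop("negative allele count")
  structure(list(reference_id = reference_id, position = position,
                 ref_allele = ref_allele, pool_counts = pool_counts,
                 individual_counts = individual_counts,
                 individual_sex = individual_sex,
                 depth_ratio = depth_ratio),
            class = "pileup_site")
}

w_fraction <- function(counts, w_allele) {
  n <- sum(counts)
  x <- unname(counts[w_allele] %||% 0)
  if (is.na(x)) x <- 0
  list(x = x, n = n, frac = if (n > 0) x / n else NA_real_)
}

#' Flag a site as a multi-copy (ghost) locus
#'
#' Paralogous regions with small divergence to the reference attract
#' co-mapping reads, inflating site depth above the single-locus
#' expectation; such sites produce ghost variants rather than true allelic
#' differences.
#'
#' @param site a [pileup_site()] with `depth_ratio` set
#' @param multi_copy_depth_ratio flag threshold (default 1.5, strict `>`)
#' @return logical
#' @export
flag_ghost <- function(site, multi_copy_depth_ratio = 1.5) {
  isTRUE(site$depth_ratio > multi_copy_depth_ratio)
}

#' Test one site for sex linkage under a copy model
#'
#' The female pool's W-allele count is tested against the model's expected
#' fraction with a two-sided exact binomial test (consistency means p >
#' alpha); the male pool must carry the W allele at no more than
#' `max_male_error` (a tolerance covering sequencing error, pool
#' contamination and residual cross-mapping -- male pools in practice are
#' only ~97% homogeneous). Sites failing the pool tests are `unassociated`,
#' or `ghost_multi_copy` when their depth ratio betrays a co-mapping
#' paralog; a zero-depth pool yields `unassociated` with a diagnostic flag.
#'
#' @param site a [pileup_site()]
#' @param model a [copy_model()]
#' @param alpha significance level of the female-pool test (default 0.05)
#' @param max_male_error maximum tolerated male W-allele fraction
#'   (default 0.05)
#' @param ghost_threshold depth-ratio threshold passed to [flag_ghost()]
#' @return an object of class `sex_snp_call`: site coordinates, model
#'   label, expected/observed fractions, `p_female` (two-sided binomial),
#'   `p_male_contamination` (upper tail at `max_male_error`), `class`, and
#'   `diagnostic`
#' @export
test_site <- function(site, model, alpha = 0.05, max_male_error = 0.05,
                      ghost_threshold = 1.5) {
  fem <- w_fraction(site$pool_counts$female, model$w_allele)
  mal <- w_fraction(site$pool_counts$male, model$w_allele)
  exp_f <- expected_allele_fraction(model, "female")
  diagnostic <- NA_character_
  p_female <- NA_real_; p_male <- NA_real_
  if (fem$n == 0 || mal$n == 0) {
    cls <- "unassociated"
    diagnostic <- "zero-depth pool"
  } else {
    p_female <- stats::binom.test(fem$x, fem$n, p = exp_f)$p.value
    p_male <- stats::pbinom(mal$x - 1L, mal$n, max_male_error,
                            lower.tail = FALSE)
    pool_ok <- p_female > alpha && mal$frac <= max_male_error &&
      fem$frac > 0
    cls <- if (pool_ok) "sex_linked"
    else if (flag_ghost(site, ghost_threshold)) "ghost_multi_copy"
    else "unassociated"
  }
  structure(list(
    reference_id = site$reference_id, position = site$position,
    model = model$label, expected_female_fraction = exp_f,
    observed_female_fraction = fem$frac,
    observed_male_fraction = mal$frac,
    p_female = p_female, p_male_contamination = p_male,
    class = cls, ghost = flag_ghost(site, ghost_threshold),
    diagnostic = diagnostic, individual_concordant = NA),
    class = "sex_snp_call")
}

#' Confirm a candidate site in sexed individuals
#'
#' Every female individual must carry the W allele at a fraction consistent
#' with the copy model (two-sided binomial test at `alpha`), and every male
#' at no more than `max_male_error`; a single discordant individual fails
#' the site.
#'
#' @param call a `sex_snp_call` from [test_site()]
#' @param site the corresponding [pileup_site()] carrying
#'   `individual_counts` and `individual_sex`
#' @param model the [copy_model()] used for the pools
#' @param alpha per-individual significance level (default 0.01)
#' @param max_male_error maximum W fraction tolerated in a male
#' @return the call with `individual_concordant` set (TRUE/FALSE) and a
#'   `discordant_individuals` attribute
#' @export
confirm_in_individuals <- function(call, site, model, alpha = 0.01,
                                   max_male_error = 0.05) {
  sexes <- site$individual_sex
  if (length(site$individual_counts) == 0)
    stop("site carries no individual counts")
  if (is.null(names(sexes)) ||
      !all(names(site$individual_counts) %in% names(sexes)))
    stop("missing sex labels for individuals")
  exp_f <- expected_allele_fraction(model, "female")
  discordant <- character(0)
  for (id in names(site$individual_counts)) {
    wf <- w_fraction(site$individual_counts[[id]], model$w_allele)
    ok <- if (sexes[[id]] == "female") {
      wf$n > 0 &&
        stats::binom.test(wf$x, wf$n, p = exp_f)$p.value > alpha
    } else {
      wf$n > 0 && wf$frac <= max_male_error
    }
    if (!ok) discordant <- c(discordant, id)
  }
  call$individual_concordant <- length(discordant) == 0
  attr(call, "discordant_individuals") <- discordant
  call
}

#' Scan many sites under candidate copy models
#'
#' Tests every site under each supplied model, keeps the best-fitting model
#' (largest female-pool p-value), optionally applies Benjamini-Hochberg
#' correction across sites, and returns calls in deterministic
#' (reference, position) order together with per-reference class counts.
#'
#' @param sites list of [pileup_site()] objects
#' @param models list of [copy_model()] objects
#' @param alpha,max_male_error,ghost_threshold passed to [test_site()]
#' @param bh if TRUE, `p_female` values are BH-adjusted before
#'   classification (off by default for single-region workflows)
#' @return a list with `calls` (data.frame, one row per site) and `summary`
#'   (per-reference class counts)
#' @export
genome_scan <- function(sites, models = list(copy_model("simple_WZ"),
                                             copy_model("W_plus_duplicated_paralog")),
                        alpha = 0.05, max_male_error = 0.05,
                        ghost_threshold = 1.5, bh = FALSE) {
  if (length(sites) == 0)
    return(list(calls = data.frame(), summary = data.frame()))
  best <- lapply(sites, function(s) {
    cand <- lapply(models, function(m)
      test_site(s, m, alpha = alpha, max_male_error = max_male_error,
                ghost_threshold = ghost_threshold))
    ps <- vapply(cand, function(cc) cc$p_female %||% NA_real_, numeric(1))
    if (all(is.na(ps))) cand[[1]] else cand[[which.max(ps)]]
  })
  calls <- do.call(rbind, lapply(best, function(cc)
    data.frame(reference_id = cc$reference_id, position = cc$position,
               model = cc$model,
               expected_female_fraction = cc$expected_female_fraction,
               observed_female_fraction = cc$observed_female_fraction,
               observed_male_fraction = cc$observed_male_fraction,
               p_female = cc$p_female,
               p_male_contamination = cc$p_male_contamination,
               ghost = cc$ghost, class = cc$class)))
  calls <- calls[order(calls$reference_id, calls$position), ]
  rownames(calls) <- NULL
  if (bh) {
    calls$p_female_bh <- stats::p.adjust(calls$p_female, method = "BH")
  }
  summary <- as.data.frame(table(reference_id = calls$reference_id,
                                 class = calls$class))
  summary <- summary[summary$Freq > 0, ]
  rownames(summary) <- NULL
  list(calls = calls, summary = summary)
}
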