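#' A PCR primer pair
#'
#' @param forward,reverse primer sequences, both written 5'->3'
#' @param max_product maximum amplicon length in bp (default 3000)
#' @param max_mismatch mismatches tolerated per primer (default 0); the 3'
#'   terminal base must always match exactly
#' @return an object of class `primer_pair`
#' @export
primer_pair <- function(forward, reverse, max_product = 3000,
                        max_mismatch = 0) {
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15) stop("primer shorter than 15 nt: ", p)
    if (grepl("[^ACGTN]", p)) stop("primer has non-IUPAC characters: ", p)
  }
  structure(list(forward = forward, reverse = reverse,
                 max_product = as.integer(max_product),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

# forward-primer binding sites on the plus strand of `template`
# (max_mismatch tolerated, 3'-terminal base exact). Returns start positions.
primer_sites <- function(primer, template, max_mismatch) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer), template,
    max.mismatch = max_mismatch, fixed = FALSE)
  starts <- Biostrings::start(hits)
  if (max_mismatch > 0 && length(starts)) {
    # enforce the exact 3' clamp
    last <- substr(primer, nchar(primer), nchar(primer))
    tmpl_chr <- as.character(template)
    keep <- substr(tmpl_chr, starts + nchar(primer) - 1L,
                   starts + nchar(primer) - 1L) == last | last == "N"
    starts <- starts[keep]
  }
  starts
}

# rc(reverse)-primer sites on the plus strand; the reverse primer's 3' end
# is the FIRST base of its plus-strand footprint
reverse_sites <- function(primer, template, max_mismatch) {
  rc <- reverse_complement_chr(primer)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(rc), template,
    max.mismatch = max_mismatch, fixed = FALSE)
  starts <- Biostrings::start(hits)
  if (max_mismatch > 0 && length(starts)) {
    first <- substr(rc, 1L, 1L)  # complement of the primer's 3' base
    tmpl_chr <- as.character(template)
    keep <- substr(tmpl_chr, starts, starts) == first | first == "N"
    starts <- starts[keep]
  }
  starts
}

#' In-silico PCR on one template
#'
#' Reports every amplicon where the forward primer anneals to one strand
#' and the reverse primer anneals downstream on the other, within
#' `max_product` bases. Both orientations of the template are searched;
#' coordinates are always reported on the supplied (plus) strand, 0-based
#' half-open, with length inclusive of both primers. Mismatches up to
#' `max_mismatch` are allowed per primer but the 3' terminal base must
#' match exactly (no extension from a mismatched 3' end).
#'
#' @param template a character string or [Biostrings::DNAString]
#' @param primers a [primer_pair()]
#' @return data.frame with columns start, end (0-based half-open), length,
#'   strand (`+` when the forward primer sits on the plus strand)
#' @export
insilico_pcr <- function(template, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  tmpl <- if (inherits(template, "DNAString")) template
  else Biostrings::DNAString(as.character(template))
  if (length(tmpl) == 0) stop("empty template")
  out <- list()
  scan_orientation <- function(fwd, rev, strand) {
    fs <- primer_sites(fwd, tmpl, primers$max_mismatch)
    rs <- reverse_sites(rev, tmpl, primers$max_mismatch)
    lf <- nchar(fwd); lr <- nchar(rev)
    for (f in fs) {
      # reverse footprint strictly downstream of the forward footprint
      ok <- rs[rs >= f + lf & rs + lr - f <= primers$max_product]
      for (r in ok)
        out[[length(out) + 1L]] <<- data.frame(
          start = f - 1L, end = r + lr - 1L, length = r + lr - f,
          strand = strand)
    }
  }
  scan_orientation(primers$forward, primers$reverse, "+")
  scan_orientation(primers$reverse, primers$forward, "-")
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), strand = character(0)))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start, res$end, res$strand), ]
  rownames(res) <- NULL
  res
}

#' A dominant or co-dominant sex-marker assay
#'
#' Dominant assays amplify only from the W haplotype (band presence means W
#' carrier). Co-dominant assays pair a W-specific target amplicon with a
#' control amplicon from the paralogous locus present in both sexes, which
#' doubles as an internal positive control: two bands call the female
#' pattern, the control band alone calls male, and a missing control
#' invalidates the assay rather than silently scoring absence.
#'
#' @param name assay name
#' @param mode `"dominant"` or `"codominant"`
#' @param target a [primer_pair()] for the sex-specific amplicon
#' @param control a [primer_pair()] for the paralog amplicon (required in
#'   codominant mode)
#' @param expected_lengths optional named vector documenting expected band
#'   sizes
#' @return an object of class `marker_assay`
#' @export
marker_assay <- function(name, mode = c("dominant", "codominant"),
                         target, control = NULL,
                         expected_lengths = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "primer_pair"))
  if (mode == "codominant") {
    if (is.null(control)) stop("codominant assay requires a control pair")
    stopifnot(inherits(control, "primer_pair"))
  }
  structure(list(name = name, mode = mode, target = target,
                 control = control, expected_lengths = expected_lengths),
            class = "marker_assay")
}

#' Score a marker assay on one genome
#'
#' Runs [insilico_pcr()] for the target (and control) primers over every
#' sequence of the genome and derives the band-pattern call.
#'
#' @param assay a [marker_assay()]
#' @param genome a [Biostrings::DNAStringSet] (all sequences carried by one
#'   individual, e.g. its two haplotypes)
#' @return a list of class `band_pattern` with `bands` (data.frame: source,
#'   sequence, length) and `call` (`"female-pattern"`, `"male-pattern"` or
#'   `"fail"`)
#' @export
score_assay <- function(assay, genome) {
  stopifnot(inherits(assay, "marker_assay"))
  amplify <- function(primers) {
    hits <- lapply(names(genome), function(sn) {
      am <- insilico_pcr(genome[[sn]], primers)
      if (nrow(am)) cbind(sequence = sn, am) else NULL
    })
    do.call(rbind, Filter(Negate(is.null), hits))
  }
  t_amp <- amplify(assay$target)
  bands <- NULL
  if (!is.null(t_amp) && nrow(t_amp))
    bands <- data.frame(source = "target", sequence = t_amp$sequence,
                        length = t_amp$length)
  target_present <- !is.null(t_amp) && nrow(t_amp) > 0
  if (assay$mode == "dominant") {
    call <- if (target_present) "female-pattern" else "male-pattern"
  } else {
    c_amp <- amplify(assay$control)
    control_present <- !is.null(c_amp) && nrow(c_amp) > 0
    if (control_present)
      bands <- rbind(bands, data.frame(source = "control",
                                       sequence = c_amp$sequence,
                                       length = c_amp$length))
    call <- if (!control_present) "fail"
    else if (target_present) "female-pattern" else "male-pattern"
  }
  structure(list(bands = bands %||% data.frame(source = character(0),
                                               sequence = character(0),
                                               length = integer(0)),
                 call = call, assay = assay$name),
            class = "band_pattern")
}

#' Concordance of marker calls with panel sex labels
#'
#' @param patterns named list of `band_pattern` objects (one per
#'   individual)
#' @param sexes named character vector of labels (`"female"`/`"male"`)
#'   covering every individual
#' @return a list with `n_female_concordant`, `n_male_concordant`, and
#'   `discordant` (data.frame of mismatching or failed individuals with
#'   band detail)
#' @export
panel_concordance <- function(patterns, sexes) {
  ids <- names(patterns)
  if (length(patterns) > 0 && (is.null(ids) || !all(ids %in% names(sexes))))
    stop("every individual needs a sex label")
  nf <- 0L; nm <- 0L
  disc <- NULL
  for (id in ids) {
    call <- patterns[[id]]$call
    expected <- if (sexes[[id]] == "female") "female-pattern"
    else "male-pattern"
    if (identical(call, expected)) {
      if (sexes[[id]] == "female") nf <- nf + 1L else nm <- nm + 1L
    } else {
      bands <- patterns[[id]]$bands
      disc <- rbind(disc, data.frame(
        id = id, sex = sexes[[id]], call = call,
        bands = paste(sprintf("%s:%d", bands$source, bands$length),
                      collapse = ",")))
    }
  }
  list(n_female_concordant = nf, n_male_concordant = nm,
       discordant = disc %||% data.frame(id = character(0),
                                         sex = character(0),
                                         call = character(0),
                                         bands = character(0)))
}

#' Expected F1 band ratio from parental sex genotypes
#'
#' Enumerates the four gamete combinations of a cross among W/Z genotypes
#' and returns the exact presence:absence ratio of a dominant W-linked band
#' (presence = at least one W). Under the ZW model the seed parent must
#' carry a W; a ZZ mother is flagged as impossible.
#'
#' @param mother,father genotypes from `"WW"`, `"WZ"`, `"ZZ"`
#' @param mode assay mode (band logic is identical for the W-specific
#'   amplicon of both modes)
#' @return named integer vector `c(present, absent)` reduced to lowest
#'   terms
#' @export
expected_f1_ratio <- function(mother, father, mode = "dominant") {
  legal <- c("WW", "WZ", "ZZ")
  if (!mother %in% legal || !father %in% legal)
    stop("genotypes must be WW, WZ or ZZ")
  if (mother == "ZZ")
    stop("impossible parent pair: a ZZ seed parent cannot occur under ",
         "the ZW model")
  gam <- function(g) strsplit(g, "")[[1]]
  offspring <- outer(gam(mother), gam(father), paste0)
  present <- sum(grepl("W", offspring))
  absent <- length(offspring) - present
  d <- gcd(present, absent)
  if (d == 0) d <- 1L
  c(present = present %/% d, absent = absent %/% d)
}

#' Chi-square test of marker segregation against an expected ratio
#'
#' Pearson goodness-of-fit of observed presence/absence counts against the
#' expected Mendelian ratio (no continuity correction).
#'
#' @param presence logical (or 0/1) vector of band presence per progeny
#' @param ratio expected `c(present, absent)` ratio (default 3:1)
#' @return a list with `statistic`, `df`, `p_value`, and the observed
#'   counts
#' @export
segregation_test <- function(presence, ratio = c(3, 1)) {
  presence <- as.logical(presence)
  presence <- presence[!is.na(presence)]
  if (length(presence) < 10) stop("need at least 10 scored progeny")
  if (any(ratio <= 0)) stop("expected class ratio must be positive")
  obs <- c(present = sum(presence), absent = sum(!presence))
  ht <- suppressWarnings(stats::chisq.test(obs, p = ratio / sum(ratio)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, observed = obs,
       expected = unname(ht$expected))
}

#' Design synthetic sex-marker assays from the planted FSR
#'
#' Builds a dominant assay (primers inside an FSR gene, amplifying only
#' from the W haplotype at zero mismatches because the donor paralog has
#' diverged) and a co-dominant assay (the same W-specific target plus a
#' control pair at the donor paralog locus with a distinct product length).
#'
#' @param genome output of [simulate_zw_genome()]
#' @param primer_bp primer length (default 22)
#' @param product_target,product_control amplicon lengths for the target
#'   and control bands
#' @return a list with `dominant` and `codominant` [marker_assay()]s
#' @export
design_sex_marker_assays <- function(genome, primer_bp = 22,
                                     product_target = 300,
                                     product_control = 450) {
  pm <- genome$truth$paralog_map
  if (nrow(pm) == 0) stop("no FSR genes in this simulation")
  fc_chr <- genome$truth$fsr_interval$chrom
  w_chr <- as.character(genome$w[[fc_chr]])
  z_chr <- as.character(genome$z[[fc_chr]])
  g <- pm[1, ]
  sub_pcr <- function(seq, start1, len, product) {
    fwd <- substr(seq, start1, start1 + primer_bp - 1L)
    rev_site <- substr(seq, start1 + product - primer_bp, start1 + product - 1L)
    primer_pair(fwd, reverse_complement_chr(rev_site))
  }
  target <- sub_pcr(w_chr, g$w_start + 10L, primer_bp, product_target)
  control <- sub_pcr(z_chr, g$donor_start + 10L, primer_bp, product_control)
  list(
    dominant = marker_assay("fsr_dominant", "dominant", target,
                            expected_lengths = c(target = product_target)),
    codominant = marker_assay("fsr_codominant", "codominant", target,
                              control = control,
                              expected_lengths = c(target = product_target,
                                                   control = product_control)))
}

#' Materialize the haplotype sequences carried by a sex genotype
#'
#' @param genotype `"WW"`, `"WZ"` or `"ZZ"`
#' @param genome output of [simulate_zw_genome()]
#' @param chromosomes which chromosomes to include (default: the FSR
#'   chromosome only, sufficient for marker assays)
#' @return a [Biostrings::DNAStringSet]
#' @export
genotype_genome <- function(genotype, genome,
                            chromosomes = genome$truth$fsr_interval$chrom) {
  haps <- strsplit(genotype, "")[[1]]
  seqs <- character(0)
  for (i in seq_along(haps)) {
    src <- if (haps[i] == "W") genome$w else genome$z
    for (ch in chromosomes)
      seqs[paste0(ch, "_hap", i, "_", haps[i])] <- as.character(src[[ch]])
  }
  Biostrings::DNAStringSet(seqs)
}
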