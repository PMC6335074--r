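#' Simulate a ZW haplotype pair with a planted female-specific region
#'
#' Generates a Z haplotype (one sequence per chromosome) and a W haplotype
#' identical to it except for a single inserted female-specific region (FSR)
#' on the configured chromosome. The FSR interleaves `n_fsr_genes` gene
#' segments -- each copied from a donor locus elsewhere on the same
#' chromosome and mutated at `paralog_divergence` per site -- with
#' repeat-like filler, echoing the transposon-rich, paralog-derived
#' architecture of W-linked regions in dioecious plants.
#'
#' @param config a [sim_config()]
#' @return a list with elements `z` and `w` ([Biostrings::DNAStringSet] of
#'   chromosomes named `chr1..chrN`) and `truth`, a list carrying
#'   `fsr_interval` (chrom, 0-based half-open start/end on the W haplotype),
#'   `paralog_map` (one row per FSR gene with its W interval and Z donor
#'   interval), `fsr_layout` (gene/repeat segments relative to the FSR
#'   start), and `insertion_point` (0-based offset on the Z chromosome).
#' @export
simulate_zw_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  z_chr <- vapply(config$chromosome_length_bp, random_dna, character(1))
  names(z_chr) <- chrom_names

  L <- config$fsr_length_bp
  fc <- config$fsr_chromosome
  chr_len <- config$chromosome_length_bp[fc]
  ins <- floor(config$fsr_position * chr_len)

  paralog_map <- data.frame(gene = character(0), w_start = integer(0),
                            w_end = integer(0), donor_start = integer(0),
                            donor_end = integer(0))
  layout <- data.frame(segment = character(0), type = character(0),
                       rel_start = integer(0), rel_end = integer(0))
  fsr_seq <- ""

  if (L > 0) {
    ng <- config$n_fsr_genes
    gene_total <- round(L * (1 - config$repeat_fraction_fsr))
    gene_len <- gene_total %/% ng
    if (gene_len < 1) stop_field("n_fsr_genes",
                                 "too many genes for the FSR length")
    filler_total <- L - gene_len * ng
    n_fill <- ng + 1L
    fill_len <- rep(filler_total %/% n_fill, n_fill)
    fill_len[n_fill] <- fill_len[n_fill] + filler_total - sum(fill_len)

    # donor loci: evenly spaced, upstream of the insertion point so their
    # coordinates are shared between the Z and W haplotypes
    donor_gap <- 2000L
    donor_start0 <- round(0.05 * chr_len)
    donor_starts <- donor_start0 + (seq_len(ng) - 1L) * (gene_len + donor_gap)
    if (max(donor_starts) + gene_len >= ins)
      stop_field("fsr_length_bp",
                 "donor paralog loci do not fit upstream of the insertion point")

    pieces <- character(2L * ng + 1L)
    rel <- 0L
    for (i in seq_len(ng)) {
      pieces[2L * i - 1L] <- repeat_filler(fill_len[i])
      layout <- rbind(layout, data.frame(
        segment = sprintf("repeat_%02d", i), type = "repeat",
        rel_start = rel, rel_end = rel + fill_len[i]))
      rel <- rel + fill_len[i]
      donor <- substr(z_chr[fc], donor_starts[i] + 1L,
                      donor_starts[i] + gene_len)
      pieces[2L * i] <- mutate_dna(donor, config$paralog_divergence)
      paralog_map <- rbind(paralog_map, data.frame(
        gene = sprintf("fsr_gene_%d", i),
        w_start = ins + rel, w_end = ins + rel + gene_len,
        donor_start = donor_starts[i],
        donor_end = donor_starts[i] + gene_len))
      layout <- rbind(layout, data.frame(
        segment = sprintf("fsr_gene_%d", i), type = "gene",
        rel_start = rel, rel_end = rel + gene_len))
      rel <- rel + gene_len
    }
    pieces[2L * ng + 1L] <- repeat_filler(fill_len[n_fill])
    layout <- rbind(layout, data.frame(
      segment = sprintf("repeat_%02d", n_fill), type = "repeat",
      rel_start = rel, rel_end = rel + fill_len[n_fill]))
    fsr_seq <- paste(pieces, collapse = "")
    stopifnot(nchar(fsr_seq) == L)
  }

  w_chr <- z_chr
  w_chr[fc] <- paste0(substr(z_chr[fc], 1L, ins), fsr_seq,
                      substr(z_chr[fc], ins + 1L, chr_len))

  truth <- list(
    fsr_interval = list(chrom = chrom_names[fc], start = ins, end = ins + L),
    paralog_map = paralog_map,
    fsr_layout = layout,
    insertion_point = ins,
    chrom_names = chrom_names
  )
  list(z = Biostrings::DNAStringSet(z_chr),
       w = Biostrings::DNAStringSet(w_chr),
       truth = truth)
}

#' Fragment a haplotype into scaffolds with known placement truth
#'
#' Cuts each chromosome into scaffolds at seeded-random positions (scaled so
#' mean scaffold size is near `scaffold_n50_target_bp`), reverse-complements
#' a random half of them, and -- when `config$chimera` is set -- joins one
#' scaffold from the FSR-bearing chromosome to one from a different
#' chromosome into a single deliberately chimeric scaffold, emulating the
#' misjoined scaffold that linkage mapping later splits.
#'
#' @param haplotype a [Biostrings::DNAStringSet] of chromosomes (typically
#'   the W haplotype, i.e. the female assembly)
#' @param truth the truth list from [simulate_zw_genome()]
#' @param config a [sim_config()]
#' @param seed integer; defaults to `config$rng_seed + 97`
#' @return a list with `scaffolds` (DNAStringSet), `placement` (one row per
#'   scaffold part: scaffold_id, part, chromosome index, 0-based half-open
#'   chrom_start/chrom_end, orientation, scaf_start/scaf_end within the
#'   emitted scaffold), and `chimera_id` (NA when no chimera was made)
#' @export
fragment_assembly <- function(haplotype, truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$chimera && length(haplotype) < 2)
    stop("chimera requested but fewer than two chromosomes available")
  set.seed(seed %||% (config$rng_seed + 97L))

  placement <- NULL
  seqs <- character(0)
  sid <- 0L
  for (ci in seq_along(haplotype)) {
    L <- Biostrings::width(haplotype)[ci]
    n_parts <- max(1L, round(L / config$scaffold_n50_target_bp))
    cuts <- if (n_parts > 1)
      sort(sample(seq_len(L - 1L), n_parts - 1L)) else integer(0)
    bounds <- c(0L, cuts, L)
    chr_seq <- as.character(haplotype[[ci]])
    for (k in seq_len(length(bounds) - 1L)) {
      sid <- sid + 1L
      s0 <- bounds[k]; e0 <- bounds[k + 1L]
      part_seq <- substr(chr_seq, s0 + 1L, e0)
      ori <- if (runif(1) < 0.5) "+" else "-"
      if (ori == "-") part_seq <- reverse_complement_chr(part_seq)
      id <- sprintf("scaffold_%03d", sid)
      seqs[id] <- part_seq
      placement <- rbind(placement, data.frame(
        scaffold_id = id, part = 1L, chromosome = ci,
        chrom_start = s0, chrom_end = e0, orientation = ori,
        scaf_start = 0L, scaf_end = e0 - s0))
    }
  }

  chimera_id <- NA_character_
  if (config$chimera) {
    fc <- config$fsr_chromosome
    other <- setdiff(unique(placement$chromosome), fc)[1]
    # join the first scaffold of the FSR chromosome to the last of another;
    # avoid the FSR-bearing scaffold itself so the planted region stays whole
    cand_a <- placement$scaffold_id[placement$chromosome == fc]
    fsr_scaf <- scaffold_containing(placement, fc, truth$fsr_interval$start)
    cand_a <- setdiff(cand_a, fsr_scaf)
    if (length(cand_a) == 0) cand_a <- placement$scaffold_id[
      placement$chromosome == fc][1]
    a <- cand_a[1]
    b <- tail(placement$scaffold_id[placement$chromosome == other], 1)
    chimera_id <- paste0(a, "c")
    ra <- placement[placement$scaffold_id == a, ]
    rb <- placement[placement$scaffold_id == b, ]
    la <- ra$scaf_end; lb <- rb$scaf_end
    seqs[chimera_id] <- paste0(seqs[a], seqs[b])
    placement <- placement[!placement$scaffold_id %in% c(a, b), ]
    ra$scaffold_id <- chimera_id; ra$part <- 1L
    rb$scaffold_id <- chimera_id; rb$part <- 2L
    rb$scaf_start <- la; rb$scaf_end <- la + lb
    placement <- rbind(placement, ra, rb)
    seqs <- seqs[setdiff(names(seqs), c(a, b))]
  }
  placement <- placement[order(placement$scaffold_id, placement$part), ]
  rownames(placement) <- NULL
  list(scaffolds = Biostrings::DNAStringSet(seqs),
       placement = placement, chimera_id = chimera_id)
}

# scaffold id whose truth placement covers 0-based position pos0 on chromosome ci
scaffold_containing <- function(placement, ci, pos0) {
  hit <- placement$chromosome == ci & placement$chrom_start <= pos0 &
    placement$chrom_end > pos0
  placement$scaffold_id[hit][1]
}

#' Map a chromosome coordinate onto its scaffold
#'
#' Translates a 0-based chromosome position into the (scaffold, 1-based
#' position) frame of the fragmented assembly, honouring the emitted
#' orientation of each scaffold part.
#'
#' @param placement the placement truth table from [fragment_assembly()]
#' @param chromosome chromosome index
#' @param pos0 0-based chromosome coordinate
#' @return a list `(scaffold_id, position)` with `position` 1-based, or NULL
#'   if the coordinate falls in no scaffold part
#' @export
truth_to_scaffold_position <- function(placement, chromosome, pos0) {
  hit <- which(placement$chromosome == chromosome &
                 placement$chrom_start <= pos0 &
                 placement$chrom_end > pos0)
  if (length(hit) == 0) return(NULL)
  r <- placement[hit[1], ]
  scaf_pos0 <- if (r$orientation == "+")
    r$scaf_start + (pos0 - r$chrom_start)
  else
    r$scaf_start + (r$chrom_end - 1L - pos0)
  list(scaffold_id = r$scaffold_id, position = scaf_pos0 + 1L)
}
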