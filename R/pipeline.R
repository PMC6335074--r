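write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic ZW analysis pipeline
#'
#' End-to-end orchestration on a simulated dataset: simulate the ZW
#' haplotype pair and pool depth tracks; scan both references for
#' sex-specific regions and call the sex system; test pooled SNP sites
#' under copy models and confirm the top candidate in sexed individuals;
#' fragment the female assembly, anchor scaffolds back to the genetic map
#' and build pseudomolecules with an AGP; aggregate the F1 genotype matrix
#' into haploblocks, compute the recombination-frequency matrix and call
#' centromeres; design and validate sex-marker assays on a germplasm
#' panel and test 3:1 F1 segregation; and write a machine-readable run
#' report. Stage outputs (FASTA, BED, AGP, TSV, JSON) are written under
#' `out_dir`; identical config and seed reproduce them byte-identically.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if needed)
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it (defaults to `config$rng_seed`)
#' @param n_assoc_sites sites per class in the SNP-association stage
#' @param write_depth_tracks if TRUE the (large) per-base depth TSVs are
#'   written as well
#' @return the run report, invisibly (also written to
#'   `out_dir/report.json`)
#' @export
run_zw_pipeline <- function(config = sim_config(), out_dir,
                            seed = config$rng_seed, n_assoc_sites = 50,
                            write_depth_tracks = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$rng_seed <- as.integer(seed)
  params <- scan_params()

  # -- stage 1: simulate ---------------------------------------------------
  genome <- simulate_zw_genome(config)
  Biostrings::writeXStringSet(genome$z, file.path(out_dir, "male_haplotype.fasta"))
  Biostrings::writeXStringSet(genome$w, file.path(out_dir, "female_haplotype.fasta"))
  jsonlite::write_json(
    list(fsr_interval = genome$truth$fsr_interval,
         paralog_map = genome$truth$paralog_map),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  f_on_f <- simulate_pool_depth(genome$w, genome$truth, config, "female",
                                seed = seed + 11L)
  m_on_f <- simulate_pool_depth(genome$w, genome$truth, config, "male",
                                seed = seed + 12L)
  f_on_m <- simulate_pool_depth(genome$z, genome$truth, config, "female",
                                seed = seed + 13L)
  m_on_m <- simulate_pool_depth(genome$z, genome$truth, config, "male",
                                seed = seed + 14L)
  if (write_depth_tracks) {
    write_depth_track(f_on_f, file.path(out_dir, "depth_female_pool_female_ref.tsv"))
    write_depth_track(m_on_f, file.path(out_dir, "depth_male_pool_female_ref.tsv"))
  }

  # -- stage 2: depth scan and sex-system call -----------------------------
  female_scan <- scan_sex_specific_regions(f_on_f, m_on_f, params)
  male_scan <- scan_sex_specific_regions(m_on_m, f_on_m, params)
  call <- classify_sex_system(female_scan, male_scan, params)
  candidates_to_bed(female_scan$candidates,
                    file.path(out_dir, "female_specific_regions.bed"))
  jsonlite::write_json(
    list(model = call$model, evidence = call$evidence,
         female_specific = female_scan$candidates,
         male_specific = male_scan$candidates,
         params = unclass(params)),
    file.path(out_dir, "scan_report.json"), auto_unbox = TRUE, digits = 6)

  # -- stage 3: pooled SNP association -------------------------------------
  set.seed(seed + 41L)
  fsr <- genome$truth$fsr_interval
  models <- list(simple_WZ = copy_model("simple_WZ"),
                 W_plus_duplicated_paralog = copy_model("W_plus_duplicated_paralog"))
  mk_site <- function(pos, fem_model, mal_model, depth_ratio) {
    pileup_site("chr_sim", pos, "A", list(
      female = simulate_site_pileup(fem_model, config$pool_depth_f,
                                    config$base_error_rate),
      male = simulate_site_pileup(mal_model, config$pool_depth_m,
                                  config$base_error_rate)),
      depth_ratio = depth_ratio)
  }
  sites <- list()
  has_fsr <- fsr$end > fsr$start
  true_pos <- if (has_fsr)
    sort(sample(seq(fsr$start + 1L, fsr$end), n_assoc_sites,
                replace = TRUE)) else integer(0)
  if (has_fsr) {
    for (i in seq_len(n_assoc_sites))     # W + duplicated paralog (1:2)
      sites[[length(sites) + 1L]] <- mk_site(
        true_pos[i], c(A = 1, G = 2), c(G = 2), 1.5)
    for (i in seq_len(n_assoc_sites))     # simple W vs Z site (1:1)
      sites[[length(sites) + 1L]] <- mk_site(
        sample.int(fsr$start, 1), c(A = 1, G = 1), c(G = 2), 1.0)
  }
  for (i in seq_len(n_assoc_sites))       # unassociated heterozygous site
    sites[[length(sites) + 1L]] <- mk_site(
      sample.int(fsr$start, 1), c(A = 1, G = 1), c(A = 1, G = 1), 1.0)
  scan <- genome_scan(sites, models)
  write_tsv(scan$calls, file.path(out_dir, "snp_calls.tsv"))
  n_sex_linked <- sum(scan$calls$class == "sex_linked")

  # confirm the strongest 1:2 candidate in 3 + 3 sexed individuals
  top_call <- NULL
  if (has_fsr) {
  set.seed(seed + 42L)
  ind_counts <- c(lapply(1:3, function(i)
    simulate_site_pileup(c(A = 1, G = 2), 44, config$base_error_rate)),
    lapply(1:3, function(i)
      simulate_site_pileup(c(G = 2), 44, config$base_error_rate)))
  names(ind_counts) <- c(paste0("F", 1:3), paste0("M", 1:3))
  ind_sex <- setNames(rep(c("female", "male"), each = 3), names(ind_counts))
  top_site <- pileup_site("chr_sim", true_pos[1], "A",
                          sites[[1]]$pool_counts,
                          individual_counts = ind_counts,
                          individual_sex = ind_sex, depth_ratio = 1.5)
  top_call <- test_site(top_site, models$W_plus_duplicated_paralog)
  top_call <- confirm_in_individuals(top_call, top_site,
                                     models$W_plus_duplicated_paralog)
  }

  # -- stage 4: scaffold anchoring -----------------------------------------
  frag <- fragment_assembly(genome$w, genome$truth, config,
                            seed = seed + 51L)
  map <- build_genetic_map_truth(genome$truth, config)
  marker_rows <- lapply(seq_len(nrow(map$markers)), function(i) {
    mk <- map$markers[i, ]
    hit <- truth_to_scaffold_position(frag$placement, mk$chromosome,
                                      mk$pos_w_bp - 1L)
    if (is.null(hit)) return(NULL)
    data.frame(marker_id = mk$marker_id, lg = mk$lg, cM = mk$cM,
               scaffold_id = hit$scaffold_id, position = hit$position)
  })
  marker_tab <- do.call(rbind, Filter(Negate(is.null), marker_rows))
  write_tsv(marker_tab, file.path(out_dir, "mapped_markers.tsv"))
  anchored <- anchor_scaffolds(frag$scaffolds, marker_tab)
  pseudo <- build_pseudomolecules(anchored$placements, anchored$scaffolds,
                                  seed = seed + 52L)
  Biostrings::writeXStringSet(pseudo$fasta,
                              file.path(out_dir, "pseudomolecules.fasta"))
  write_agp(pseudo$agp, file.path(out_dir, "pseudomolecules.agp"))
  write_tsv(anchored$placements, file.path(out_dir, "placements.tsv"))
  anchored_bp <- sum(Biostrings::width(anchored$scaffolds)[
    names(anchored$scaffolds) %in% anchored$placements$scaffold_id])
  total_bp <- sum(Biostrings::width(anchored$scaffolds))

  # -- stage 5: haploblocks, rf matrix, centromeres ------------------------
  f1 <- simulate_f1_population(genome$truth, config, map = map,
                               seed = seed + 61L)
  geno <- flag_double_recombinants(f1$genotypes, f1$seg_type,
                                   f1$map$markers)
  blocks <- aggregate_haploblocks(geno, f1$seg_type, f1$map$markers)
  rfm <- rf_matrix(blocks)
  export_rf_matrix(rfm, tsv_path = file.path(out_dir, "rf_matrix.tsv"),
                   png_path = file.path(out_dir, "rf_heatmap.png"))
  pos_of <- setNames(map$markers$pos_bp, map$markers$marker_id)
  block_tab <- do.call(rbind, lapply(blocks, function(b) data.frame(
    block_id = b$id, chromosome = b$lg, cM = b$cM,
    pos_bp = mean(pos_of[b$members]), n_markers = length(b$members))))
  cen <- suppressWarnings(detect_centromere(block_tab))
  write_tsv(block_tab, file.path(out_dir, "haploblocks.tsv"))
  if (!is.null(cen)) write_tsv(cen, file.path(out_dir, "centromeres.tsv"))

  # -- stage 6: sex markers ------------------------------------------------
  conc <- list(n_female_concordant = 0L, n_male_concordant = 0L,
               discordant = data.frame())
  seg <- list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  if (has_fsr) {
    assays <- design_sex_marker_assays(genome)
    panel <- simulate_germplasm_panel(config, seed = seed + 71L)
    gt_pattern <- lapply(
      setNames(nm = unique(c(panel$genotype, "WW", "WZ", "ZZ"))),
      function(g) score_assay(assays$codominant, genotype_genome(g, genome)))
    patterns <- setNames(gt_pattern[panel$genotype], panel$id)
    sexes <- setNames(panel$sex, panel$id)
    conc <- panel_concordance(patterns, sexes)
    f1_presence <- f1$sex_genotype %in% c("WW", "WZ")
    seg <- segregation_test(f1_presence, expected_f1_ratio("WZ", "WZ"))
    jsonlite::write_json(
      list(concordance = conc[c("n_female_concordant", "n_male_concordant")],
           discordant = conc$discordant,
           f1_segregation = seg[c("statistic", "df", "p_value")]),
      file.path(out_dir, "marker_report.json"), auto_unbox = TRUE,
      digits = 6)
  }

  # -- stage 7: run report -------------------------------------------------
  report <- list(
    schema_version = "1.0",
    parameters = unclass(config),
    sex_system = call$model,
    candidate_regions = female_scan$candidates,
    n_sex_linked_snps = n_sex_linked,
    top_snp_individual_concordant = isTRUE(top_call$individual_concordant),
    marker_concordance = list(
      female = conc$n_female_concordant, male = conc$n_male_concordant,
      discordant = nrow(conc$discordant)),
    f1_segregation_p = seg$p_value,
    pseudochromosomes = list(
      n_scaffolds = length(anchored$scaffolds),
      n_anchored = nrow(anchored$placements),
      anchored_fraction = anchored_bp / total_bp,
      n_chromosomes = length(pseudo$fasta)),
    n_haploblocks = length(blocks),
    n_centromere_calls = if (is.null(cen)) 0L else nrow(cen))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(report)
}
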