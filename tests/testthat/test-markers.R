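rc_chr <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("primer validation enforces length and alphabet", {
  expect_error(primer_pair("ACGTACGTACGTACG", "ACGT"), "15 nt")
  expect_error(primer_pair("ACGTACGTACGTACGX", "ACGTACGTACGTACGT"),
               "non-IUPAC")
  expect_s3_class(primer_pair("ACGTACGTACGTACGT", "ACGTACGTACGTACGT"),
                  "primer_pair")
})

test_that("a constructed template yields one amplicon of the exact length", {
  set.seed(61)
  fwd <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  rev <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  insert <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  template <- paste0(fwd, insert, rc_chr(rev))
  amp <- insilico_pcr(template, primer_pair(fwd, rev))
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 20 + 100 + 20)
  expect_equal(amp$start, 0)
  expect_equal(amp$end, 140)
  # a template lacking the reverse site gives nothing
  expect_equal(nrow(insilico_pcr(paste0(fwd, insert),
                                 primer_pair(fwd, rev))), 0)
  # the reverse complement of the template amplifies too (minus strand)
  amp2 <- insilico_pcr(rc_chr(template), primer_pair(fwd, rev))
  expect_equal(nrow(amp2), 1)
  expect_equal(amp2$strand, "-")
  expect_equal(amp2$length, 140)
  # product length cap
  expect_equal(nrow(insilico_pcr(template,
                                 primer_pair(fwd, rev,
                                             max_product = 139))), 0)
})

test_that("in-silico PCR equals the all-positions oracle on random templates", {
  set.seed(62)
  n_hits <- 0L
  for (i in 1:500) {
    tlen <- sample(60:300, 1)
    template <- paste(sample(c("A", "C", "G", "T"), tlen, TRUE),
                      collapse = "")
    # half the time plant real sites so hits exist
    fwd <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    rev <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    if (i %% 2 == 0) {
      fpos <- sample(seq_len(tlen - 50), 1)
      substr(template, fpos, fpos + 15) <- fwd
      rpos <- sample(seq(fpos + 16, tlen - 15), 1)
      substr(template, rpos, rpos + 15) <- rc_chr(rev)
    }
    got <- insilico_pcr(template, primer_pair(fwd, rev,
                                              max_product = 250))
    want <- oracle_pcr(template, fwd, rev, 250)
    expect_equal(got, want, label = paste("template", i))
    n_hits <- n_hits + nrow(want)
  }
  expect_gt(n_hits, 100)  # the comparison exercised real amplicons
})

test_that("mismatch tolerance honours the exact 3' clamp", {
  set.seed(63)
  fwd <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  rev <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  # internal mismatch in the forward site: found only with max_mismatch = 1
  fwd_mut <- fwd
  substr(fwd_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(fwd, 10, 10))[1]
  template <- paste0(fwd_mut, mid, rc_chr(rev))
  expect_equal(nrow(insilico_pcr(template, primer_pair(fwd, rev))), 0)
  expect_equal(nrow(insilico_pcr(template,
                                 primer_pair(fwd, rev, max_mismatch = 1))),
               1)
  # 3'-terminal mismatch is never tolerated
  fwd_3p <- fwd
  substr(fwd_3p, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fwd, 20, 20))[1]
  template3 <- paste0(fwd_3p, mid, rc_chr(rev))
  expect_equal(nrow(insilico_pcr(template3,
                                 primer_pair(fwd, rev, max_mismatch = 1))),
               0)
})

test_that("dominant and codominant assays call genotype genomes correctly", {
  g <- tiny_genome()
  assays <- design_sex_marker_assays(g)
  wz <- genotype_genome("WZ", g)
  zz <- genotype_genome("ZZ", g)
  ww <- genotype_genome("WW", g)

  expect_equal(score_assay(assays$dominant, wz)$call, "female-pattern")
  expect_equal(score_assay(assays$dominant, ww)$call, "female-pattern")
  expect_equal(score_assay(assays$dominant, zz)$call, "male-pattern")

  p_wz <- score_assay(assays$codominant, wz)
  expect_equal(p_wz$call, "female-pattern")
  expect_setequal(p_wz$bands$source, c("target", "control"))
  p_zz <- score_assay(assays$codominant, zz)
  expect_equal(p_zz$call, "male-pattern")
  expect_equal(unique(p_zz$bands$source), "control")
  # two distinct band lengths distinguish the amplicons
  expect_false(any(p_wz$bands$length[p_wz$bands$source == "target"] %in%
                     p_wz$bands$length[p_wz$bands$source == "control"]))

  # deleting the control locus invalidates the assay (internal control)
  no_control <- Biostrings::DNAStringSet(
    setNames(strrep("A", 1000), "empty"))
  expect_equal(score_assay(assays$codominant, no_control)$call, "fail")
})

test_that("panel concordance is perfect on an error-free synthetic panel", {
  cfg <- tiny_config(panel_n_female = 133, panel_n_male = 128)
  g <- tiny_genome()
  assays <- design_sex_marker_assays(g)
  panel <- simulate_germplasm_panel(cfg, seed = 64)
  by_gt <- lapply(setNames(nm = unique(panel$genotype)), function(gt)
    score_assay(assays$codominant, genotype_genome(gt, g)))
  patterns <- setNames(by_gt[panel$genotype], panel$id)
  sexes <- setNames(panel$sex, panel$id)
  conc <- panel_concordance(patterns, sexes)
  expect_equal(conc$n_female_concordant, 133)
  expect_equal(conc$n_male_concordant, 128)
  expect_equal(nrow(conc$discordant), 0)

  # one mislabeled individual surfaces in the discordant list
  sexes_bad <- sexes
  sexes_bad[[panel$id[1]]] <- "male"
  conc2 <- panel_concordance(patterns, sexes_bad)
  expect_equal(conc2$discordant$id, panel$id[1])
  # empty panel gives zeros
  conc0 <- panel_concordance(list(), character(0))
  expect_equal(conc0$n_female_concordant + conc0$n_male_concordant, 0)
  expect_error(panel_concordance(patterns[1], character(0)), "sex label")
})

test_that("Mendelian enumeration gives the expected band ratios", {
  expect_equal(expected_f1_ratio("WZ", "WZ"), c(present = 3, absent = 1))
  expect_equal(expected_f1_ratio("WZ", "ZZ"), c(present = 1, absent = 1))
  expect_equal(expected_f1_ratio("WW", "ZZ"), c(present = 1, absent = 0))
  expect_equal(expected_f1_ratio("WW", "WZ"), c(present = 1, absent = 0))
  expect_error(expected_f1_ratio("ZZ", "WZ"), "impossible")
  expect_error(expected_f1_ratio("WX", "WZ"), "genotypes")
})

test_that("segregation chi-square matches hand computation", {
  # 72 present / 23 absent vs 3:1 -> expected 71.25 / 23.75
  seg <- segregation_test(c(rep(TRUE, 72), rep(FALSE, 23)))
  expect_equal(seg$statistic,
               0.75^2 / 71.25 + 0.75^2 / 23.75, tolerance = 1e-12)
  expect_equal(seg$df, 1)
  expect_gt(seg$p_value, 0.8)
  # exact 3:1 gives zero
  expect_equal(segregation_test(c(rep(TRUE, 75), rep(FALSE, 25)))$statistic,
               0)
  # a 50/45 split is firmly rejected
  expect_lt(segregation_test(c(rep(TRUE, 50), rep(FALSE, 45)))$p_value,
            0.001)
  expect_error(segregation_test(rep(TRUE, 5)), "at least 10")
  expect_error(segregation_test(rep(TRUE, 20), ratio = c(3, 0)), "positive")
})
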