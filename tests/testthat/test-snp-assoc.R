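test_that("expected allele fractions are exact rationals of copy counts", {
  m12 <- copy_model("W_plus_duplicated_paralog")
  expect_equal(expected_allele_fraction(m12, "female"), 1 / 3)
  expect_equal(expected_allele_fraction(m12, "male"), 0)
  m11 <- copy_model("simple_WZ")
  expect_equal(expected_allele_fraction(m11, "female"), 1 / 2)
  expect_equal(expected_allele_fraction(m11, "male", allele = "G"), 1)
  custom <- copy_model("custom", female = c(A = 2, G = 3), male = c(G = 2))
  expect_equal(expected_allele_fraction(custom, "female"), 2 / 5)
  expect_error(copy_model("custom", female = c(A = 0), male = c(G = 2)),
               "positive")
})

test_that("the pool test classifies the canonical site patterns", {
  m12 <- copy_model("W_plus_duplicated_paralog")
  # heterozygous female pool at ~1:2, male almost fixed: sex-linked
  s <- pileup_site("chr8", 140699, "A",
                   list(female = c(A = 35, G = 71), male = c(A = 4, G = 123)),
                   depth_ratio = 1.5)
  call <- test_site(s, m12)
  expect_equal(call$class, "sex_linked")
  expect_equal(call$observed_male_fraction, 4 / 127, tolerance = 1e-12)
  expect_gt(call$p_female, 0.05)

  # both pools heterozygous: unassociated
  s2 <- pileup_site("chr1", 1, "A",
                    list(female = c(A = 53, G = 53), male = c(A = 60, G = 67)))
  expect_equal(test_site(s2, m12)$class, "unassociated")

  # monomorphic: unassociated
  s3 <- pileup_site("chr1", 2, "A",
                    list(female = c(A = 0, G = 100), male = c(A = 0, G = 100)))
  expect_equal(test_site(s3, m12)$class, "unassociated")

  # zero-depth pool: unassociated with diagnostic
  s4 <- pileup_site("chr1", 3, "A",
                    list(female = c(A = 0, G = 0), male = c(A = 0, G = 100)))
  call4 <- test_site(s4, m12)
  expect_equal(call4$class, "unassociated")
  expect_equal(call4$diagnostic, "zero-depth pool")
})

test_that("binomial p matches the cumulative-sum oracle for n <= 200", {
  for (n in c(10, 53, 106, 200)) {
    for (x in unique(round(seq(0, n, length.out = 9)))) {
      for (p0 in c(1 / 3, 1 / 2)) {
        got <- stats::binom.test(x, n, p0)$p.value
        want <- oracle_binom_two_sided(x, n, p0)
        expect_equal(got, want, tolerance = 1e-9,
                     label = sprintf("x=%d n=%d p=%.3f", x, n, p0))
      }
    }
  }
  # and the package routes through the same exact test
  s <- pileup_site("c", 1, "A",
                   list(female = c(A = 30, G = 76), male = c(G = 120)))
  call <- test_site(s, copy_model("W_plus_duplicated_paralog"))
  expect_equal(call$p_female, oracle_binom_two_sided(30, 106, 1 / 3),
               tolerance = 1e-9)
})

test_that("depth-ratio ghost flag separates multi-copy sites", {
  s_hi <- pileup_site("c", 1, "A", list(female = c(A = 1), male = c(A = 1)),
                      depth_ratio = 3.0)
  s_lo <- pileup_site("c", 1, "A", list(female = c(A = 1), male = c(A = 1)),
                      depth_ratio = 1.0)
  expect_true(flag_ghost(s_hi))
  expect_false(flag_ghost(s_lo))
  # simulated: cross-mapping paralog site has ~1.5x depth, single locus ~1x
  on_counts <- simulate_site_pileup(c(A = 1, G = 2), 1e4, 0, seed = 21)
  off_counts <- simulate_site_pileup(c(A = 1, G = 1), 1e4, 0, seed = 22)
  expect_true(flag_ghost(pileup_site("c", 1, "A",
                                     list(female = on_counts, male = on_counts),
                                     depth_ratio = sum(on_counts) / 1e4),
                         multi_copy_depth_ratio = 1.25))
  expect_false(flag_ghost(pileup_site("c", 1, "A",
                                      list(female = off_counts, male = off_counts),
                                      depth_ratio = sum(off_counts) / 1e4),
                          multi_copy_depth_ratio = 1.25))
})

test_that("individual confirmation fails on a single discordant individual", {
  m12 <- copy_model("W_plus_duplicated_paralog")
  pools <- list(female = c(A = 35, G = 71), male = c(G = 127))
  good <- list(F1 = c(A = 15, G = 29), F2 = c(A = 14, G = 30),
               F3 = c(A = 16, G = 28), M1 = c(G = 44), M2 = c(G = 44),
               M3 = c(G = 44))
  sexes <- setNames(rep(c("female", "male"), each = 3), names(good))
  s <- pileup_site("c", 1, "A", pools, individual_counts = good,
                   individual_sex = sexes)
  call <- confirm_in_individuals(test_site(s, m12), s, m12)
  expect_true(call$individual_concordant)

  bad <- good
  bad$M2 <- c(A = 15, G = 29)  # a male carrying the W allele
  s2 <- pileup_site("c", 1, "A", pools, individual_counts = bad,
                    individual_sex = sexes)
  call2 <- confirm_in_individuals(test_site(s2, m12), s2, m12)
  expect_false(call2$individual_concordant)
  expect_equal(attr(call2, "discordant_individuals"), "M2")
  expect_error(confirm_in_individuals(call, pileup_site(
    "c", 1, "A", pools, individual_counts = good), m12), "sex labels")
})

test_that("panel concordance over simulated truth recovers sex linkage", {
  set.seed(33)
  m12 <- copy_model("W_plus_duplicated_paralog")
  n_ok <- 0L
  for (i in 1:100) {
    truly_linked <- i <= 50
    fem <- lapply(1:3, function(j) simulate_site_pileup(
      if (truly_linked) c(A = 1, G = 2) else c(G = 2), 44, 0.002))
    mal <- lapply(1:3, function(j) simulate_site_pileup(c(G = 2), 44, 0.002))
    counts <- c(fem, mal)
    names(counts) <- c(paste0("F", 1:3), paste0("M", 1:3))
    sexes <- setNames(rep(c("female", "male"), each = 3), names(counts))
    s <- pileup_site("c", i, "A",
                     list(female = simulate_site_pileup(
                       if (truly_linked) c(A = 1, G = 2) else c(G = 2),
                       106, 0.002),
                       male = simulate_site_pileup(c(G = 2), 127, 0.002)),
                     individual_counts = counts, individual_sex = sexes)
    call <- confirm_in_individuals(test_site(s, m12), s, m12)
    if (call$individual_concordant == truly_linked) n_ok <- n_ok + 1L
  }
  # expected error bound, computed by exact enumeration: a truly linked
  # site fails only when one of its three females trips the per-individual
  # binomial test (alpha = 0.01, n ~ 44 reads, p = 1/3)
  # site depth is Poisson(44 * 3/2); average the rejection rate over it
  q <- sum(vapply(30:110, function(n) {
    pv <- vapply(0:n, function(x) oracle_binom_two_sided(x, n, 1 / 3),
                 numeric(1))
    dpois(n, 66) * sum(dbinom(0:n, n, 1 / 3)[pv <= 0.01])
  }, numeric(1)))
  lambda <- 50 * (1 - (1 - q)^3)
  expect_gte(n_ok, 100 - ceiling(lambda + 3 * sqrt(max(lambda, 1))))
})

test_that("genome_scan keeps the best model, is order-invariant and summarises", {
  set.seed(44)
  mk <- function(pos, fem, mal) pileup_site("chrS", pos, "A", list(
    female = simulate_site_pileup(fem, 106, 0.01),
    male = simulate_site_pileup(mal, 127, 0.01)))
  sites <- c(lapply(1:20, function(i) mk(i, c(A = 1, G = 2), c(G = 2))),
             lapply(21:40, function(i) mk(i, c(A = 1, G = 1), c(G = 2))),
             lapply(41:60, function(i) mk(i, c(A = 1, G = 1), c(A = 1, G = 1))))
  scan <- genome_scan(sites)
  expect_equal(nrow(scan$calls), 60)
  # 1:2 sites fit the paralog model, 1:1 sites the simple model
  expect_true(mean(scan$calls$model[1:20] ==
                     "W_plus_duplicated_paralog") >= 0.8)
  expect_true(mean(scan$calls$model[21:40] == "simple_WZ") >= 0.8)
  expect_true(all(scan$calls$class[41:60] == "unassociated"))
  expect_true(mean(scan$calls$class[1:40] == "sex_linked") >= 0.9)
  # shuffled input gives identical output
  scan2 <- genome_scan(sites[sample(60)])
  expect_identical(scan$calls, scan2$calls)
  # empty input
  expect_equal(nrow(genome_scan(list())$calls), 0)
})
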