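mk_markers <- function(scaffold_id, lg, pos, cm) {
  data.frame(marker_id = sprintf("%s_m%d", scaffold_id, seq_along(lg)),
             lg = lg, cM = cm, scaffold_id = scaffold_id, position = pos)
}

test_that("scaffold assignment: single group, chimera, unassigned", {
  single <- mk_markers("s1", rep(3L, 5), seq(1e4, 5e4, 1e4), 1:5)
  a1 <- assign_scaffolds(single)
  expect_equal(a1$lg, 3L)
  expect_false(a1$chimeric)

  chim <- rbind(mk_markers("s2", rep(8L, 3), c(1e4, 5e4, 1e5), 1:3),
                mk_markers("s2", rep(2L, 2), c(1.5e5, 2.5e5), 10:11))
  a2 <- assign_scaffolds(chim)
  expect_true(a2$chimeric)
  expect_true(is.na(a2$lg))

  conflict <- mk_markers("s3", c(1L, 2L), c(100, 200), c(0, 0))
  expect_warning(a3 <- assign_scaffolds(conflict), "unassigned")
  expect_true(is.na(a3$lg))
  expect_false(a3$chimeric)
})

test_that("chimera flag equals the contiguous-block oracle for all 2-LG arrangements", {
  for (n in 2:6) {
    grids <- expand.grid(rep(list(c(1L, 2L)), n))
    for (r in seq_len(nrow(grids))) {
      lgs <- as.integer(grids[r, ])
      mk <- mk_markers("sx", lgs, seq_len(n) * 1000, seq_len(n))
      got <- suppressWarnings(assign_scaffolds(mk))
      expect_equal(got$chimeric, oracle_chimeric(lgs),
                   label = paste(lgs, collapse = ""))
    }
  }
})

test_that("chimeric scaffolds split at the midpoint between blocks", {
  seqc <- strrep("ACGT", 75000)  # 300 kb
  mk <- rbind(mk_markers("s906", rep(8L, 2), c(50000, 100000), 1:2),
              mk_markers("s906", rep(2L, 2), c(150000, 200000), 5:6))
  sp <- split_chimeric(seqc, mk)
  expect_equal(sp$cut_points, 125000)
  expect_equal(unname(nchar(sp$parts)), c(125000, 175000))
  expect_equal(sum(nchar(sp$parts)), nchar(seqc))
  expect_equal(names(sp$parts), c("s906a", "s906b"))
  # markers inherited with shifted coordinates
  expect_equal(sp$markers$scaffold_id, c("s906a", "s906a", "s906b", "s906b"))
  expect_equal(sp$markers$position, c(50000, 100000, 25000, 75000))
  # non-chimeric input errors
  expect_error(split_chimeric(seqc, mk_markers("s1", rep(1L, 4),
                                               1:4 * 1e4, 1:4)),
               "not chimeric")
  # interleaved blocks error
  inter <- mk_markers("s9", c(1L, 1L, 2L, 2L, 1L, 1L), 1:6 * 1e4,
                      c(1, 2, 9, 10, 3, 4))
  expect_error(split_chimeric(seqc, inter), "interleaved")
})

test_that("ordering is by median cM with deterministic tie-breaks", {
  pl <- data.frame(scaffold_id = c("b", "a", "c"),
                   anchor_cM = c(5.2, 0.0, 7.7),
                   supporting_marker_count = c(3, 3, 3))
  expect_equal(order_scaffolds(pl)$scaffold_id, c("a", "b", "c"))
  tie <- data.frame(scaffold_id = c("z", "y"),
                    anchor_cM = c(5, 5),
                    supporting_marker_count = c(2, 6))
  expect_equal(order_scaffolds(tie)$scaffold_id, c("y", "z"))
  tie2 <- data.frame(scaffold_id = c("z", "y"),
                     anchor_cM = c(5, 5),
                     supporting_marker_count = c(4, 4))
  expect_equal(order_scaffolds(tie2)$scaffold_id, c("y", "z"))
})

test_that("orientation votes follow cM order and abstain correctly", {
  up <- data.frame(position = c(1e4, 2e4, 3e4), cM = c(1, 2, 3))
  expect_equal(orient_scaffold(up), "+")
  down <- data.frame(position = c(1e4, 2e4, 3e4), cM = c(3, 2, 1))
  expect_equal(orient_scaffold(down), "-")
  expect_equal(orient_scaffold(up[1:2, ]), "?")  # fewer than 3 markers
  tied <- data.frame(position = c(1e4, 2e4, 3e4), cM = c(1, 1, 1))
  expect_equal(orient_scaffold(tied), "?")
})

test_that("orientation equals the brute-force pair-vote oracle", {
  set.seed(55)
  for (n in 3:6) {
    perms <- unique(replicate(40, sample(n), simplify = FALSE))
    for (pp in perms) {
      cm <- as.numeric(pp)
      cm[sample(n, 1)] <- cm[sample(n, 1)]  # inject occasional cM ties
      mk <- data.frame(position = seq_len(n) * 1000, cM = cm)
      expect_equal(orient_scaffold(mk), oracle_orient(mk$position, mk$cM),
                   label = paste(cm, collapse = ","))
    }
  }
})

test_that("pseudomolecule assembly inserts exactly 1000 N between scaffolds", {
  scafs <- Biostrings::DNAStringSet(c(sA = strrep("A", 100),
                                      sB = strrep("G", 200)))
  pl <- data.frame(scaffold_id = c("sA", "sB"), chromosome = 1L,
                   anchor_cM = c(0, 5), supporting_marker_count = 3L,
                   orientation = "+", order_index = 1:2)
  built <- build_pseudomolecules(pl, scafs)
  expect_equal(nchar(as.character(built$fasta[["chr1"]])), 1300)
  chr <- as.character(built$fasta[["chr1"]])
  expect_equal(substr(chr, 101, 1100), strrep("N", 1000))
  expect_equal(nrow(built$agp), 3)
  expect_equal(built$agp$component_type, c("W", "N", "W"))

  # single scaffold, + orientation: chromosome equals the scaffold
  solo <- build_pseudomolecules(pl[1, ], scafs[1])
  expect_equal(as.character(solo$fasta[["chr1"]]), strrep("A", 100))
  # missing sequence errors
  expect_error(build_pseudomolecules(pl, scafs[1]), "missing sequence")
})

test_that("AGP round-trips to the emitted FASTA through files", {
  set.seed(66)
  scafs <- Biostrings::DNAStringSet(setNames(
    vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"),
                                         50 + 37 * i, TRUE),
                                  collapse = ""), character(1)),
    paste0("s", 1:5)))
  pl <- data.frame(scaffold_id = paste0("s", 1:4),
                   chromosome = c(1L, 1L, 2L, 2L),
                   anchor_cM = c(0, 3, 1, 9),
                   supporting_marker_count = c(3L, 4L, 3L, 2L),
                   orientation = c("+", "-", "+", "?"),
                   order_index = c(1L, 2L, 1L, 2L))
  built <- build_pseudomolecules(pl, scafs, seed = 3)   # s5 -> chr0
  agp_path <- withr::local_tempfile(fileext = ".agp")
  write_agp(built$agp, agp_path)
  rebuilt <- agp_to_fasta(read_agp(agp_path), scafs)
  expect_identical(as.character(rebuilt), as.character(built$fasta))
  # conservation: object lengths = scaffold lengths + 1000 per adjacency
  expect_equal(sum(Biostrings::width(built$fasta)),
               sum(Biostrings::width(scafs)) + 1000 * 2)
  # chromosome 0 exists and carries the unanchored scaffold
  expect_true("chr0" %in% names(built$fasta))
  # reverse-complement involution
  s <- as.character(scafs[[2]])
  rc2 <- Biostrings::reverseComplement(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(as.character(rc2), s)
})

test_that("anchoring recovers placement truth on a dense synthetic map", {
  cfg <- tiny_config(chimera = TRUE)
  g <- tiny_genome()
  frag <- fragment_assembly(g$w, g$truth, cfg, seed = 8)
  map <- build_genetic_map_truth(g$truth, cfg)
  rows <- lapply(seq_len(nrow(map$markers)), function(i) {
    mk <- map$markers[i, ]
    hit <- truth_to_scaffold_position(frag$placement, mk$chromosome,
                                      mk$pos_w_bp - 1L)
    if (is.null(hit)) return(NULL)
    data.frame(marker_id = mk$marker_id, lg = mk$lg, cM = mk$cM,
               scaffold_id = hit$scaffold_id, position = hit$position)
  })
  marker_tab <- do.call(rbind, Filter(Negate(is.null), rows))
  res <- suppressWarnings(anchor_scaffolds(frag$scaffolds, marker_tab))
  truth_pl <- frag$placement

  for (i in seq_len(nrow(res$placements))) {
    p <- res$placements[i, ]
    # split chimera parts keep their parent id as a prefix
    tp <- truth_pl[truth_pl$scaffold_id == p$scaffold_id |
                     startsWith(p$scaffold_id, truth_pl$scaffold_id), ]
    tp <- tp[tp$chromosome == p$chromosome, ]
    expect_gte(nrow(tp), 1)
    if (p$supporting_marker_count >= 3 && nrow(tp) == 1 &&
        !grepl("c[ab]$", p$scaffold_id))
      expect_equal(p$orientation, tp$orientation,
                   label = p$scaffold_id)
  }
  # within each chromosome, recovered order matches physical truth order
  for (ch in unique(res$placements$chromosome)) {
    pl <- res$placements[res$placements$chromosome == ch, ]
    pl <- pl[order(pl$order_index), ]
    starts <- vapply(pl$scaffold_id, function(id) {
      tp <- truth_pl[(truth_pl$scaffold_id == id |
                        startsWith(id, truth_pl$scaffold_id)) &
                       truth_pl$chromosome == ch, ]
      min(tp$chrom_start)
    }, numeric(1))
    expect_equal(cor(seq_along(starts), starts, method = "spearman"), 1)
  }
})
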