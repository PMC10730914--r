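test_that("NG86 counting on engineered pairs and the Jukes-Cantor form", {
  # identical sequences
  e0 <- estimate_ks(strrep("ATG", 40), strrep("ATG", 40))
  expect_equal(e0$Sd, 0)
  expect_equal(e0$Nd, 0)
  expect_equal(e0$Ks, 0)
  expect_equal(e0$Ka, 0)
  # 30 TTT codons, one synonymous third-position change: S = 30 * (1/3),
  # Sd = 1, ps = 0.1 -> Ks = -(3/4) ln(1 - 4*0.1/3)
  a <- strrep("TTT", 30)
  b <- paste0("TTC", strrep("TTT", 29))
  e <- estimate_ks(a, b)
  expect_equal(e$S, 10)
  expect_equal(e$Sd, 1)
  expect_equal(e$ps, 0.1)
  expect_equal(e$Ks, 0.1073256, tolerance = 1e-6)
  expect_true(e$valid)
  # short alignments and saturated pairs are flagged invalid
  expect_false(estimate_ks(strrep("TTT", 10), strrep("TTT", 10))$valid)
  expect_error(estimate_ks("ATGATG", "ATG"), "equal length")
})

test_that("9-codon fixture counts equal the pathway-enumeration oracle", {
  a <- "ATGAAACTTGGGACCCGATGGTTTCAA"  # 9 codons, no stops
  b <- "ATGAGGCTAGGGATCCGTTGGTATCAG"  # 0-3 differences per codon
  ca <- synteloss:::split_codons(a)
  cb <- synteloss:::split_codons(b)
  exp_sd <- 0; exp_nd <- 0
  for (k in seq_along(ca)) {
    cnt <- oracle_ng86_pair(ca[k], cb[k])
    exp_sd <- exp_sd + cnt[1]; exp_nd <- exp_nd + cnt[2]
  }
  e <- estimate_ks(a, b)
  expect_equal(e$Sd, unname(exp_sd), tolerance = 1e-12)
  expect_equal(e$Nd, unname(exp_nd), tolerance = 1e-12)
})

test_that("evolve_cds respects branch length, rate classes, and the code", {
  set.seed(9)
  cds <- synteloss:::random_cds(100)
  expect_identical(evolve_cds(cds, 0, 5.6e-9, 1.4e-9), cds)
  # r_n = 0: protein never changes
  for (i in 1:25) {
    ev <- evolve_cds(cds, 40, 5.6e-9, 0)
    expect_identical(synteloss:::translate_fast(ev),
                     synteloss:::translate_fast(cds))
  }
  # no internal stops ever, length preserved
  for (i in 1:25) {
    ev <- evolve_cds(cds, 100, 5.6e-9, 3e-9)
    expect_equal(nchar(ev), nchar(cds))
    expect_false(grepl("\\*", synteloss:::translate_fast(ev)))
  }
  expect_error(evolve_cds("ATGTAA", 1, 1e-9, 1e-9), "stop codon")
  expect_error(evolve_cds("ATGA", 1, 1e-9, 1e-9), "divisible")
})

test_that("simulated synonymous divergence is recovered by the estimator", {
  set.seed(31)
  ks <- replicate(100, {
    anc <- synteloss:::random_cds(300)
    a <- evolve_cds(anc, 13.41, 5.6e-9, 1.4e-9)
    b <- evolve_cds(anc, 13.41, 5.6e-9, 1.4e-9)
    estimate_ks(a, b)$Ks
  })
  expect_equal(mean(ks), 5.6e-9 * 2 * 13.41e6, tolerance = 0.02 / 0.15)
})

test_that("peak detection: unimodal, bimodal, and sparse inputs", {
  set.seed(13)
  uni <- abs(rnorm(500, 0.15, 0.03))
  pk <- detect_ks_peaks(uni)
  expect_lt(abs(pk$mode[1] - 0.15), 0.02)
  mix <- c(abs(rnorm(500, 0.15, 0.03)), abs(rnorm(500, 0.5, 0.08)))
  pk2 <- detect_ks_peaks(mix)
  expect_gte(nrow(pk2), 2)
  modes <- sort(pk2$mode[1:2])
  expect_equal(modes[1], 0.15, tolerance = 0.05)
  expect_equal(modes[2], 0.5, tolerance = 0.1)
  expect_warning(empty <- detect_ks_peaks(numeric()), "too few")
  expect_equal(nrow(empty), 0)
  expect_warning(detect_ks_peaks(runif(10)), "too few")
})

test_that("block Ks is the median over valid pairs", {
  set.seed(17)
  anc <- synteloss:::random_cds(60)
  div <- evolve_cds(anc, 30, 5.6e-9, 1.4e-9)
  cds <- c(g1 = anc, g2 = anc, g3 = anc, g4 = anc, g5 = anc, g6 = div,
           short1 = synteloss:::random_cds(10),
           short2 = synteloss:::random_cds(10))
  block <- structure(list(
    block_id = "b0001", chrom_a = "c1", chrom_b = "c2",
    orientation = "same", score = 30,
    anchors = data.frame(gene_a = c("g1", "g3", "g5", "short1"),
                         gene_b = c("g2", "g4", "g6", "short2"),
                         chrom_a = "c1", chrom_b = "c2",
                         rank_a = 0:3, rank_b = 0:3,
                         family_id = paste0("f", 0:3),
                         stringsAsFactors = FALSE)),
    class = "synteny_block")
  expected <- median(c(
    estimate_ks(anc, anc)$Ks, estimate_ks(anc, anc)$Ks,
    estimate_ks(synteloss:::codon_align(anc, div)$a,
                synteloss:::codon_align(anc, div)$b)$Ks))
  expect_equal(block_ks(block, cds), expected)
  # a block with no valid pair is excluded with a warning
  bad <- block
  bad$anchors <- bad$anchors[4, ]
  expect_warning(out <- block_ks(bad, cds), "no valid")
  expect_true(is.na(out))
})

test_that("WGD dating arithmetic and degenerate inputs", {
  ev <- date_wgd(0.15, 0.04, 5.6e-9)
  expect_equal(ev$T_mya, 0.15 / (2 * 5.6e-9) / 1e6, tolerance = 1e-12)
  expect_equal(ev$T_mya, 13.39, tolerance = 0.01)
  expect_true(ev$ci95_mya[1] <= ev$T_mya && ev$T_mya <= ev$ci95_mya[2])
  expect_equal(date_wgd(0, 0, 5.6e-9)$T_mya, 0)
  d0 <- date_wgd(0.2, 0, 5.6e-9)
  expect_equal(d0$ci95_mya[1], d0$ci95_mya[2])
  expect_error(date_wgd(0.15, 0.04, 0), "positive")
})
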