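fam_map <- function(ann_a, ann_b, fam_a, fam_b = fam_a) {
  data.frame(gene_id = c(ann_a$gene_id, ann_b$gene_id),
             family_id = c(fam_a, fam_b), stringsAsFactors = FALSE)
}

test_that("anchors: diagonal for identical genomes, repeat cap, errors", {
  annA <- make_ann(10, prefix = "a")
  annB <- make_ann(10, prefix = "b")
  fams <- fam_map(annA, annB, sprintf("f%02d", 1:10))
  anc <- build_anchors(annA, annB, fams)
  expect_equal(nrow(anc), 10)
  expect_equal(anc$rank_a, anc$rank_b)
  # family with 25 copies in genome A contributes no anchors
  annA25 <- make_ann(25, prefix = "x")
  fams25 <- rbind(fam_map(annA25, annB[1, ],
                          rep("frep", 25), "frep"))
  expect_equal(nrow(build_anchors(annA25, annB[1, , drop = FALSE], fams25,
                                  copy_cap = 20)), 0)
  bad <- annA; bad$start[1] <- NA
  expect_error(build_anchors(bad, annB, fams), "coordinates")
})

test_that("chaining finds collinear runs and honors the block threshold", {
  mk_anchors <- function(ra, rb) {
    data.frame(gene_a = paste0("a", ra), gene_b = paste0("b", rb),
               chrom_a = "c1", chrom_b = "c1", rank_a = ra, rank_b = rb,
               family_id = paste0("f", ra), stringsAsFactors = FALSE)
  }
  bl <- chain_anchors(mk_anchors(0:5, 0:5))
  expect_length(bl, 1)
  expect_equal(bl[[1]]$score, 60)
  expect_equal(bl[[1]]$orientation, "same")
  expect_equal(nrow(bl[[1]]$anchors), 6)
  # four anchors fall below the >=5 threshold
  expect_length(chain_anchors(mk_anchors(0:3, 0:3)), 0)
  # strictly reversed rank_b order gives one inverted block
  inv <- chain_anchors(mk_anchors(0:5, 5:0))
  expect_length(inv, 1)
  expect_equal(inv[[1]]$orientation, "inverted")
  # an oversized gap splits the run
  split <- chain_anchors(mk_anchors(c(0:5, 40:45), c(0:5, 40:45)),
                         max_gap = 25)
  expect_length(split, 2)
})

test_that("chaining is invariant to relabeling and joint order reversal", {
  set.seed(5)
  ra <- sort(sample(0:30, 12))
  rb <- ra + sample(-2:2, 12, TRUE)
  a <- data.frame(gene_a = paste0("a", seq_along(ra)),
                  gene_b = paste0("b", seq_along(ra)),
                  chrom_a = "c1", chrom_b = "c2", rank_a = ra, rank_b = rb,
                  family_id = paste0("f", seq_along(ra)),
                  stringsAsFactors = FALSE)
  base <- chain_anchors(a, min_block_size = 2)
  relab <- a; relab$chrom_a <- "chr9"; relab$chrom_b <- "chrX"
  bl2 <- chain_anchors(relab, min_block_size = 2)
  expect_equal(vapply(base, `[[`, 0, "score"),
               vapply(bl2, `[[`, 0, "score"))
  # reversing both genomes' gene orders preserves the optimal chain score
  # (greedy extraction beyond the first block is deterministic but may
  # resolve score ties differently, so only the DP optimum is compared)
  rev_a <- a
  rev_a$rank_a <- max(a$rank_a) - a$rank_a
  rev_a$rank_b <- max(a$rank_b) - a$rank_b
  bl3 <- chain_anchors(rev_a, min_block_size = 2)
  expect_equal(max(vapply(base, `[[`, 0, "score")),
               max(vapply(bl3, `[[`, 0, "score")))
  expect_equal(vapply(base, function(b) b$orientation, "")[1],
               vapply(bl3, function(b) b$orientation, "")[1])
  # blocks are anchor-disjoint and drawn from the input
  used <- unlist(lapply(base, function(b) b$anchors$gene_a))
  expect_equal(anyDuplicated(used), 0)
  expect_true(all(used %in% a$gene_a))
})

test_that("depth ratios read polyploidy out of block coverage", {
  annA <- make_ann(12, prefix = "a")
  fams_self <- data.frame(gene_id = annA$gene_id,
                          family_id = sprintf("f%02d", 1:12))
  # duplicate genome: two chromosome copies of the same gene order
  annB <- rbind(make_ann(12, chrom = "d1", prefix = "b"),
                make_ann(12, chrom = "d2", prefix = "c"))
  fams <- data.frame(gene_id = c(annA$gene_id, annB$gene_id),
                     family_id = c(sprintf("f%02d", 1:12),
                                   sprintf("f%02d", 1:12),
                                   sprintf("f%02d", 1:12)))
  bl <- chain_anchors(build_anchors(annA, annB, fams))
  dp <- depth_ratio(bl, annA, annB)
  expect_equal(dp$modal_ratio, "2:1")
  # identical single-copy genomes
  annI <- make_ann(12, prefix = "i")
  fi <- data.frame(gene_id = c(annA$gene_id, annI$gene_id),
                   family_id = rep(sprintf("f%02d", 1:12), 2))
  dpi <- depth_ratio(chain_anchors(build_anchors(annA, annI, fi)),
                     annA, annI)
  expect_equal(dpi$modal_ratio, "1:1")
  expect_warning(dp0 <- depth_ratio(list(), annA, annI), "no synteny")
  expect_equal(dp0$modal_ratio, "0:0")
})

test_that("dot-plot and collinearity serializations round-trip", {
  a <- data.frame(gene_a = paste0("a", 0:5), gene_b = paste0("b", 0:5),
                  chrom_a = "c1", chrom_b = "c2", rank_a = 0:5, rank_b = 0:5,
                  family_id = paste0("f", 0:5), stringsAsFactors = FALSE)
  bl <- chain_anchors(a)
  td <- tempfile(fileext = ".tsv")
  export_dotplot(bl, td)
  expect_equal(nrow(read.delim(td)), 6)
  back <- read_dotplot(td)
  expect_equal(back[[1]]$anchors$gene_a, bl[[1]]$anchors$gene_a)
  expect_equal(back[[1]]$score, bl[[1]]$score)
  tc <- tempfile(fileext = ".txt")
  write_collinearity(bl, tc)
  back2 <- read_collinearity(tc)
  expect_equal(back2[[1]]$anchors, bl[[1]]$anchors)
  expect_equal(back2[[1]]$orientation, bl[[1]]$orientation)
  # empty set: header-only exports, empty reads
  export_dotplot(list(), td)
  expect_equal(nrow(read.delim(td)), 0)
  expect_length(read_dotplot(td), 0)
  write_collinearity(list(), tc)
  expect_length(read_collinearity(tc), 0)
})

test_that("stacked triplication and duplication give a 6:1 depth ratio", {
  # fully retained WGT on an internal branch plus a fully retained WGD on
  # a terminal leaf: that leaf covers a pre-WGT outgroup six-fold (3 x 2)
  tr <- ape::read.tree(text = "((A:6,B:6)ab:4,C:10)r;")
  cfg <- sim_config(seed = 12, n_chromosomes = 1,
                    n_background_genes_per_chrom = 16,
                    loss_rate = 0, pseudogenization_rate = 0,
                    translocation_rate = 0,
                    wgt_branches = c(ab = 1.0), wgd_branches = c(A = 1.0),
                    reference_species = "A")
  ds <- generate_dataset(tr, cfg)
  expect_equal(nrow(ds$leaves$A$ann), 6 * 28)
  expect_equal(nrow(ds$leaves$C$ann), 28)
  res <- run_pipeline(as_workspace(ds), tempfile("sixone"),
                      stages = c("homology", "synteny"), overwrite = TRUE)
  dr <- res$depth_ratios
  expect_equal(dr$modal_ratio[dr$target == "C" & dr$query == "A"], "6:1")
})
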