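test_that("Dollo losses on the textbook quartet and edge cases", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  d <- dollo_losses(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(d$loss_count, 2)
  expect_setequal(d$loss_edges$branch_id, c("B", "D"))
  expect_equal(dollo_losses(tr, c(A = 1, B = 1, C = 1, D = 1))$loss_count, 0)
  expect_equal(dollo_losses(tr, c(A = 0, B = 0, C = 0, D = 0))$loss_count, 0)
  # a whole clade lost maps to its stem branch
  d2 <- dollo_losses(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(d2$loss_edges$branch_id, "cd")
  expect_error(dollo_losses(tr, c(A = 1, B = 0, C = 1)), "missing")
  expect_error(dollo_losses(ape::read.tree(text = "(A:1,B:1,C:1);"),
                            c(A = 1, B = 0, C = 1)), "rooted")
})

test_that("Dollo equals brute-force single-gain minimization (property)", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    traits <- setNames(sample(0:1, n, TRUE), tr$tip.label)
    expect_equal(dollo_losses(tr, traits)$loss_count,
                 brute_dollo_count(tr, traits), info = i)
  }
})

test_that("Dollo loss edges partition exactly the trait-free leaves", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    traits <- setNames(sample(0:1, n, TRUE, prob = c(0.4, 0.6)),
                       tr$tip.label)
    if (all(traits == 0) || all(traits == 1)) next
    d <- dollo_losses(tr, traits)
    tr2 <- synteloss:::label_nodes(stats::reorder(tr, "cladewise"))
    lab <- c(tr2$tip.label, tr2$node.label)
    below <- function(branch) {
      node <- match(branch, lab)
      if (node <= length(tr2$tip.label)) return(lab[node])
      ape::extract.clade(tr2, node)$tip.label
    }
    covered <- unlist(lapply(d$loss_edges$branch_id, below))
    # each zero leaf is covered exactly once; no one leaf is covered
    expect_setequal(covered, names(traits)[traits == 0])
    expect_equal(anyDuplicated(covered), 0)
  }
})

test_that("pathway loss report stars clade stems; locus level differs", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  model <- load_pathway()
  enz <- model$steps$enzyme
  mat <- matrix("intact", 12, 4, dimnames = list(enz, c("A", "B", "C", "D")))
  hs <- hs_exclusive_steps(model)$enzyme
  mat[hs, c("C", "D")] <- "pseudogene"
  mat <- structure(mat, class = c("presence_matrix", "matrix"))
  rep <- pathway_loss_report(mat, tr, model)
  expect_equal(unname(rep$phenotype[c("A", "B", "C", "D")]), c(1, 1, 0, 0))
  expect_equal(rep$starred_branches, "cd")
  # functionally lost but locus-retained: locus-level Dollo sees no loss
  expect_equal(rep$per_gene[["LS"]]$loss_count, 1)
  expect_equal(rep$per_gene_locus[["LS"]]$loss_count, 0)
  expect_error(pathway_loss_report(
    structure(mat, dimnames = list(enz, c("A", "B", "C", "Z"))), tr, model),
    "missing from tree")
  # starred newick round-trips with the annotation
  tf <- tempfile(fileext = ".nwk")
  write_starred_newick(tr, rep, tf)
  expect_true(grepl("cd\\*", readLines(tf)))
})

test_that("marginal reconstruction: identity limit and normalization", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  col <- setNames(rep("V", 4), c("A", "B", "C", "D"))
  ma <- marginal_ancestral(tr, col, rate_scale = 1e-9)
  expect_true(all(abs(ma$posterior[, "V"] - 1) < 1e-9))
  expect_equal(unname(rowSums(ma$posterior)), rep(1, nrow(ma$posterior)),
               tolerance = 1e-9)
  # gaps are uninformative, the rest still drives the posterior
  col2 <- c(A = "V", B = "-", C = "V", D = "V")
  ma2 <- marginal_ancestral(tr, col2, rate_scale = 0.01)
  expect_gt(ma2$posterior["r", "V"], 0.99)
  # conflicting states across zero-length branches have zero likelihood
  tr0 <- ape::read.tree(text = "((A:0,B:0)ab:1,C:1)r;")
  expect_error(marginal_ancestral(tr0, c(A = "V", B = "L", C = "V")),
               "zero likelihood")
})

test_that("marginal posteriors equal exhaustive summation on 3 taxa", {
  set.seed(37)
  for (i in 1:20) {
    t1 <- runif(1, 0.01, 0.5); t2 <- runif(1, 0.01, 0.5)
    t3 <- runif(1, 0.01, 0.5); t4 <- runif(1, 0.01, 0.5)
    tr <- ape::read.tree(text = sprintf("((A:%.17g,B:%.17g)u:%.17g,C:%.17g)r;",
                                        t1, t2, t3, t4))
    col <- setNames(sample(AA20, 3, TRUE), c("A", "B", "C"))
    ma <- marginal_ancestral(tr, col)
    ref <- brute_marginal3(t1, t2, t3, t4, col[c("A", "B", "C")])
    expect_equal(unname(ma$posterior["r", ]), unname(ref$root),
                 tolerance = 1e-9)
    expect_equal(unname(ma$posterior["u", ]), unname(ref$internal),
                 tolerance = 1e-9)
    expect_equal(ma$log_likelihood, log(ref$lik), tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to the rooting used for calculation", {
  set.seed(41)
  tr <- ape::rtree(6, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  col <- setNames(sample(AA20, 6, TRUE), tr$tip.label)
  base <- marginal_ancestral(tr, col)$log_likelihood
  for (node in c(2, 4)) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[node],
                          resolve.root = TRUE)
    expect_equal(marginal_ancestral(rerooted, col)$log_likelihood, base,
                 tolerance = 1e-9)
  }
})

test_that("a custom rate matrix reproduces the Poisson closed form", {
  Q <- matrix(1 / 19, 20, 20)
  diag(Q) <- -1
  tr <- ape::read.tree(text = "((A:0.2,B:0.1)u:0.15,C:0.3)r;")
  col <- c(A = "V", B = "L", C = "V")
  m1 <- marginal_ancestral(tr, col)
  m2 <- marginal_ancestral(tr, col, Q = Q)
  expect_equal(m1$posterior, m2$posterior, tolerance = 1e-8)
})

test_that("site-set reconstruction indexes alignment columns", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)u:0.1,C:0.1)r;")
  aln <- c(A = "VLVAV", B = "VLVAV", C = "VLLAV")
  out <- ancestral_sites(tr, aln, sites = c(1, 3))
  expect_named(out, c("1", "3"))
  expect_equal(out[["1"]]$states[["r"]], "V")
  expect_error(ancestral_sites(tr, aln, sites = 9), "outside")
  expect_error(ancestral_sites(tr, c(A = "VL", B = "VLV", C = "VLV"),
                               sites = 1), "equal length")
})
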