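test_that("self-alignment is perfect and scores are symmetric", {
  set.seed(1)
  p <- random_protein(40)
  h <- local_align(p, p)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$query_coverage, 1)
  expect_true(h$e_value < 1e-5)
  S <- synteloss:::blosum62_az()
  for (i in 1:30) {
    a <- random_protein(sample(3:30, 1))
    b <- random_protein(sample(3:30, 1))
    expect_equal(synteloss:::cpp_local_score(a, b, S, 11, 1),
                 synteloss:::cpp_local_score(b, a, S, 11, 1))
  }
  expect_error(local_align("", "AA"), "empty")
  expect_error(local_align("AB!", "AA"), "illegal")
})

test_that("local alignment equals exhaustive enumeration on tiny pairs", {
  set.seed(7)
  S <- synteloss:::blosum62_az()
  for (i in 1:40) {
    a <- random_protein(sample(2:5, 1))
    b <- random_protein(sample(2:5, 1))
    expect_equal(synteloss:::cpp_local_score(a, b, S, 11, 1),
                 brute_local_score(a, b, S, 11, 1),
                 info = paste(a, b))
  }
})

test_that("hit table enumerates, deduplicates, filters and round-trips", {
  set.seed(2)
  g <- rep(random_protein(50), 3)  # three identical gene copies
  protA <- setNames(g, paste0("A_", 1:3))
  protB <- setNames(g, paste0("B_", 1:3))
  hits <- build_hit_table(list(A = protA, B = protB))
  # all C(6,2) = 15 unordered pairs of identical genes are significant
  expect_equal(nrow(hits), 15)
  expect_true(all(hits$qseqid < hits$sseqid))
  expect_true(all(hits$evalue <= 1e-5))
  # one species: within-proteome paralog hits only
  solo <- build_hit_table(list(A = protA))
  expect_equal(nrow(solo), 3)
  expect_true(all(solo$qspecies == "A" & solo$sspecies == "A"))
  expect_warning(build_hit_table(list(A = protA, B = character())), "empty")
  expect_error(build_hit_table(list(A = protA, B = protA)), "duplicate")
  # unrelated proteins fall below the E-value threshold
  far <- build_hit_table(list(A = c(x = random_protein(40)),
                              B = c(y = random_protein(40))))
  expect_equal(nrow(far), 0)
  tf <- tempfile(fileext = ".tsv")
  write_hit_table(hits, tf)
  back <- read_hit_table(tf)
  expect_equal(back$qseqid, hits$qseqid)
  expect_equal(back$bitscore, hits$bitscore, tolerance = 1e-9)
})

test_that("family clustering is single-linkage and refines monotonically", {
  mkhit <- function(q, s, pid, cov = 1) {
    data.frame(qseqid = q, sseqid = s, pident = pid, query_coverage = cov,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(mkhit("A", "B", 90), mkhit("B", "C", 85), mkhit("A", "C", 20))
  fam <- cluster_families(hits, identity_min = 30)
  expect_equal(length(unique(fam$family_id)), 1)  # single linkage bridges
  fam2 <- cluster_families(hits, identity_min = 95)
  expect_equal(length(unique(fam2$family_id)), 3)
  # coverage threshold also gates edges
  fam3 <- cluster_families(rbind(mkhit("A", "B", 90, cov = 0.2)),
                           coverage_min = 0.5)
  expect_equal(length(unique(fam3$family_id)), 2)
  # monotone refinement on a random graded graph
  set.seed(3)
  ids <- sprintf("g%02d", 1:12)
  rnd <- data.frame(qseqid = sample(ids, 40, TRUE),
                    sseqid = sample(ids, 40, TRUE),
                    pident = runif(40, 20, 100), query_coverage = 1,
                    stringsAsFactors = FALSE)
  rnd <- rnd[rnd$qseqid != rnd$sseqid, ]
  fams <- lapply(c(30, 60, 90), function(th)
    cluster_families(rnd, identity_min = th, universe = ids))
  for (k in 1:2) {
    lo <- setNames(fams[[k]]$family_id, fams[[k]]$gene_id)
    hi <- setNames(fams[[k + 1]]$family_id, fams[[k + 1]]$gene_id)
    for (f in unique(hi))  # every refined family sits inside one coarse one
      expect_equal(length(unique(lo[names(hi)[hi == f]])), 1)
  }
})

test_that("pathway-gene identification returns ranked tandem copies", {
  set.seed(4)
  ref <- random_protein(100)
  mutate <- function(p, k) {
    s <- strsplit(p, "")[[1]]
    i <- sample(seq_along(s), k)
    s[i] <- sample(AA20, k, TRUE)
    paste(s, collapse = "")
  }
  prot <- c(t1 = mutate(ref, 2), t2 = mutate(ref, 4), t3 = mutate(ref, 6),
            t4 = mutate(ref, 8), bg1 = random_protein(100),
            bg2 = random_protein(100))
  out <- identify_pathway_genes(list(sp = prot), c(TRI = ref))
  expect_setequal(out$gene_id, c("t1", "t2", "t3", "t4"))
  expect_equal(out$gene_id[out$rank == 1], "t1")
  expect_true(all(diff(out$bitscore[order(out$rank)]) <= 0))
  expect_error(identify_pathway_genes(list(sp = prot), c("")), "reference")
})
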