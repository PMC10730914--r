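test_that("identical seeds give byte-identical written datasets", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  write_dataset(mini_sim(seed = 5), d1)
  write_dataset(mini_sim(seed = 5), d2)
  expect_identical(report_hash(d1), report_hash(d2))
  d3 <- file.path(tempdir(), "det3")
  write_dataset(mini_sim(seed = 6), d3)
  expect_false(identical(report_hash(d1), report_hash(d3)))
})

test_that("with no events every leaf keeps the full intact pathway", {
  tr <- ape::read.tree(text = "((A:5,B:5)ab:5,(C:5,D:5)cd:5)r;")
  cfg <- sim_config(seed = 2, n_chromosomes = 2,
                    n_background_genes_per_chrom = 14,
                    loss_rate = 0, pseudogenization_rate = 0,
                    translocation_rate = 0)
  ds <- generate_dataset(tr, cfg)
  expect_true(all(ds$truth$scenario == "intact"))
  expect_length(ds$truth$loss_edges, 0)
  expect_true(all(ds$truth$phenotype == 1))
  expect_equal(nrow(ds$truth$event_log), 0)
  # every leaf holds the ancestral gene count
  expect_true(all(vapply(ds$leaves, function(l) nrow(l$ann), 0L) ==
                    2 * 14 + 12))
})

test_that("leaf gene counts reconcile with the event log (conservation)", {
  tr <- ape::read.tree(text = "((A:8,B:8)ab:6,(C:9,D:9)cd:5)r;")
  cfg <- sim_config(seed = 4, n_chromosomes = 2,
                    n_background_genes_per_chrom = 14,
                    loss_rate = 0.004, pseudogenization_rate = 0.004,
                    translocation_rate = 0.002,
                    wgd_branches = c(C = 0.5))
  ds <- generate_dataset(tr, cfg)
  ev <- ds$truth$event_log
  anc_n <- 2 * 14 + 12
  for (leaf in tr$tip.label) {
    path <- path_branches(ds$tree, leaf)
    on_path <- ev[ev$branch %in% path, ]
    gains <- sum(on_path$event %in% c("wgd_copy", "tandem_copy"))
    losses <- sum(on_path$event %in%
                    c("loss", "pseudogenization", "pathway_loss_absent",
                      "pathway_loss_pseudo"))
    expect_equal(nrow(ds$leaves[[leaf]]$ann), anc_n + gains - losses,
                 info = leaf)
  }
})

test_that("the truth matrix replays exactly from the event log", {
  ds <- mini_sim(seed = 11, wgd = c(C = 0.6), loss = "D")
  ev <- ds$truth$event_log
  symbols <- ds$model$steps$enzyme
  for (leaf in ds$tree$tip.label) {
    path <- path_branches(ds$tree, leaf)
    live <- setNames(rep(1L, length(symbols)), symbols)
    resid <- setNames(rep(0L, length(symbols)), symbols)
    on_path <- ev[ev$branch %in% path & !is.na(ev$symbol), ]
    # replay in log order (events were appended chronologically)
    for (k in seq_len(nrow(on_path))) {
      s <- on_path$symbol[k]
      switch(on_path$event[k],
             wgd_copy = , tandem_copy = { live[s] <- live[s] + 1L },
             pseudogenization = , pathway_loss_pseudo = {
               live[s] <- live[s] - 1L; resid[s] <- resid[s] + 1L },
             loss = , pathway_loss_absent = { live[s] <- live[s] - 1L },
             translocation = NULL)
    }
    replayed <- ifelse(live > 0, "intact",
                       ifelse(resid > 0, "pseudogene", "absent"))
    expect_equal(unname(ds$truth$scenario[symbols, leaf]),
                 unname(replayed), info = leaf)
  }
})

test_that("WGD with full retention doubles every gene below the branch", {
  tr <- ape::read.tree(text = "((A:5,B:5)ab:5,C:10)r;")
  cfg <- sim_config(seed = 8, n_chromosomes = 2,
                    n_background_genes_per_chrom = 14,
                    loss_rate = 0, pseudogenization_rate = 0,
                    translocation_rate = 0, wgd_branches = c(ab = 1.0))
  ds <- generate_dataset(tr, cfg)
  for (leaf in c("A", "B")) {
    tab <- table(ds$leaves[[leaf]]$family)
    expect_true(all(tab == 2), info = leaf)
  }
  expect_true(all(table(ds$leaves$C$family) == 1))
  # recorded duplicate pairs carry the duplication age
  wp <- ds$truth$wgd_pairs
  expect_true(all(wp$age_my == 10))
  expect_equal(unique(wp$true_ks), 2 * cfg$syn_rate * 1e7)
})

test_that("pseudogenization modes leave scannable residuals", {
  tr <- ape::read.tree(text = "((A:5,B:5)ab:5,(C:5,D:5)cd:5)r;")
  for (mode in c("truncate-5prime-2-exons", "premature-stop")) {
    cfg <- sim_config(seed = 21, n_chromosomes = 2,
                      n_background_genes_per_chrom = 14,
                      loss_rate = 0, pseudogenization_rate = 0,
                      translocation_rate = 0, pathway_loss_branches = "D",
                      pseudogenization_mode = mode)
    ds <- generate_dataset(tr, cfg)
    res <- ds$leaves$D$residuals
    pseudo <- rownames(ds$truth$scenario)[
      ds$truth$scenario[, "D"] == "pseudogene"]
    expect_setequal(res$symbol[!is.na(res$symbol)], pseudo)
    # residual sequence sits inside the genomic chromosome at its locus
    if (nrow(res) > 0) {
      r1 <- res[1, ]
      expect_lte(r1$end, nchar(ds$leaves$D$genomic[[r1$chrom]]))
    }
  }
})
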