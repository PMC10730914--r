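test_that("flanking windows in gene and bp units, with chromosome ends", {
  ann <- make_ann(11)
  cfg_g <- scenario_config(unit = "genes", window_genes = 2)
  mid <- syntenic_window("g006", ann, cfg_g)
  expect_equal(mid$gene_id, c("g004", "g005", "g007", "g008"))
  expect_equal(mid$side, c("upstream", "upstream", "downstream", "downstream"))
  first <- syntenic_window("g001", ann, cfg_g)
  expect_true(all(first$side == "downstream"))
  # bp unit: 2500 bp at 1 kb spacing reaches two genes each side
  cfg_bp <- scenario_config(unit = "bp", window_bp = 2500)
  expect_equal(syntenic_window("g006", ann, cfg_bp)$gene_id, mid$gene_id)
  expect_error(syntenic_window("nope", ann), "not in annotation")
})

test_that("pseudogene scan: stop lesions, truncations, random windows", {
  set.seed(23)
  cds <- synteloss:::random_cds(100)
  ref <- synteloss:::translate_fast(cds)
  pad <- function(x) paste0(synteloss:::random_dna(400), x,
                            synteloss:::random_dna(400))
  # premature stop inserted mid-CDS
  stopped <- paste0(substring(cds, 1, 150), "TAA", substring(cds, 154, 300))
  ps <- pseudogene_scan(ref, pad(stopped))
  expect_equal(ps$locus_state, "pseudogene")
  expect_true(ps$evidence$premature_stop)
  # 5' truncation: only the terminal 40% of the coding sequence remains
  trunc <- substring(cds, 181, 300)
  pt <- pseudogene_scan(ref, pad(trunc))
  expect_equal(pt$locus_state, "pseudogene")
  expect_lt(pt$evidence$coverage, 0.8)
  expect_gte(pt$evidence$coverage, 0.3)
  # the full intact CDS: full coverage, no lesion -> not a pseudogene call
  pi <- pseudogene_scan(ref, pad(cds))
  expect_equal(pi$locus_state, "absent")
  expect_gte(pi$evidence$coverage, 0.8)
  expect_false(pi$evidence$premature_stop)
  # random windows never qualify (seeded, many replicates)
  for (i in 1:100) {
    pr <- pseudogene_scan(ref, synteloss:::random_dna(2000))
    expect_equal(pr$locus_state, "absent")
  }
  expect_warning(p0 <- pseudogene_scan(ref, "AT"), "shorter")
  expect_equal(p0$locus_state, "absent")
})

# One small simulated clade exercises the full cascade.
scen_fixture <- new.env(parent = emptyenv())
scen_setup <- function() {
  if (!is.null(scen_fixture$x)) return(scen_fixture$x)
  ds <- mini_sim(seed = 11, wgd = c(C = 1.0), loss = "D")
  ws <- as_workspace(ds)
  proteomes <- lapply(ws$species, `[[`, "protein")
  hits <- build_hit_table(proteomes)
  fams <- cluster_families(hits, universe = unlist(lapply(proteomes, names),
                                                   use.names = FALSE))
  pg <- identify_pathway_genes(proteomes, ws$pathway_refs)
  annotations <- lapply(ws$species, `[[`, "ann")
  genomic <- lapply(ws$species, `[[`, "genomic")
  blocks <- list()
  for (s in ws$tree$tip.label) {
    anc <- build_anchors(annotations$A, annotations[[s]], fams)
    if (s == "A") anc <- anc[anc$chrom_a < anc$chrom_b, , drop = FALSE]
    blocks[[s]] <- chain_anchors(anc)
  }
  scen_fixture$x <- list(ds = ds, ws = ws, fams = fams, pg = pg,
                         annotations = annotations, genomic = genomic,
                         proteomes = proteomes, blocks = blocks)
  scen_fixture$x
}

test_that("cascade: self-synteny, forced losses, and intact relatives", {
  fx <- scen_setup()
  tri <- fx$pg$gene_id[fx$pg$species == "A" & fx$pg$enzyme == "TRI" &
                         fx$pg$rank == 1]
  ref_prot <- fx$proteomes$A[[tri]]
  self <- classify_gene(tri, "A", "A", "TRI", list(), fx$fams,
                        fx$annotations, fx$genomic, fx$proteomes, ref_prot)
  expect_equal(self$scenario, 1L)
  expect_equal(self$locus_state, "intact")
  expect_equal(self$gene_id, tri)
  # intact sister species: scenario 1 through a supporting block
  cb <- classify_gene(tri, "A", "B", "TRI", fx$blocks$B, fx$fams,
                      fx$annotations, fx$genomic, fx$proteomes, ref_prot)
  expect_equal(cb$scenario, 1L)
  expect_equal(cb$locus_state, "intact")
  expect_false(is.na(cb$block_id))
  # forced-loss species: synteny present, gene missing (scenario 2)
  cd <- classify_gene(tri, "A", "D", "TRI", fx$blocks$D, fx$fams,
                      fx$annotations, fx$genomic, fx$proteomes, ref_prot)
  expect_equal(cd$scenario, 2L)
  truth_d <- fx$ds$truth$scenario["TRI", "D"]
  expect_equal(cd$locus_state, truth_d)
  expect_error(classify_gene(tri, "A", "Z", "TRI", list(), fx$fams,
                             fx$annotations, fx$genomic, fx$proteomes,
                             ref_prot),
               "without annotation")
})

test_that("widening the window never demotes scenario 1 to scenario 3", {
  fx <- scen_setup()
  for (enz in c("TRI", "PMT", "H6H")) {
    g <- fx$pg$gene_id[fx$pg$species == "A" & fx$pg$enzyme == enz &
                         fx$pg$rank == 1]
    if (length(g) == 0) next
    rp <- fx$proteomes$A[[g]]
    prev <- NULL
    for (wg in c(4, 10, 20)) {
      cfg <- scenario_config(unit = "genes", window_genes = wg)
      cl <- classify_gene(g, "A", "B", enz, fx$blocks$B, fx$fams,
                          fx$annotations, fx$genomic, fx$proteomes, rp, cfg)
      if (!is.null(prev) && prev == 1L) expect_false(cl$scenario == 3L)
      prev <- cl$scenario
    }
  }
})

test_that("matrix consensus follows intact > pseudogene > absent", {
  model <- load_pathway()
  mkcall <- function(ref, enz, sp, scen, state) {
    structure(list(reference = ref, enzyme = enz, species = sp,
                   scenario = scen, locus_state = state,
                   functional_state = state, gene_id = NA_character_,
                   block_id = NA_character_, synteny_unsupported = FALSE,
                   evidence = NULL), class = "scenario_call")
  }
  calls <- list(
    mkcall("r1", "TRI", "sp1", 2L, "pseudogene"),
    mkcall("r2", "TRI", "sp1", 1L, "intact"),
    mkcall("r3", "TRI", "sp1", 2L, "absent"),
    mkcall("r1", "LS", "sp1", 2L, "absent"),
    mkcall("r2", "LS", "sp1", 3L, "pseudogene"),
    mkcall("r1", "TRI", "sp2", 2L, "absent"),
    mkcall("r2", "TRI", "sp2", 2L, "absent"))
  m <- build_matrix(calls, model, species_order = c("sp1", "sp2"))
  expect_equal(m["TRI", "sp1"], "intact")
  expect_equal(attr(m, "scenario")["TRI", "sp1"], 1L)
  expect_equal(m["LS", "sp1"], "pseudogene")
  expect_equal(m["TRI", "sp2"], "absent")
  expect_equal(rownames(m), model$steps$enzyme)
  # TSV round trip including the pseudogene glyph and scenario digits
  tf <- tempfile(fileext = ".tsv")
  write_matrix(m, tf)
  back <- read_matrix(tf)
  expect_equal(unclass(synteloss:::unclass_matrix(back)),
               unclass(synteloss:::unclass_matrix(m)))
  expect_equal(attr(back, "scenario"), attr(m, "scenario"))
})
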