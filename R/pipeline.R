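# End-to-end orchestration of the comparative pipeline.
#
# Stage order mirrors the analysis: homology -> synteny -> scenarios ->
# ksdate -> infer. Each stage writes plain-text outputs into the run
# directory and is resumable: when its outputs already exist they are
# reused rather than recomputed. All outputs are deterministic functions
# of the workspace and parameters (the run log carries no timestamps), so
# identical runs produce hash-identical bundles.

PIPELINE_STAGES <- c("homology", "synteny", "scenarios", "ksdate", "infer")

#' Run the comparative pipeline
#'
#' @param ws a `workspace` from [load_workspace()] or [as_workspace()].
#' @param out_dir run directory for stage outputs.
#' @param stages subset of `c("homology", "synteny", "scenarios", "ksdate",
#'   "infer")`; dependencies must be satisfied (scenarios needs synteny,
#'   which needs homology; infer needs scenarios) either within the call
#'   or by outputs of a previous run in the same directory.
#' @param params an [align_params()].
#' @param scen_config a [scenario_config()].
#' @param min_block_size,max_gap chaining parameters (see
#'   [chain_anchors()]).
#' @param syn_rate synonymous rate for WGD dating, default 5.6e-9.
#' @param overwrite recompute stages even when outputs exist.
#' @return list of class `pipeline_result` with the in-memory stage
#'   products (`hits`, `families`, `pathway_genes`, `blocks`,
#'   `depth_ratios`, `calls`, `matrix`, `ks`, `wgd_events`, `report`).
#' @export
run_pipeline <- function(ws, out_dir, stages = PIPELINE_STAGES,
                         params = align_params(),
                         scen_config = scenario_config(),
                         min_block_size = 5, max_gap = 25,
                         syn_rate = 5.6e-9, overwrite = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- list(synteny = "homology", scenarios = "synteny",
               ksdate = "synteny", infer = "scenarios")
  res <- list()
  log <- c(sprintf("# pipeline run; seed=%s", ws$seed),
           sprintf("# species=%d references=%s", length(ws$species),
                   paste(ws$reference_species, collapse = ",")),
           sprintf("# evalue_max=%g min_block_size=%d max_gap=%d syn_rate=%g",
                   params$evalue_max, min_block_size, max_gap, syn_rate),
           sprintf("# window_bp=%d min_flank_anchors=%d",
                   scen_config$window_bp, scen_config$min_flank_anchors))
  done <- function(stage) file.exists(stage_marker(out_dir, stage))
  for (st in PIPELINE_STAGES) {
    if (!st %in% stages) next
    dep <- need[[st]]
    if (!is.null(dep) && !dep %in% stages && !done(dep))
      stop("stage '", st, "' requires stage '", dep,
           "' (run it first or include it in `stages`)")
  }
  if ("homology" %in% stages)
    res <- c(res, stage_homology(ws, out_dir, params, overwrite))
  if ("synteny" %in% stages)
    res <- c(res, stage_synteny(ws, out_dir, min_block_size, max_gap,
                                overwrite))
  if ("scenarios" %in% stages)
    res <- c(res, stage_scenarios(ws, out_dir, scen_config, params,
                                  overwrite))
  if ("ksdate" %in% stages)
    res <- c(res, stage_ksdate(ws, out_dir, params, syn_rate, overwrite))
  if ("infer" %in% stages)
    res <- c(res, stage_infer(ws, out_dir, overwrite))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  structure(res, class = "pipeline_result")
}

stage_marker <- function(out_dir, stage) {
  file.path(out_dir, stage, ".done")
}

mark_done <- function(out_dir, stage) {
  writeLines("ok", stage_marker(out_dir, stage))
}

stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, stage)
  dir.create(d, showWarnings = FALSE)
  d
}

stage_homology <- function(ws, out_dir, params, overwrite) {
  d <- stage_dir(out_dir, "homology")
  f_hits <- file.path(d, "hits.tsv")
  f_fam <- file.path(d, "families.tsv")
  f_pg <- file.path(d, "pathway_genes.tsv")
  if (!overwrite && file.exists(stage_marker(out_dir, "homology"))) {
    return(list(hits = read_hit_table(f_hits), families = read_tsv(f_fam),
                pathway_genes = read_tsv(f_pg)))
  }
  proteomes <- lapply(ws$species, `[[`, "protein")
  hits <- build_hit_table(proteomes, params)
  universe <- unlist(lapply(proteomes, names), use.names = FALSE)
  fams <- cluster_families(hits, universe = universe)
  pg <- identify_pathway_genes(proteomes, ws$pathway_refs, params = params)
  write_hit_table(hits, f_hits)
  write_tsv(fams, f_fam)
  write_tsv(pg, f_pg)
  mark_done(out_dir, "homology")
  list(hits = hits, families = fams, pathway_genes = pg)
}

# Pairs for which synteny blocks are computed: every reference against
# every species (cross-pairs), plus every genome against itself (for
# paralog/WGD profiling).
synteny_pairs <- function(ws) {
  refs <- ws$reference_species
  sps <- names(ws$species)
  pairs <- unique(c(
    lapply(refs, function(r) lapply(setdiff(sps, r), function(s) c(r, s))),
    lapply(sps, function(s) list(c(s, s)))))
  unique(do.call(c, pairs))
}

pair_key <- function(a, b) paste0(a, "__", b)

stage_synteny <- function(ws, out_dir, min_block_size, max_gap, overwrite) {
  d <- stage_dir(out_dir, "synteny")
  fams <- read_tsv(file.path(out_dir, "homology", "families.tsv"))
  pairs <- synteny_pairs(ws)
  blocks <- list()
  if (!overwrite && file.exists(stage_marker(out_dir, "synteny"))) {
    for (p in pairs) {
      k <- pair_key(p[1], p[2])
      blocks[[k]] <- read_collinearity(file.path(d, paste0(k, ".txt")))
    }
    return(list(blocks = blocks,
                depth_ratios = read_tsv(file.path(d, "depth_ratios.tsv"))))
  }
  for (p in pairs) {
    a <- p[1]; b <- p[2]
    anc <- build_anchors(ws$species[[a]]$ann, ws$species[[b]]$ann, fams)
    if (a == b) {
      anc <- anc[anc$chrom_a < anc$chrom_b, , drop = FALSE]
    }
    bl <- chain_anchors(anc, min_block_size = min_block_size,
                        max_gap = max_gap)
    k <- pair_key(a, b)
    blocks[[k]] <- bl
    write_collinearity(bl, file.path(d, paste0(k, ".txt")))
    export_dotplot(bl, file.path(d, paste0(k, ".dotplot.tsv")))
  }
  depth <- list()
  for (p in pairs) {
    if (p[1] == p[2]) next
    dp <- depth_ratio(blocks[[pair_key(p[1], p[2])]],
                      ws$species[[p[1]]]$ann, ws$species[[p[2]]]$ann)
    depth[[length(depth) + 1]] <- data.frame(
      target = p[1], query = p[2], modal_ratio = dp$modal_ratio,
      stringsAsFactors = FALSE)
    dp2 <- list(modal_ratio = paste(rev(strsplit(dp$modal_ratio,
                                                 ":")[[1]]), collapse = ":"))
    depth[[length(depth) + 1]] <- data.frame(
      target = p[2], query = p[1], modal_ratio = dp2$modal_ratio,
      stringsAsFactors = FALSE)
  }
  depth <- if (length(depth) > 0) do.call(rbind, depth) else
    data.frame(target = character(), query = character(),
               modal_ratio = character())
  write_tsv(depth, file.path(d, "depth_ratios.tsv"))
  mark_done(out_dir, "synteny")
  list(blocks = blocks, depth_ratios = depth)
}

stage_scenarios <- function(ws, out_dir, scen_config, params, overwrite) {
  d <- stage_dir(out_dir, "scenarios")
  f_mat <- file.path(d, "matrix.tsv")
  f_calls <- file.path(d, "calls.jsonl")
  if (!overwrite && file.exists(stage_marker(out_dir, "scenarios"))) {
    return(list(matrix = read_matrix(f_mat),
                calls = jsonl_to_df(f_calls)))
  }
  fams <- read_tsv(file.path(out_dir, "homology", "families.tsv"))
  pg <- read_tsv(file.path(out_dir, "homology", "pathway_genes.tsv"))
  blocks <- list()
  for (r in ws$reference_species)
    for (s in setdiff(names(ws$species), r)) {
      k <- pair_key(r, s)
      blocks[[k]] <- read_collinearity(
        file.path(out_dir, "synteny", paste0(k, ".txt")))
    }
  annotations <- lapply(ws$species, `[[`, "ann")
  genomic <- lapply(ws$species, `[[`, "genomic")
  proteomes <- lapply(ws$species, `[[`, "protein")
  calls <- list()
  for (r in ws$reference_species) {
    for (enz in names(ws$pathway_refs)) {
      cand <- pg[pg$species == r & pg$enzyme == enz & pg$rank == 1, ,
                 drop = FALSE]
      ref_gene <- if (nrow(cand) > 0) cand$gene_id[1] else
        fallback_ref_gene(ws$pathway_refs[[enz]], proteomes[[r]], params)
      if (is.na(ref_gene)) next
      ref_prot <- proteomes[[r]][[ref_gene]]
      for (s in names(ws$species)) {
        cl <- classify_gene(ref_gene, r, s, enz,
                            blocks[[pair_key(r, s)]] %||% list(), fams,
                            annotations, genomic, proteomes, ref_prot,
                            scen_config, params)
        calls[[length(calls) + 1]] <- cl
      }
    }
  }
  mat <- build_matrix(calls, ws$model, species_order = ws$tree$tip.label)
  write_matrix(mat, f_mat)
  df_to_jsonl(attr(mat, "calls"), f_calls)
  mark_done(out_dir, "scenarios")
  list(matrix = mat, calls = attr(mat, "calls"))
}

# When the strict (>=80% identity) identification misses the reference
# genome's own copy of an enzyme, fall back to the best diverged hit so the
# enzyme's row is still classified rather than silently dropped.
fallback_ref_gene <- function(ref_protein, proteome, params,
                              identity_min = 50) {
  h <- cpp_query_hits(toupper(ref_protein), names(proteome),
                      toupper(unname(proteome)), blosum62_az(),
                      params$gap_open, params$gap_extend, params$ka_lambda,
                      log(params$ka_K), params$evalue_max, 4L, 30L)
  h <- h[h$pident >= identity_min, , drop = FALSE]
  if (nrow(h) == 0) return(NA_character_)
  h$sseqid[order(-h$bitscore, h$sseqid)][1]
}

df_to_jsonl <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df)))
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  invisible(path)
}

jsonl_to_df <- function(path) {
  rows <- lapply(readLines(path), function(x) {
    l <- jsonlite::fromJSON(x)
    l[vapply(l, is.null, logical(1))] <- NA
    as.data.frame(l, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

stage_ksdate <- function(ws, out_dir, params, syn_rate, overwrite) {
  d <- stage_dir(out_dir, "ksdate")
  f_ks <- file.path(d, "self_ks.tsv")
  f_ev <- file.path(d, "wgd_events.tsv")
  if (!overwrite && file.exists(stage_marker(out_dir, "ksdate"))) {
    return(list(ks = read_tsv(f_ks), wgd_events = read_tsv(f_ev)))
  }
  out_ks <- list()
  events <- list()
  for (sp in names(ws$species)) {
    bl <- read_collinearity(file.path(out_dir, "synteny",
                                      paste0(pair_key(sp, sp), ".txt")))
    if (length(bl) == 0) next
    cds <- ws$species[[sp]]$cds
    for (b in bl) {
      pk <- pair_ks(b$anchors$gene_a, b$anchors$gene_b, cds, params)
      pk$species <- sp
      pk$block_id <- b$block_id
      out_ks[[length(out_ks) + 1]] <- pk
    }
    ksv <- do.call(rbind, out_ks)
    ksv <- ksv$Ks[ksv$species == sp & ksv$valid]
    pk <- suppressWarnings(detect_ks_peaks(ksv))
    for (i in seq_len(nrow(pk))) {
      ev <- date_wgd(pk$mode[i], pk$component_sd[i], syn_rate)
      events[[length(events) + 1]] <- data.frame(
        species = sp, peak = i, weight = pk$weight[i],
        ks_mode = ev$ks_mode, component_sd = ev$component_sd,
        T_mya = ev$T_mya, ci_low = ev$ci95_mya[1], ci_high = ev$ci95_mya[2],
        n_pairs = length(ksv), stringsAsFactors = FALSE)
    }
  }
  ks <- if (length(out_ks) > 0) do.call(rbind, out_ks) else
    data.frame(gene_a = character(), gene_b = character(), Ks = numeric(),
               valid = logical(), species = character(),
               block_id = character())
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(species = character(), peak = integer(), weight = numeric(),
               ks_mode = numeric(), component_sd = numeric(),
               T_mya = numeric(), ci_low = numeric(), ci_high = numeric(),
               n_pairs = integer())
  write_tsv(ks, f_ks)
  write_tsv(events, f_ev)
  mark_done(out_dir, "ksdate")
  list(ks = ks, wgd_events = events)
}

stage_infer <- function(ws, out_dir, overwrite) {
  d <- stage_dir(out_dir, "infer")
  f_loss <- file.path(d, "losses.tsv")
  f_phen <- file.path(d, "phenotype.tsv")
  f_nwk <- file.path(d, "starred.nwk")
  mat <- read_matrix(file.path(out_dir, "scenarios", "matrix.tsv"))
  report <- pathway_loss_report(mat, ws$tree, ws$model)
  if (overwrite || !file.exists(stage_marker(out_dir, "infer"))) {
    per_gene <- do.call(rbind, lapply(names(report$per_gene), function(g)
      data.frame(trait = g, level = "functional",
                 loss_count = report$per_gene[[g]]$loss_count,
                 loss_branches = paste(report$per_gene[[g]]$loss_edges$branch_id,
                                       collapse = ","),
                 stringsAsFactors = FALSE)))
    per_locus <- do.call(rbind, lapply(names(report$per_gene_locus),
                                       function(g)
      data.frame(trait = g, level = "locus",
                 loss_count = report$per_gene_locus[[g]]$loss_count,
                 loss_branches = paste(
                   report$per_gene_locus[[g]]$loss_edges$branch_id,
                   collapse = ","),
                 stringsAsFactors = FALSE)))
    phen <- data.frame(trait = "pathway_phenotype", level = "phenotype",
                       loss_count = report$phenotype_dollo$loss_count,
                       loss_branches = paste(report$starred_branches,
                                             collapse = ","),
                       stringsAsFactors = FALSE)
    write_tsv(rbind(phen, per_gene, per_locus), f_loss)
    write_tsv(data.frame(species = names(report$phenotype),
                         producer = unname(report$phenotype)), f_phen)
    write_starred_newick(ws$tree, report, f_nwk)
    mark_done(out_dir, "infer")
  }
  list(report = report)
}

#' Hash of a pipeline run directory
#'
#' md5 over the sorted per-file md5 sums of every regular file in the run
#' directory; identical runs produce identical hashes.
#' @param dir run directory.
#' @export
report_hash <- function(dir) {
  rel <- sort(list.files(dir, recursive = TRUE))
  files <- file.path(dir, rel)
  files <- files[!dir.exists(files)]
  sums <- tools::md5sum(files)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(rel, unname(sums), sep = "\t"), tf)
  unname(tools::md5sum(tf))
}
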