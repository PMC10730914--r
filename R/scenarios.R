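# Microsynteny scenario classification.
#
# For every pathway gene of a reference genome and every query genome, the
# cascade asks: (1) does a collinear block anchored by the reference gene's
# flanking window reach the query, and does it contain a family ortholog?
# -> scenario 1, synteny supports presence; (2) block but no ortholog ->
# scenario 2, synteny supports absence, and a six-frame translated scan of
# the putative region decides pseudogene vs absent; (3) no block at all ->
# scenario 3, fall back to a genome-wide family search (translocated but
# intact genes) and, failing that, a translated scan around the best
# genome-wide hit. Calls from several reference genomes are merged with
# precedence intact > pseudogene > absent.

#' Microsynteny classification parameters
#'
#' @param window_bp flanking window on each side of the reference gene in
#'   bp, default 100000 (100 kb).
#' @param window_genes alternative window radius in gene ranks, default 20;
#'   also used to pad putative regions.
#' @param min_flank_anchors minimum window anchors a block must carry to
#'   establish the putative region, default 3.
#' @param unit `"bp"` or `"genes"`.
#' @param flank_sides `"either"` (default; the anchor quorum may come from
#'   the upstream or the downstream flank) or `"both"`.
#' @param pseudo_identity_min minimum translated identity (percent) for
#'   pseudogene evidence, default 40.
#' @param pseudo_cov_min minimum reference coverage for pseudogene
#'   evidence, default 0.3.
#' @param pseudo_cov_intact coverage at or above which a clean hit looks
#'   like a full-length gene rather than a fragment, default 0.8.
#' @param min_segment_aa shortest translated segment worth aligning,
#'   default 12.
#' @param scan_evalue_max per-segment E-value cutoff for translated hits,
#'   default 1e-3; keeps chance 8-15 residue matches in large windows from
#'   piling up into spurious pseudogene evidence.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(window_bp = 100000, window_genes = 20,
                            min_flank_anchors = 3, unit = c("bp", "genes"),
                            flank_sides = c("either", "both"),
                            pseudo_identity_min = 40, pseudo_cov_min = 0.3,
                            pseudo_cov_intact = 0.8, min_segment_aa = 12,
                            scan_evalue_max = 1e-3) {
  unit <- match.arg(unit)
  flank_sides <- match.arg(flank_sides)
  stopifnot(window_bp > 0, window_genes > 0, min_flank_anchors >= 1,
            scan_evalue_max > 0)
  structure(list(window_bp = window_bp, window_genes = window_genes,
                 min_flank_anchors = min_flank_anchors, unit = unit,
                 flank_sides = flank_sides,
                 pseudo_identity_min = pseudo_identity_min,
                 pseudo_cov_min = pseudo_cov_min,
                 pseudo_cov_intact = pseudo_cov_intact,
                 min_segment_aa = min_segment_aa,
                 scan_evalue_max = scan_evalue_max),
            class = "scenario_config")
}

#' Flanking genes around a reference gene
#'
#' Genes within `window_bp` (or within `window_genes` ranks) on each side
#' of the focal gene on its chromosome, excluding the gene itself, in
#' positional order. Genes at chromosome ends get a one-sided window.
#'
#' @param gene_id focal gene.
#' @param ann annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param config a [scenario_config()].
#' @return data.frame of flanking genes with a `side`
#'   (`"upstream"`/`"downstream"`) column.
#' @export
syntenic_window <- function(gene_id, ann, config = scenario_config()) {
  i <- match(gene_id, ann$gene_id)
  if (is.na(i)) stop("gene ", gene_id, " not in annotation")
  focal <- ann[i, ]
  same <- ann[ann$chrom == focal$chrom, , drop = FALSE]
  same <- same[order(same$start), , drop = FALSE]
  k <- match(gene_id, same$gene_id)
  if (config$unit == "genes") {
    lo <- max(1, k - config$window_genes)
    hi <- min(nrow(same), k + config$window_genes)
    sel <- same[setdiff(lo:hi, k), , drop = FALSE]
  } else {
    sel <- same[same$gene_id != gene_id &
                  same$end >= focal$start - config$window_bp &
                  same$start <= focal$end + config$window_bp, , drop = FALSE]
  }
  sel$side <- ifelse(sel$start < focal$start, "upstream", "downstream")
  sel
}

#' Six-frame translated pseudogene scan of a genomic window
#'
#' Translates the window in all six frames, splits each frame at stop
#' codons, locally aligns the reference protein to every segment, merges
#' colinear qualifying hits and assesses disabling lesions. A locus is
#' called a pseudogene when merged identity and coverage qualify
#' (`pseudo_identity_min`, `pseudo_cov_min`) and there is a lesion:
#' truncated coverage (`< pseudo_cov_intact`), a premature stop
#' interrupting a same-frame coding run, or a frameshift break. Without a
#' qualifying alignment the locus is absent. The scan never returns
#' "intact": a clean full-coverage hit would have been caught upstream as
#' scenario 1.
#'
#' @param ref_protein reference enzyme protein (string).
#' @param window_nt genomic window nucleotide sequence.
#' @param config a [scenario_config()].
#' @param params an [align_params()].
#' @return list with `locus_state` (`"pseudogene"`/`"absent"`) and
#'   `evidence` (identity, coverage, premature_stop, frameshift_breaks,
#'   per-hit table).
#' @export
pseudogene_scan <- function(ref_protein, window_nt,
                            config = scenario_config(),
                            params = align_params()) {
  ref_protein <- toupper(ref_protein)
  evidence <- list(identity_pct = 0, coverage = 0, premature_stop = FALSE,
                   frameshift_breaks = 0L, hits = NULL)
  if (is.null(window_nt) || nchar(window_nt) < 3) {
    warning("window shorter than one codon; locus called absent")
    return(list(locus_state = "absent", evidence = evidence))
  }
  hits <- translated_hits(ref_protein, toupper(window_nt), config, params)
  if (nrow(hits) == 0)
    return(list(locus_state = "absent", evidence = evidence))
  merged <- merge_colinear_hits(hits)
  reflen <- nchar(ref_protein)
  covered <- unique(unlist(mapply(seq, merged$qstart, merged$qend,
                                  SIMPLIFY = FALSE)))
  coverage <- length(covered) / reflen
  identity <- sum(merged$pident * merged$length) / sum(merged$length)
  lesion <- lesion_calls(merged)
  evidence <- list(identity_pct = identity, coverage = coverage,
                   premature_stop = lesion$premature_stop,
                   frameshift_breaks = lesion$frameshift_breaks,
                   hits = merged)
  qualifies <- identity >= config$pseudo_identity_min &&
    coverage >= config$pseudo_cov_min
  pseudo <- qualifies && (coverage < config$pseudo_cov_intact ||
                            lesion$premature_stop ||
                            lesion$frameshift_breaks >= 1)
  list(locus_state = if (pseudo) "pseudogene" else "absent",
       evidence = evidence)
}

# Align the reference protein to every stop-free translated segment of the
# six frames; returns significant hits (per-segment E-value filter) with
# window coordinates. Segment alignments run as one batched C++ call.
translated_hits <- function(ref_protein, window_nt, config, params) {
  wlen <- nchar(window_nt)
  seg_seq <- character(); seg_off <- integer()
  seg_frame <- integer(); seg_strand <- character()
  strands <- list(`+` = window_nt, `-` = revcomp(window_nt))
  for (strand in names(strands)) {
    nt <- strands[[strand]]
    for (f in 0:2) {
      sub <- substring(nt, f + 1, f + 3 * ((wlen - f) %/% 3))
      if (nchar(sub) < 3) next
      aa <- translate_fast(sub)
      segs <- frame_segments(aa, config$min_segment_aa)
      for (sg in segs) {
        seg_seq <- c(seg_seq, sg$seq)
        seg_off <- c(seg_off, sg$offset)
        seg_frame <- c(seg_frame, f)
        seg_strand <- c(seg_strand, strand)
      }
    }
  }
  empty <- data.frame(strand = character(), frame = integer(),
                      pident = numeric(), length = integer(),
                      qstart = integer(), qend = integer(),
                      nt_start = integer(), nt_end = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(seg_seq) == 0) return(empty)
  h <- cpp_query_hits(ref_protein, as.character(seq_along(seg_seq)),
                      seg_seq, blosum62_az(), params$gap_open,
                      params$gap_extend, params$ka_lambda,
                      log(params$ka_K), config$scan_evalue_max, 4L, 12L)
  if (nrow(h) == 0) return(empty)
  # rescale per-segment E-values to the whole translated search space
  # (the standard database-length correction), then filter
  total_aa <- sum(nchar(seg_seq))
  h$evalue <- h$evalue * total_aa / nchar(seg_seq[as.integer(h$sseqid)])
  h <- h[h$evalue <= config$scan_evalue_max &
           h$pident >= config$pseudo_identity_min & h$length >= 10, ,
         drop = FALSE]
  if (nrow(h) == 0) return(empty)
  i <- as.integer(h$sseqid)
  data.frame(strand = seg_strand[i], frame = seg_frame[i],
             pident = h$pident, length = h$length,
             qstart = h$qstart, qend = h$qend,
             nt_start = seg_frame[i] + 3 * (seg_off[i] + h$sstart - 1) + 1,
             nt_end = seg_frame[i] + 3 * (seg_off[i] + h$send),
             score = as.numeric(h$raw), stringsAsFactors = FALSE)
}

frame_segments <- function(aa, min_aa) {
  parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
  segs <- list()
  off <- 0L
  for (p in parts) {
    if (nchar(p) >= min_aa)
      segs[[length(segs) + 1]] <- list(seq = p, offset = off)
    off <- off + nchar(p) + 1L
  }
  segs
}

# Greedy colinear merge of hits: ascending reference coordinates with small
# overlap tolerance, best-scoring hits first claim their interval.
merge_colinear_hits <- function(hits) {
  hits <- hits[order(-hits$score), , drop = FALSE]
  taken <- hits[1, , drop = FALSE]
  for (i in seq_len(nrow(hits))[-1]) {
    h <- hits[i, ]
    overlap <- any(pmin(taken$qend, h$qend) - pmax(taken$qstart, h$qstart) + 1 >
                     0.3 * h$length)
    if (!overlap) taken <- rbind(taken, h)
  }
  taken[order(taken$qstart), , drop = FALSE]
}

lesion_calls <- function(merged) {
  premature <- FALSE
  shifts <- 0L
  if (nrow(merged) > 1) {
    for (i in seq_len(nrow(merged) - 1)) {
      a <- merged[i, ]; b <- merged[i + 1, ]
      if (a$strand != b$strand) { shifts <- shifts + 1L; next }
      ref_gap <- b$qstart - a$qend - 1
      nt_gap <- abs(b$nt_start - a$nt_end) - 1
      if (a$frame != b$frame) {
        shifts <- shifts + 1L
      } else if (ref_gap <= 10 && nt_gap <= 60) {
        # same frame, colinear, interrupted by a stop in between
        premature <- TRUE
      }
    }
  }
  list(premature_stop = premature, frameshift_breaks = shifts)
}

#' Classify one pathway gene in one query genome
#'
#' Runs the scenario cascade for a reference gene against a query species.
#' `blocks` must be the synteny blocks computed with the reference
#' annotation as side A and the query annotation as side B.
#'
#' @param ref_gene reference gene id.
#' @param ref_species,query_species species names.
#' @param enzyme enzyme symbol being classified (metadata for the call).
#' @param blocks list of `synteny_block` between the two genomes.
#' @param families family table from [cluster_families()].
#' @param annotations named list species -> annotation data.frame.
#' @param genomic named list species -> named per-chromosome sequence
#'   vector (required for the translated scans; may be `NULL`, in which
#'   case unscannable loci are called absent with a warning).
#' @param proteomes named list species -> named protein vectors (used to
#'   rank candidate orthologs).
#' @param ref_protein reference protein sequence for the focal gene.
#' @param config a [scenario_config()].
#' @param params an [align_params()].
#' @return list of class `scenario_call`: `reference`, `enzyme`, `species`,
#'   `scenario` (1/2/3), `locus_state`, `functional_state`, `gene_id`,
#'   `block_id`, `synteny_unsupported`, `evidence`.
#' @export
classify_gene <- function(ref_gene, ref_species, query_species, enzyme,
                          blocks, families, annotations, genomic,
                          proteomes, ref_protein,
                          config = scenario_config(),
                          params = align_params()) {
  ann_ref <- annotations[[ref_species]]
  ann_q <- annotations[[query_species]]
  if (is.null(ann_q)) stop("query species without annotation: ", query_species)
  fam <- setNames(families$family_id, families$gene_id)
  ref_fam <- fam[[ref_gene]] %||% NA_character_
  if (is.na(ref_fam)) ref_fam <- "__unassigned__"
  call0 <- function(scenario, locus_state, gene_id = NA_character_,
                    block_id = NA_character_, unsupported = FALSE,
                    evidence = NULL) {
    structure(list(reference = ref_species, enzyme = enzyme,
                   species = query_species, scenario = scenario,
                   locus_state = locus_state,
                   functional_state = locus_state, gene_id = gene_id,
                   block_id = block_id, synteny_unsupported = unsupported,
                   evidence = evidence), class = "scenario_call")
  }
  if (identical(ref_species, query_species))
    return(call0(1L, "intact", gene_id = ref_gene, block_id = "self"))
  win <- syntenic_window(ref_gene, ann_ref, config)
  up <- win$gene_id[win$side == "upstream"]
  down <- win$gene_id[win$side == "downstream"]
  support <- lapply(blocks, function(b) {
    nu <- sum(b$anchors$gene_a %in% up)
    nd <- sum(b$anchors$gene_a %in% down)
    ok <- if (config$flank_sides == "both")
      nu >= config$min_flank_anchors && nd >= config$min_flank_anchors
    else nu >= config$min_flank_anchors || nd >= config$min_flank_anchors
    list(block = b, n = nu + nd, ok = ok)
  })
  support <- Filter(function(s) s$ok, support)
  rq <- gene_ranks(ann_q)
  if (length(support) > 0) {
    ns <- vapply(support, function(s) s$n, 0)
    sc <- vapply(support, function(s) s$block$score, 0)
    support <- support[order(-ns, -sc)]
    region_of <- function(b) {
      win_anchor <- b$anchors[b$anchors$gene_a %in% win$gene_id, ,
                              drop = FALSE]
      span_b <- range(win_anchor$rank_b)
      lo <- span_b[1] - config$window_genes
      hi <- span_b[2] + config$window_genes
      list(span = span_b,
           genes = rq$gene_id[rq$chrom == b$chrom_b & rq$rank >= lo &
                                rq$rank <= hi])
    }
    # scenario 1 when any supporting block's region holds a family ortholog
    for (s in support) {
      reg <- region_of(s$block)
      orth <- reg$genes[!is.na(fam[reg$genes]) & fam[reg$genes] == ref_fam]
      if (length(orth) > 0)
        return(call0(1L, "intact",
                     gene_id = best_candidate(orth,
                                              proteomes[[query_species]],
                                              ref_protein, params),
                     block_id = s$block$block_id))
    }
    # scenario 2: region exists, ortholog missing -> scan the best region
    best <- support[[1]]$block
    reg <- region_of(best)
    region_genes <- reg$genes
    span_b <- reg$span
    wnt <- region_sequence(ann_q, genomic[[query_species]], best$chrom_b,
                           region_genes, span_b, rq, config)
    if (is.null(wnt)) {
      warning("no genomic sequence for ", query_species,
              "; scenario-2 locus called absent without scan")
      return(call0(2L, "absent", block_id = best$block_id))
    }
    ps <- pseudogene_scan(ref_protein, wnt, config, params)
    return(call0(2L, ps$locus_state, block_id = best$block_id,
                 evidence = ps$evidence))
  }
  # scenario 3: no collinear block
  orth_all <- names(fam)[!is.na(fam) & fam == ref_fam]
  orth_all <- intersect(orth_all, ann_q$gene_id)
  if (length(orth_all) > 0)
    return(call0(3L, "intact",
                 gene_id = best_candidate(orth_all,
                                          proteomes[[query_species]],
                                          ref_protein, params),
                 unsupported = TRUE))
  if (is.null(genomic[[query_species]]))
    return(call0(3L, "absent"))
  gw <- genomewide_scan(ref_protein, genomic[[query_species]], config, params)
  if (is.null(gw)) return(call0(3L, "absent"))
  ps <- pseudogene_scan(ref_protein, gw, config, params)
  call0(3L, ps$locus_state, evidence = ps$evidence)
}

best_candidate <- function(gene_ids, proteome, ref_protein, params) {
  if (length(gene_ids) == 1 || is.null(proteome)) return(sort(gene_ids)[1])
  sc <- vapply(gene_ids, function(g) {
    p <- proteome[[g]]
    if (is.null(p)) return(-Inf)
    cpp_local_score(toupper(ref_protein), toupper(p), blosum62_az(),
                    params$gap_open, params$gap_extend)
  }, numeric(1))
  gene_ids[order(-sc, gene_ids)][1]
}

# Genomic subsequence of a putative region: bp span of the region's genes
# (or of the anchor span when the region holds no genes), padded by the
# configured window.
region_sequence <- function(ann_q, chrom_seqs, chrom, region_genes, span_b,
                            rq, config) {
  if (is.null(chrom_seqs) || is.null(chrom_seqs[[chrom]])) return(NULL)
  seqlen <- nchar(chrom_seqs[[chrom]])
  sel <- ann_q[ann_q$gene_id %in% region_genes, , drop = FALSE]
  if (nrow(sel) == 0) {
    anchor_genes <- rq$gene_id[rq$chrom == chrom & rq$rank >= span_b[1] &
                                 rq$rank <= span_b[2]]
    sel <- ann_q[ann_q$gene_id %in% anchor_genes, , drop = FALSE]
  }
  if (nrow(sel) == 0) return(NULL)
  lo <- max(1, min(sel$start) - config$window_bp)
  hi <- min(seqlen, max(sel$end) + config$window_bp)
  substring(chrom_seqs[[chrom]], lo, hi)
}

# Best translated hit across all chromosomes; returns a window around it.
genomewide_scan <- function(ref_protein, chrom_seqs, config, params) {
  best <- NULL
  for (cn in names(chrom_seqs)) {
    hits <- translated_hits(toupper(ref_protein), toupper(chrom_seqs[[cn]]),
                            config, params)
    if (nrow(hits) == 0) next
    h <- hits[which.max(hits$score), ]
    if (is.null(best) || h$score > best$score) {
      best <- h
      best$chrom <- cn
      best$chrlen <- nchar(chrom_seqs[[cn]])
    }
  }
  if (is.null(best)) return(NULL)
  # map minus-strand coordinates back to the forward strand
  nt <- c(best$nt_start, best$nt_end)
  if (best$strand == "-") nt <- best$chrlen - rev(nt) + 1
  lo <- max(1, nt[1] - config$window_bp)
  hi <- min(best$chrlen, nt[2] + config$window_bp)
  substring(chrom_seqs[[best$chrom]], lo, hi)
}

#' Build the presence/pseudogene/absence matrix
#'
#' Merges scenario calls from all reference genomes into one cell per
#' (enzyme, species) with precedence intact > pseudogene > absent (synteny
#' support for presence is the strongest evidence class); among calls
#' agreeing on the state, the lowest scenario number is kept.
#'
#' @param calls list of `scenario_call` objects (or a data.frame of them).
#' @param model pathway model (row order).
#' @param species_order column order (e.g. tree tip order).
#' @return character matrix of class `presence_matrix` (rows enzymes,
#'   columns species, cells `"intact"`/`"pseudogene"`/`"absent"`) with
#'   attributes `scenario` (integer matrix) and `calls` (data.frame).
#' @export
build_matrix <- function(calls, model, species_order = NULL) {
  df <- if (is.data.frame(calls)) calls else
    do.call(rbind, lapply(calls, function(x)
      data.frame(reference = x$reference, enzyme = x$enzyme,
                 species = x$species, scenario = x$scenario,
                 locus_state = x$locus_state,
                 synteny_unsupported = isTRUE(x$synteny_unsupported),
                 gene_id = x$gene_id %||% NA_character_,
                 stringsAsFactors = FALSE)))
  enz <- model$steps$enzyme
  sp <- species_order %||% sort(unique(df$species))
  rankstate <- c(intact = 1L, pseudogene = 2L, absent = 3L)
  M <- matrix("absent", length(enz), length(sp), dimnames = list(enz, sp))
  S <- matrix(NA_integer_, length(enz), length(sp), dimnames = list(enz, sp))
  for (e in enz) for (s in sp) {
    sub <- df[df$enzyme == e & df$species == s, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(rankstate[sub$locus_state], sub$scenario), , drop = FALSE]
    M[e, s] <- sub$locus_state[1]
    S[e, s] <- sub$scenario[1]
  }
  structure(M, scenario = S, calls = df, class = c("presence_matrix",
                                                   "matrix"))
}

unclass_matrix <- function(m) {
  attr(m, "scenario") <- NULL
  attr(m, "calls") <- NULL
  unclass(m)
}

#' @export
print.presence_matrix <- function(x, ...) {
  glyph <- c(intact = "P", pseudogene = "\u03a8", absent = "A")
  m <- matrix(glyph[unclass_matrix(x)], nrow(x), ncol(x),
              dimnames = dimnames(x))
  cat("presence_matrix (P intact, \u03a8 pseudogene, A absent):\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Write / read a presence matrix TSV
#'
#' Cells carry the state glyph (`P`, `Ψ`, `A`) plus the scenario digit
#' when known (e.g. `P1`, `A2`).
#' @param mat a `presence_matrix`.
#' @param path TSV path.
#' @export
write_matrix <- function(mat, path) {
  glyph <- c(intact = "P", pseudogene = "\u03a8", absent = "A")
  S <- attr(mat, "scenario")
  cells <- matrix(paste0(glyph[unclass_matrix(mat)],
                         ifelse(is.na(S), "", S)),
                  nrow(mat), ncol(mat), dimnames = dimnames(mat))
  df <- data.frame(enzyme = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- df$enzyme
  state <- c(P = "intact", "\u03a8" = "pseudogene", A = "absent")
  M <- matrix(state[substring(cells, 1, 1)], nrow(cells), ncol(cells),
              dimnames = dimnames(cells))
  S <- matrix(suppressWarnings(as.integer(substring(cells, 2))),
              nrow(cells), ncol(cells), dimnames = dimnames(cells))
  structure(M, scenario = S, calls = NULL,
            class = c("presence_matrix", "matrix"))
}
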