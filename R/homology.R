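# All-vs-all protein similarity search and family clustering.
#
# Alignment is exact affine-gap local alignment (Gotoh) under BLOSUM62 with
# BLAST-default gap costs; significance uses Karlin-Altschul statistics with
# the gapped BLOSUM62 constants, so E-values have BLAST-like semantics (the
# conventional E <= 1e-5 retention filter) without claiming BLAST-identical
# numbers. Families are single-linkage connected components of the filtered
# hit graph.

#' Alignment and hit-filtering parameters
#'
#' @param substitution_matrix currently only `"BLOSUM62"`.
#' @param gap_open,gap_extend affine gap costs (a gap of length L costs
#'   `gap_open + L * gap_extend`); BLAST protein defaults 11/1.
#' @param ka_lambda,ka_K Karlin-Altschul constants for bit-score and E-value
#'   computation; defaults are the gapped BLOSUM62 values (0.267, 0.041).
#' @param evalue_max retention threshold for hits, default `1e-5`.
#' @return list of class `align_params`.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62", gap_open = 11,
                         gap_extend = 1, ka_lambda = 0.267, ka_K = 0.041,
                         evalue_max = 1e-5) {
  if (!identical(substitution_matrix, "BLOSUM62"))
    stop("only BLOSUM62 is supported")
  stopifnot(gap_open > 0, gap_extend > 0, evalue_max > 0,
            ka_lambda > 0, ka_K > 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 ka_lambda = ka_lambda, ka_K = ka_K,
                 evalue_max = evalue_max),
            class = "align_params")
}

#' Optimal local alignment of two proteins
#'
#' Exact Smith-Waterman/Gotoh dynamic programming with affine gaps. The bit
#' score is `(lambda * raw - ln K) / ln 2` and the E-value `m * n * 2^-bit`
#' for sequence lengths `m`, `n`. Identity is computed over all aligned
#' columns (gaps included); query coverage is the aligned fraction of the
#' query.
#'
#' @param a,b protein sequences (single strings; 20-letter alphabet plus X,
#'   which scores 0 against everything).
#' @param params an [align_params()] object.
#' @return list of class `homology_hit` with `raw_score`, `bit_score`,
#'   `e_value`, `identity_pct`, `query_coverage`, 1-based alignment
#'   coordinates and column counts.
#' @export
local_align <- function(a, b, params = align_params()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  assert_protein(a, "query"); assert_protein(b, "subject")
  r <- cpp_local_align(a, b, blosum62_az(), params$gap_open,
                       params$gap_extend)
  bit <- (params$ka_lambda * r$score - log(params$ka_K)) / log(2)
  ev <- nchar(a) * nchar(b) * 2^(-bit)
  structure(list(raw_score = r$score, bit_score = bit, e_value = ev,
                 identity_pct = if (r$ncols > 0) 100 * r$nid / r$ncols else 0,
                 query_coverage = if (r$score > 0)
                   (r$qend - r$qstart + 1) / nchar(a) else 0,
                 qstart = r$qstart, qend = r$qend,
                 sstart = r$sstart, send = r$send,
                 length = r$ncols, mismatch = r$mismatch,
                 gapopen = r$gapopen),
            class = "homology_hit")
}

#' All-vs-all homology hit table
#'
#' Aligns every within- and cross-species protein pair once (unordered pairs
#' deduplicated; the record keeps the lexicographically smaller id as query)
#' and retains hits with E-value at or below the threshold. Output rows are
#' sorted by (query id, subject id). Long sequence pairs sharing no 4-mer
#' are skipped by an exact-word prefilter.
#'
#' @param proteomes named list (one element per species) of named character
#'   vectors of protein sequences. Gene ids must be unique across species.
#' @param params an [align_params()] object.
#' @return data.frame with the 12 standard tabular-search columns (`qseqid`,
#'   `sseqid`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`) plus `raw`, `query_coverage`,
#'   `qspecies`, `sspecies`.
#' @export
build_hit_table <- function(proteomes, params = align_params()) {
  if (!is.list(proteomes) || is.null(names(proteomes)))
    stop("proteomes must be a named list of named sequence vectors")
  empty <- names(proteomes)[vapply(proteomes, length, 1L) == 0]
  if (length(empty) > 0)
    warning("empty proteome(s): ", paste(empty, collapse = ", "))
  ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (anyDuplicated(ids) > 0)
    stop("duplicate gene ids across species: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(unlist(proteomes, use.names = FALSE))
  species <- rep(names(proteomes), vapply(proteomes, length, 1L))
  ord <- order(ids)
  ids <- ids[ord]; seqs <- seqs[ord]; species <- species[ord]
  hits <- cpp_hit_table(ids, seqs, blosum62_az(), params$gap_open,
                        params$gap_extend, params$ka_lambda,
                        log(params$ka_K), params$evalue_max,
                        4L, 30L)
  sp <- setNames(species, ids)
  hits$qspecies <- unname(sp[hits$qseqid])
  hits$sspecies <- unname(sp[hits$sseqid])
  hits[order(hits$qseqid, hits$sseqid), , drop = FALSE]
}

#' Write / read a hit table in 12-column tabular-search format
#' @param hits data.frame from [build_hit_table()].
#' @param path output TSV path.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  extra <- intersect(c("raw", "query_coverage", "qspecies", "sspecies"),
                     names(hits))
  write_tsv(hits[, c(cols, extra)], path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) read_tsv(path)

#' Cluster retained hits into gene families
#'
#' Single-linkage clustering: the families are the connected components of
#' the graph whose edges are hits passing both the identity and the
#' query-coverage threshold. Genes present in the hit table but without a
#' passing edge become singleton families. Family ids are the
#' lexicographically smallest member id.
#'
#' @param hits hit table from [build_hit_table()].
#' @param identity_min minimum percent identity for an edge, default 30.
#' @param coverage_min minimum query coverage for an edge, default 0.5.
#' @param universe optional character vector of all gene ids; genes absent
#'   from the hit table then still receive singleton families.
#' @return data.frame with columns `gene_id`, `family_id`.
#' @export
cluster_families <- function(hits, identity_min = 30, coverage_min = 0.5,
                             universe = NULL) {
  pass <- hits$pident >= identity_min & hits$query_coverage >= coverage_min
  genes <- sort(unique(c(hits$qseqid, hits$sseqid, universe)))
  g <- igraph::graph_from_data_frame(
    hits[pass, c("qseqid", "sseqid"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = genes))
  comp <- igraph::components(g)$membership
  fam <- vapply(split(names(comp), comp), min, character(1))
  data.frame(gene_id = names(comp),
             family_id = unname(fam[as.character(comp)]),
             row.names = NULL, stringsAsFactors = FALSE)[order(names(comp)), ]
}

#' Identify pathway-gene candidates against reference enzymes
#'
#' For each species, aligns every reference enzyme protein against the
#' species proteome and reports genes whose identity and E-value pass the
#' thresholds, ranked by bit score (several hits per enzyme are expected for
#' tandem duplicates).
#'
#' @param proteomes named list of named protein vectors, as in
#'   [build_hit_table()].
#' @param reference_seqs named character vector: enzyme symbol -> reference
#'   protein sequence. Every enzyme must have a reference.
#' @param identity_min minimum percent identity, default 80 (high-confidence
#'   ortholog calls).
#' @param params an [align_params()] object.
#' @return data.frame with columns `species`, `enzyme`, `gene_id`, `pident`,
#'   `bitscore`, `evalue`, `rank` (1 = best per species x enzyme).
#' @export
identify_pathway_genes <- function(proteomes, reference_seqs,
                                   identity_min = 80,
                                   params = align_params()) {
  if (is.null(names(reference_seqs)) || any(names(reference_seqs) == "") ||
      any(!nzchar(reference_seqs)))
    stop("every enzyme needs a named, non-empty reference sequence")
  out <- list()
  for (sp in names(proteomes)) {
    prot <- proteomes[[sp]]
    if (length(prot) == 0) next
    for (enz in names(reference_seqs)) {
      h <- cpp_query_hits(toupper(reference_seqs[[enz]]), names(prot),
                          toupper(unname(prot)), blosum62_az(),
                          params$gap_open, params$gap_extend,
                          params$ka_lambda, log(params$ka_K),
                          params$evalue_max, 4L, 30L)
      h <- h[h$pident >= identity_min, , drop = FALSE]
      if (nrow(h) == 0) next
      h <- h[order(-h$bitscore, h$sseqid), , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        species = sp, enzyme = enz, gene_id = h$sseqid, pident = h$pident,
        bitscore = h$bitscore, evalue = h$evalue, rank = seq_len(nrow(h)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(species = character(), enzyme = character(),
                      gene_id = character(), pident = numeric(),
                      bitscore = numeric(), evalue = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
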