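# Synteny: gene-rank anchors, collinear block chaining, depth ratios.
#
# Anchors address genes by their order (rank) along each chromosome, which
# makes chaining robust to the compressed intergenic scale of simulated
# genomes. Chaining is MCScanX-style dynamic programming per chromosome pair
# and orientation, with greedy best-first extraction; blocks need at least
# `min_block_size` anchors (default 5, the conventional `-s 5`).

#' Build cross-genome anchors from shared families
#'
#' One anchor per cross-genome gene pair sharing a family. Families with
#' more than `copy_cap` members in either genome contribute no anchors
#' (repeat suppression). For self-comparison of a genome pass the same
#' annotation twice; identical gene pairs are then excluded.
#'
#' @param ann_a,ann_b gene annotations: data.frames with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (see [load_workspace()]); gene ranks
#'   are 0-based positions in start order per chromosome.
#' @param families data.frame (`gene_id`, `family_id`) from
#'   [cluster_families()].
#' @param copy_cap anchor-eligibility cap per genome per family, default 20.
#' @return data.frame with columns `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `family_id`, ordered deterministically.
#' @export
build_anchors <- function(ann_a, ann_b, families, copy_cap = 20) {
  fa <- setNames(families$family_id, families$gene_id)
  ra <- gene_ranks(ann_a)
  rb <- gene_ranks(ann_b)
  ra$family_id <- unname(fa[ra$gene_id])
  rb$family_id <- unname(fa[rb$gene_id])
  ra <- ra[!is.na(ra$family_id), ]
  rb <- rb[!is.na(rb$family_id), ]
  over_a <- names(which(table(ra$family_id) > copy_cap))
  over_b <- names(which(table(rb$family_id) > copy_cap))
  drop <- union(over_a, over_b)
  ra <- ra[!ra$family_id %in% drop, ]
  rb <- rb[!rb$family_id %in% drop, ]
  m <- merge(ra, rb, by = "family_id", suffixes = c("_a", "_b"))
  m <- m[m$gene_id_a != m$gene_id_b, , drop = FALSE]
  out <- data.frame(gene_a = m$gene_id_a, gene_b = m$gene_id_b,
                    chrom_a = m$chrom_a, chrom_b = m$chrom_b,
                    rank_a = m$rank_a, rank_b = m$rank_b,
                    family_id = m$family_id, stringsAsFactors = FALSE)
  out[order(out$chrom_a, out$rank_a, out$chrom_b, out$rank_b), , drop = FALSE]
}

# 0-based gene ranks along each chromosome, by start coordinate.
gene_ranks <- function(ann) {
  if (any(is.na(ann$start)) || any(is.na(ann$chrom)))
    stop("gene(s) missing coordinates: ",
         paste(ann$gene_id[is.na(ann$start) | is.na(ann$chrom)],
               collapse = ", "))
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rk <- stats::ave(seq_len(nrow(ann)), ann$chrom, FUN = seq_along) - 1L
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
             rank = as.integer(rk), stringsAsFactors = FALSE)
}

#' Chain anchors into collinear synteny blocks
#'
#' Per chromosome pair and orientation, finds maximum-score chains of
#' anchors by dynamic programming: anchors sorted by `rank_a`, a transition
#' allowed when both rank gaps are at most `max_gap`, chain score
#' `sum(match_score) - gap_penalty * sum(rank gaps)`. Chains are extracted
#' greedily best-first (ties by chromosome pair, then smallest starting
#' `rank_a`), their anchors removed, and chains shorter than
#' `min_block_size` discarded.
#'
#' @param anchors data.frame from [build_anchors()].
#' @param min_block_size minimum anchors per block, default 5.
#' @param max_gap maximum rank gap between consecutive anchors on either
#'   genome, default 25.
#' @param gap_penalty penalty per skipped rank, default 1.
#' @param match_score score per anchor, default 10.
#' @return list of `synteny_block` objects: each a list with `block_id`,
#'   `chrom_a`, `chrom_b`, `orientation` (`"same"`/`"inverted"`), `score`,
#'   and an `anchors` data.frame.
#' @export
chain_anchors <- function(anchors, min_block_size = 5, max_gap = 25,
                          gap_penalty = 1, match_score = 10) {
  blocks <- list()
  if (nrow(anchors) == 0) return(blocks)
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  for (k in sort(unique(key))) {
    sub <- anchors[key == k, , drop = FALSE]
    fwd <- sub; fwd$rb <- fwd$rank_b
    rev <- sub; rev$rb <- -rev$rank_b
    # both orientations compete for the same anchors: extract the best
    # remaining chain of either orientation, remove its anchors, repeat
    avail <- rep(TRUE, nrow(sub))
    repeat {
      if (!any(avail)) break
      ch_f <- best_chain(fwd[avail, , drop = FALSE], max_gap, gap_penalty,
                         match_score)
      ch_r <- best_chain(rev[avail, , drop = FALSE], max_gap, gap_penalty,
                         match_score)
      if (is.null(ch_f) && is.null(ch_r)) break
      take_fwd <- !is.null(ch_f) &&
        (is.null(ch_r) || ch_f$score >= ch_r$score)
      ch <- if (take_fwd) ch_f else ch_r
      orient <- if (take_fwd) "same" else "inverted"
      idx <- which(avail)[ch$idx]
      avail[idx] <- FALSE
      if (length(idx) >= min_block_size) {
        an <- sub[idx, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                         "rank_a", "rank_b", "family_id")]
        an <- an[order(an$rank_a), ]
        blocks[[length(blocks) + 1]] <- structure(
          list(block_id = NA_character_, chrom_a = an$chrom_a[1],
               chrom_b = an$chrom_b[1], orientation = orient,
               score = ch$score, anchors = an),
          class = "synteny_block")
      }
    }
  }
  if (length(blocks) == 0) return(blocks)
  ord <- order(vapply(blocks, function(b) b$chrom_a, ""),
               vapply(blocks, function(b) b$chrom_b, ""),
               -vapply(blocks, function(b) b$score, 0),
               vapply(blocks, function(b) min(b$anchors$rank_a), 0))
  blocks <- blocks[ord]
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- sprintf("b%04d", i)
  blocks
}

# Best single chain by DP over anchors of one chromosome pair/orientation.
# Returns NULL when no anchor exists; ties broken by smallest starting
# rank_a, then smallest rank_b.
best_chain <- function(a, max_gap, gap_penalty, match_score) {
  n <- nrow(a)
  if (n == 0) return(NULL)
  ord <- order(a$rank_a, a$rb)
  a <- a[ord, , drop = FALSE]
  score <- rep(match_score, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ga <- a$rank_a[i] - a$rank_a[j] - 1L
      gb <- a$rb[i] - a$rb[j] - 1L
      if (ga < 0 || gb < 0) next
      if (ga > max_gap || gb > max_gap) next
      cand <- score[j] + match_score - gap_penalty * (ga + gb)
      if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
    }
  }
  besti <- which(score == max(score))
  # deterministic tie-break: chain starting at the smallest rank_a
  starts <- vapply(besti, function(i) {
    while (!is.na(prev[i])) i <- prev[i]
    a$rank_a[i]
  }, 0)
  besti <- besti[order(starts, a$rank_a[besti])][1]
  idx <- besti
  while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
  list(idx = ord[idx], score = max(score))
}

#' Syntenic depth profile and modal ratio
#'
#' Coverage of a target gene is the number of distinct blocks (regions of
#' the query genome) whose anchor rank span on the target side contains the
#' gene's rank. The modal ratio is the mode of nonzero target coverage over
#' the mode of nonzero coverage in the reciprocal direction, e.g. `"2:1"`
#' after a lineage-specific WGD in the query.
#'
#' @param blocks list of blocks from [chain_anchors()] computed with the
#'   target annotation as side A and the query annotation as side B.
#' @param ann_target,ann_query the two gene annotations.
#' @return list of class `depth_profile` with per-gene coverage vectors and
#'   `modal_ratio` (string `"p:q"`, `"0:0"` with warning when no blocks).
#' @export
depth_ratio <- function(blocks, ann_target, ann_query) {
  rt <- gene_ranks(ann_target)
  rq <- gene_ranks(ann_query)
  cov_t <- setNames(integer(nrow(rt)), rt$gene_id)
  cov_q <- setNames(integer(nrow(rq)), rq$gene_id)
  if (length(blocks) == 0) {
    warning("no synteny blocks; depth ratio undefined")
    return(structure(list(coverage_target = cov_t, coverage_query = cov_q,
                          modal_ratio = "0:0"), class = "depth_profile"))
  }
  for (b in blocks) {
    span_a <- range(b$anchors$rank_a)
    span_b <- range(b$anchors$rank_b)
    sel_t <- rt$chrom == b$chrom_a & rt$rank >= span_a[1] & rt$rank <= span_a[2]
    sel_q <- rq$chrom == b$chrom_b & rq$rank >= span_b[1] & rq$rank <= span_b[2]
    cov_t[sel_t] <- cov_t[sel_t] + 1L
    cov_q[sel_q] <- cov_q[sel_q] + 1L
  }
  structure(list(coverage_target = cov_t, coverage_query = cov_q,
                 modal_ratio = paste0(int_mode(cov_t), ":", int_mode(cov_q))),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile: modal ratio", x$modal_ratio, "\n")
  invisible(x)
}

#' Export blocks as a dot-plot table
#'
#' One row per anchor with its block id and orientation; the table is
#' lossless, so [read_dotplot()] reconstructs the block set.
#'
#' @param blocks list of blocks from [chain_anchors()].
#' @param path output TSV path.
#' @export
export_dotplot <- function(blocks, path) {
  rows <- lapply(blocks, function(b) {
    cbind(b$anchors[, c("rank_a", "rank_b")],
          block_id = b$block_id, orientation = b$orientation,
          chrom_a = b$anchors$chrom_a, chrom_b = b$anchors$chrom_b,
          gene_a = b$anchors$gene_a, gene_b = b$anchors$gene_b,
          family_id = b$anchors$family_id, score = b$score)
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(rank_a = integer(), rank_b = integer(),
               block_id = character(), orientation = character(),
               chrom_a = character(), chrom_b = character(),
               gene_a = character(), gene_b = character(),
               family_id = character(), score = numeric())
  write_tsv(df, path)
}

#' @rdname export_dotplot
#' @export
read_dotplot <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0) return(list())
  blocks <- lapply(split(df, df$block_id), function(s) {
    s <- s[order(s$rank_a), ]
    structure(list(block_id = s$block_id[1], chrom_a = as.character(s$chrom_a[1]),
                   chrom_b = as.character(s$chrom_b[1]),
                   orientation = s$orientation[1], score = s$score[1],
                   anchors = data.frame(
                     gene_a = as.character(s$gene_a),
                     gene_b = as.character(s$gene_b),
                     chrom_a = as.character(s$chrom_a),
                     chrom_b = as.character(s$chrom_b),
                     rank_a = s$rank_a, rank_b = s$rank_b,
                     family_id = as.character(s$family_id),
                     stringsAsFactors = FALSE)),
              class = "synteny_block")
  })
  unname(blocks[order(names(blocks))])
}

#' Write / read blocks in a collinearity-style text format
#'
#' Block headers carry id, chromosome pair, orientation and score; one
#' anchor pair per line. Readable back losslessly.
#' @param blocks list of blocks.
#' @param path file path.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# collinearity blocks", con)
  for (b in blocks) {
    writeLines(sprintf("## block %s chrom_a=%s chrom_b=%s orientation=%s score=%g",
                       b$block_id, b$chrom_a, b$chrom_b, b$orientation,
                       b$score), con)
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s", b$anchors$gene_a,
                       b$anchors$gene_b, b$anchors$rank_a, b$anchors$rank_b,
                       b$anchors$family_id), con)
  }
  invisible(path)
}

#' @rdname write_collinearity
#' @export
read_collinearity <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush_cur <- function(cur) {
    if (is.null(cur) || length(cur$rows) == 0) return(NULL)
    an <- do.call(rbind, cur$rows)
    structure(list(block_id = cur$id, chrom_a = cur$ca, chrom_b = cur$cb,
                   orientation = cur$orient, score = cur$score,
                   anchors = an), class = "synteny_block")
  }
  for (ln in lines) {
    if (startsWith(ln, "## block ")) {
      b <- flush_cur(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
      f <- strsplit(sub("^## block ", "", ln), " ")[[1]]
      kv <- strsplit(f[-1], "=")
      vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      cur <- list(id = f[1], ca = vals[["chrom_a"]], cb = vals[["chrom_b"]],
                  orient = vals[["orientation"]],
                  score = as.numeric(vals[["score"]]), rows = list())
    } else if (!startsWith(ln, "#") && nzchar(ln)) {
      f <- strsplit(ln, "\t")[[1]]
      cur$rows[[length(cur$rows) + 1]] <- data.frame(
        gene_a = f[1], gene_b = f[2], chrom_a = cur$ca, chrom_b = cur$cb,
        rank_a = as.integer(f[3]), rank_b = as.integer(f[4]),
        family_id = f[5], stringsAsFactors = FALSE)
    }
  }
  b <- flush_cur(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
  blocks
}
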