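# Shared fixtures and independent brute-force oracles for the test suite.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# Simple evenly-spaced annotation: n genes of 300 bp, 1 kb apart.
make_ann <- function(n, chrom = "c1", prefix = "g", offset = 0) {
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n) + offset),
             chrom = chrom, start = (seq_len(n) - 1) * 1000 + 1,
             end = (seq_len(n) - 1) * 1000 + 300, strand = "+",
             stringsAsFactors = FALSE)
}

# A fast 4-leaf simulation used by several files.
mini_sim <- function(seed = 11, wgd = c(C = 1.0), loss = "D") {
  tr <- ape::read.tree(text = "((A:6,B:6)ab:4,(C:8,D:8)cd:2)r;")
  cfg <- sim_config(seed = seed, n_chromosomes = 2,
                    n_background_genes_per_chrom = 16,
                    loss_rate = 0, pseudogenization_rate = 0,
                    translocation_rate = 0, wgd_branches = wgd,
                    pathway_loss_branches = loss, reference_species = "A")
  generate_dataset(tr, cfg)
}

# The full demonstration clade, generated and analysed once per test run
# and shared between the acceptance checks that need it.
.preset_cache <- new.env(parent = emptyenv())
preset_run <- function() {
  if (!is.null(.preset_cache$res)) return(.preset_cache$res)
  ps <- preset_clade17(seed = 7)
  ds <- generate_dataset(ps$tree, ps$config)
  dir <- file.path(tempdir(), "preset-run-a")
  res <- run_pipeline(as_workspace(ds), dir, overwrite = TRUE)
  .preset_cache$res <- list(ds = ds, dir = dir, res = res)
  .preset_cache$res
}

# --- independent oracles -------------------------------------------------

# Exhaustive local alignment: enumerate every alignment as a series of
# aligned columns separated by affine gap runs; feasible for <=5 residues.
brute_local_score <- function(a, b, S, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  best <- 0
  rec <- function(i, j, sc) {
    best <<- max(best, sc)
    if (i >= m || j >= n) return()
    for (di in 1:(m - i)) for (dj in 1:(n - j)) {
      g <- 0
      if (di > 1) g <- g + open + (di - 1) * ext
      if (dj > 1) g <- g + open + (dj - 1) * ext
      rec(i + di, j + dj, sc - g + S[A[i + di], B[j + dj]])
    }
  }
  for (i in seq_len(m)) for (j in seq_len(n))
    rec(i, j, S[A[i], B[j]])
  best
}

# Exhaustive best chain over anchor subsets (strictly increasing in both
# ranks, rank gaps bounded); returns the maximal score or -Inf.
brute_best_chain_score <- function(ra, rb, max_gap, gap_penalty,
                                   match_score) {
  n <- length(ra)
  if (n == 0) return(-Inf)
  pow <- 2^(seq_len(n) - 1)
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, pow) > 0)
    o <- order(ra[idx])
    sra <- ra[idx][o]; srb <- rb[idx][o]
    if (length(idx) > 1) {
      if (any(diff(sra) < 1) || any(diff(srb) < 1)) next
      ga <- diff(sra) - 1; gb <- diff(srb) - 1
      if (any(ga > max_gap) || any(gb > max_gap)) next
      sc <- match_score * length(idx) - gap_penalty * sum(ga + gb)
    } else sc <- match_score
    best <- max(best, sc)
  }
  best
}

# Exhaustive Dollo: minimal 1->0 transitions over all single-gain
# labelings (root fixed at 1 when any leaf carries the trait, edges may
# never go 0 -> 1).
brute_dollo_count <- function(tree, traits) {
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  leaf_state <- as.integer(traits[tree$tip.label])
  if (all(leaf_state == 0)) return(0L)
  bestloss <- Inf
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask)[seq_len(nnode)])
    state <- c(leaf_state, internal)
    if (state[ntip + 1] != 1) next  # gain fixed at root
    ok <- TRUE; losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- state[tree$edge[e, 1]]; ch <- state[tree$edge[e, 2]]
      if (p == 0 && ch == 1) { ok <- FALSE; break }
      if (p == 1 && ch == 0) losses <- losses + 1L
    }
    if (ok) bestloss <- min(bestloss, losses)
  }
  as.integer(bestloss)
}

# Independent NG86 pathway enumeration (recursive, distinct from the
# package's permutation-table construction).
oracle_ng86_pair <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  aa_of <- function(x) unname(gc_tab[[x]])
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  paths <- list()
  walk <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(sd, nd, through_stop)
      return()
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- n2[p]
      cs <- paste(cur, collapse = ""); ns <- paste(nxt, collapse = "")
      syn <- aa_of(cs) == aa_of(ns) && aa_of(ns) != "*"
      walk(nxt, setdiff(remaining, p),
           sd + as.integer(syn), nd + as.integer(!syn),
           through_stop || aa_of(ns) == "*")
    }
  }
  d <- which(n1 != n2)
  if (length(d) == 0) return(c(0, 0))
  walk(n1, d, 0L, 0L, FALSE)
  M <- do.call(rbind, paths)
  keep <- M[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(M))
  colMeans(M[keep, 1:2, drop = FALSE])
}

# Exhaustive marginal posteriors on a rooted 3-taxon tree ((A,B)u,C)r
# under the Poisson amino-acid model, by summation over both ancestral
# states.
brute_marginal3 <- function(t1, t2, t3, t4, colABC) {
  P <- function(t) {
    e <- exp(-20 * t / 19)
    M <- matrix((1 - e) / 20, 20, 20)
    diag(M) <- 1 / 20 + 19 * e / 20
    M
  }
  alpha <- AA20
  ia <- match(colABC[1], alpha); ib <- match(colABC[2], alpha)
  ic <- match(colABC[3], alpha)
  P1 <- P(t1); P2 <- P(t2); P3 <- P(t3); P4 <- P(t4)
  joint <- matrix(0, 20, 20)  # root x internal
  for (r in 1:20) for (u in 1:20)
    joint[r, u] <- (1 / 20) * P3[r, u] * P1[u, ia] * P2[u, ib] * P4[r, ic]
  list(root = rowSums(joint) / sum(joint),
       internal = colSums(joint) / sum(joint),
       lik = sum(joint))
}

# Branches (child labels) on the path from the root to a leaf.
path_branches <- function(tree, leaf) {
  tree <- stats::reorder(tree, "cladewise")
  lab <- c(tree$tip.label, tree$node.label)
  node <- match(leaf, lab)
  out <- character()
  repeat {
    e <- match(node, tree$edge[, 2])
    if (is.na(e)) break
    out <- c(out, lab[node])
    node <- tree$edge[e, 1]
  }
  out
}
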