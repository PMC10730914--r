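# Clade simulator: genomes with known evolutionary event histories.
#
# An ancestral genome (single-copy background families plus the 12 pathway
# genes at fixed loci) evolves along a rooted, Mya-scaled tree. Coding
# sequences evolve by a per-codon Gillespie process whose synonymous and
# nonsynonymous rates use the same site partition as the NG86 estimator, so
# simulated divergences are recoverable by construction, not by shared code
# paths (the estimator works from observed sequence pairs only).
#
# Structural events: whole-genome duplication/triplication on flagged
# branches (duplicate every chromosome, then drop 1 - retention of the
# duplicated genes), tandem duplication, translocation, pseudogenization
# (5' exon truncation or premature stop; the residual stays at the locus,
# outside the annotation but inside the genomic sequence) and outright gene
# loss. Forced pathway-loss branches knock out every copy of the five
# pathway-exclusive genes. Everything is driven by one seeded RNG stream.

#' Simulator configuration
#'
#' Event rates are per gene per million years; `syn_rate`/`nonsyn_rate` are
#' substitutions per synonymous/nonsynonymous site per year. Branch ids are
#' node labels of the child end of a branch (tip labels for terminal
#' branches).
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes,n_background_genes_per_chrom ancestral genome shape.
#' @param gene_length_bp coding length of every gene (multiple of 3).
#' @param intergenic_bp spacer between loci; the default 2 kb makes a 100 kb
#'   window span roughly 20 genes per side.
#' @param loss_rate,pseudogenization_rate,translocation_rate Poisson event
#'   rates applied to every gene on every branch.
#' @param tandem_dup_targets named character vector enzyme symbol -> branch
#'   id; the gene is expanded to `tandem_copies` adjacent copies there.
#' @param tandem_copies total tandem copies created, default 4.
#' @param wgd_branches named numeric vector branch id -> retention fraction
#'   in (0, 1]: whole-genome duplication at the start of that branch.
#' @param wgt_branches same, but triplication.
#' @param wgt_at_root apply a triplication to the ancestral genome itself
#'   (before the first split), retention `wgt_retention`.
#' @param wgt_retention retention used by `wgt_at_root`, default 0.2.
#' @param syn_rate,nonsyn_rate molecular clock; defaults 5.6e-9 and 1.4e-9.
#' @param pathway_loss_branches branch ids on which every copy of the five
#'   pathway-exclusive genes is forced to pseudogene-or-absent.
#' @param translocation_targets named character vector enzyme symbol ->
#'   branch id for scripted translocations.
#' @param pseudogenization_mode `"truncate-5prime-2-exons"` (default; keeps
#'   the 3'-most exon fraction of the coding sequence as the residual) or
#'   `"premature-stop"` (full-length residual with an internal stop).
#' @param multi_copy_fraction fraction of background families present twice
#'   in the ancestor (anchor-filter stress), default 0.
#' @param reference_species optional character vector marking the species
#'   to be used as annotation references downstream.
#' @param ref_proteome_node internal node label at which the reference
#'   enzyme proteins are snapshotted (the stand-in for a functionally
#'   characterized close relative); `NULL` takes the ancestral (root)
#'   proteins.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chromosomes = 3,
                       n_background_genes_per_chrom = 30,
                       gene_length_bp = 300, intergenic_bp = 2000,
                       loss_rate = 0.002, pseudogenization_rate = 0.002,
                       translocation_rate = 0.001,
                       tandem_dup_targets = character(), tandem_copies = 4,
                       wgd_branches = numeric(), wgt_branches = numeric(),
                       wgt_at_root = FALSE, wgt_retention = 0.2,
                       syn_rate = 5.6e-9, nonsyn_rate = 1.4e-9,
                       pathway_loss_branches = character(),
                       translocation_targets = character(),
                       pseudogenization_mode = "truncate-5prime-2-exons",
                       multi_copy_fraction = 0,
                       reference_species = NULL,
                       ref_proteome_node = NULL) {
  stopifnot(gene_length_bp %% 3 == 0, gene_length_bp >= 90,
            intergenic_bp >= 0,
            loss_rate >= 0, pseudogenization_rate >= 0,
            translocation_rate >= 0, syn_rate >= 0, nonsyn_rate >= 0,
            multi_copy_fraction >= 0, multi_copy_fraction <= 1)
  ret <- c(wgd_branches, wgt_branches, if (wgt_at_root) wgt_retention)
  if (length(ret) > 0 && (any(ret <= 0) || any(ret > 1)))
    stop("retention fractions must be in (0, 1]")
  if (!pseudogenization_mode %in% c("truncate-5prime-2-exons",
                                    "premature-stop"))
    stop("unknown pseudogenization_mode")
  structure(as.list(environment()), class = "sim_config")
}

#' The bundled 17-species demonstration clade
#'
#' A rooted ultrametric tree (Mya) with two outgroup species and a
#' 15-species ingroup mirroring the analysis situation: a shared
#' triplication on the ingroup stem, lineage-specific WGDs on two terminal
#' branches (`wgdA`, 13.41 Mya; `wgdM`, 11 Mya), a fourfold tandem
#' expansion of TRI on one producer branch, a PPAR translocation on one
#' non-producer branch, and three forced pathway losses (branch `lossA`
#' covering leaves n1-n3, plus terminals `n4` and `n5`), leaving 12
#' producer and 5 non-producer species. Background event rates are zero in
#' the preset so the seeded ground truth is exact; the generic generator
#' supports Poisson event rates.
#'
#' @param seed RNG seed, default 7.
#' @return list with elements `tree` (phylo) and `config` (`sim_config`).
#' @export
preset_clade17 <- function(seed = 7) {
  nwk <- paste0(
    "((out1:30,out2:30)outg:30,",
    "(((n1:5,(n2:3,n3:3)na1:2)lossA:10,",
    "((p01:6,p02:6)pa1:4,(p03:7,p04:7)pa2:3)pa0:5)a0:12,",
    "((((p05:4,p06:4)pb1:9.41,wgdA:13.41)pb0:1.59,n4:15)b1:6,",
    "(((p08:5,p09:5)pb3:6,wgdM:11)pb4:2,n5:13)b2:8)b0:6)ing:33)root;")
  tree <- ape::read.tree(text = nwk)
  config <- sim_config(
    seed = seed,
    loss_rate = 0, pseudogenization_rate = 0, translocation_rate = 0,
    tandem_dup_targets = c(TRI = "p01"), tandem_copies = 4,
    wgd_branches = c(wgdA = 0.75, wgdM = 0.75),
    wgt_branches = c(ing = 0.2),
    pathway_loss_branches = c("lossA", "n4", "n5"),
    translocation_targets = c(PPAR = "n4"),
    reference_species = c("p01", "wgdA", "p08"),
    ref_proteome_node = "ing")
  list(tree = tree, config = config)
}

# ---------------------------------------------------------------------------
# Sequence evolution

#' Evolve a coding sequence along a branch
#'
#' Per-codon Gillespie simulation: each codon substitutes with total rate
#' `r_s * s + r_n * n`, where `s` and `n` are its NG86 synonymous and
#' nonsynonymous neighbor counts (per-site scaling: each synonymous site
#' accrues `r_s` substitutions per year); mutations to stop codons are
#' rejected. Multiple hits per site are possible, matching the
#' Jukes-Cantor-corrected estimator.
#'
#' @param cds coding sequence (string over ACGT, length divisible by 3, no
#'   internal stop codons).
#' @param branch_my branch length in million years.
#' @param r_s,r_n synonymous / nonsynonymous rates per site per year.
#' @return evolved coding sequence (same length).
#' @export
evolve_cds <- function(cds, branch_my, r_s, r_n) {
  cods <- split_codons(toupper(cds))
  u <- codon_universe()
  idx <- match(cods, u$sense)
  if (anyNA(idx))
    stop("input contains a stop codon or non-ACGT characters")
  if (branch_my == 0) return(cds)
  Tyr <- branch_my * 1e6
  nb <- codon_neighbors()
  rates <- codon_total_rates(r_s, r_n)
  lam <- rates[idx]
  t1 <- ifelse(lam > 0, rexp(length(cods), pmax(lam, 1e-300)), Inf)
  hot <- which(t1 < Tyr)
  for (i in hot) {
    tcur <- t1[i]; cod <- cods[i]
    repeat {
      nbl <- nb[[cod]]
      w <- ifelse(nbl$syn, r_s, r_n)
      if (sum(w) <= 0) break
      cod <- sample(nbl$to, 1, prob = w)
      lam_i <- rates[[cod]]
      if (lam_i <= 0) break
      tcur <- tcur + rexp(1, lam_i)
      if (tcur >= Tyr) break
    }
    cods[i] <- cod
  }
  paste(cods, collapse = "")
}

codon_total_rates <- function(r_s, r_n) {
  key <- paste0("rates_", r_s, "_", r_n)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  nb <- codon_neighbors()
  rates <- vapply(nb, function(x)
    (r_s * sum(x$syn) + r_n * sum(!x$syn)) / 3, numeric(1))
  .pkg_cache[[key]] <- rates
  rates
}

# Neutral substitution of non-coding residual sequence.
neutral_evolve <- function(seq, branch_my, r) {
  if (nchar(seq) == 0 || branch_my == 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  p <- 1 - exp(-r * branch_my * 1e6)
  hit <- which(runif(length(s)) < p)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}

random_cds <- function(n_codons) {
  u <- codon_universe()
  body <- sample(setdiff(u$sense, "ATG"), n_codons - 1, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", x))))
}

# ---------------------------------------------------------------------------
# Genome representation and events

new_locus <- function(env, fam, symbol, cds, exon_frac, strand) {
  env$uid <- env$uid + 1L
  list(uid = env$uid, fam = fam, symbol = symbol, type = "gene",
       cds = cds, seq_res = NULL, exon_frac = exon_frac, strand = strand,
       dup_origin = NA_integer_, dup_node = NA_character_)
}

log_event <- function(env, branch, event, locus, detail = "") {
  env$events[[length(env$events) + 1]] <- data.frame(
    branch = branch, event = event, uid = locus$uid,
    symbol = locus$symbol %||% NA_character_, family = locus$fam,
    detail = detail, stringsAsFactors = FALSE)
}

build_ancestor <- function(env, config, model) {
  n_ch <- config$n_chromosomes
  n_bg <- config$n_background_genes_per_chrom
  n_cod <- config$gene_length_bp / 3
  genome <- list()
  symbols <- model$steps$enzyme
  # pathway gene placement: round-robin over chromosomes, interior slots
  path_chrom <- ((seq_along(symbols) - 1) %% n_ch) + 1
  for (ci in seq_len(n_ch)) {
    loci <- list()
    for (g in seq_len(n_bg)) {
      fam <- sprintf("bg_c%d_%02d", ci, g)
      strand <- sample(c("+", "-"), 1, prob = c(0.7, 0.3))
      loci[[length(loci) + 1]] <-
        new_locus(env, fam, NA_character_, random_cds(n_cod), 1, strand)
    }
    syms <- symbols[path_chrom == ci]
    slots <- round(seq(4, n_bg - 3, length.out = length(syms) + 2))
    slots <- slots[seq_along(syms) + 1]
    for (k in seq_along(syms)) {
      pl <- new_locus(env, paste0("pw_", syms[k]), syms[k],
                      random_cds(n_cod), c(0.3, 0.3, 0.4), "+")
      loci <- append(loci, list(pl), after = slots[k] + k - 1)
    }
    genome[[paste0("chr", ci)]] <- loci
  }
  if (config$multi_copy_fraction > 0) {
    bg <- unlist(lapply(genome, function(ch)
      Filter(function(l) is.na(l$symbol), ch)), recursive = FALSE)
    n_dup <- round(config$multi_copy_fraction * length(bg))
    if (n_dup > 0) {
      pick <- sample(seq_along(bg), n_dup)
      for (l in bg[pick]) {
        cp <- new_locus(env, l$fam, l$symbol, l$cds, l$exon_frac, l$strand)
        ch <- sample(names(genome), 1)
        pos <- sample(0:length(genome[[ch]]), 1)
        genome[[ch]] <- append(genome[[ch]], list(cp), after = pos)
      }
    }
  }
  genome
}

# Polyploidy with block-wise fractionation: each duplicated chromosome
# retains one contiguous segment holding `retention` of its genes (the
# pattern large-scale fractionation leaves behind); retention 1 keeps the
# whole chromosome.
apply_polyploidy <- function(env, genome, retention, ploidy, branch, tag) {
  new_chrs <- list()
  for (cn in names(genome)) {
    genes_here <- which(vapply(genome[[cn]], function(l) l$type == "gene",
                               logical(1)))
    for (k in seq_len(ploidy - 1)) {
      n <- length(genes_here)
      if (n == 0) next
      seg_len <- max(1, round(retention * n))
      seg_start <- sample.int(n - seg_len + 1, 1)
      keep_pos <- genes_here[seq(seg_start, seg_start + seg_len - 1)]
      kept <- list()
      for (pos in keep_pos) {
        l <- genome[[cn]][[pos]]
        cp <- new_locus(env, l$fam, l$symbol, l$cds, l$exon_frac, l$strand)
        cp$dup_origin <- l$uid
        cp$dup_node <- branch
        log_event(env, branch, "wgd_copy", cp, detail = paste0("of_", l$uid))
        kept[[length(kept) + 1]] <- cp
      }
      if (length(kept) > 0) new_chrs[[paste0(cn, "_", tag, k)]] <- kept
    }
  }
  c(genome, new_chrs)
}

find_loci <- function(genome, symbol, type = "gene") {
  hits <- list()
  for (cn in names(genome))
    for (i in seq_along(genome[[cn]])) {
      l <- genome[[cn]][[i]]
      if (!is.na(l$symbol) && l$symbol == symbol && l$type == type)
        hits[[length(hits) + 1]] <- list(chrom = cn, idx = i)
    }
  hits
}

make_residual <- function(locus, mode) {
  cds <- locus$cds
  n <- nchar(cds)
  if (mode == "truncate-5prime-2-exons" && length(locus$exon_frac) >= 3) {
    drop_frac <- sum(locus$exon_frac[1:2])
    from <- 3 * floor(drop_frac * n / 3) + 1
    res <- substring(cds, from, n)
  } else if (mode == "truncate-5prime-2-exons") {
    # single-exon background gene: keep the 3' 40%
    from <- 3 * floor(0.6 * n / 3) + 1
    res <- substring(cds, from, n)
  } else {
    mid <- 3 * floor(n / 6)
    res <- paste0(substring(cds, 1, mid), "TAA", substring(cds, mid + 4, n))
  }
  locus$type <- "residual"
  locus$seq_res <- res
  locus$cds <- NULL
  locus
}

pseudogenize_at <- function(env, genome, pos, branch, mode, event) {
  l <- genome[[pos$chrom]][[pos$idx]]
  l2 <- make_residual(l, mode)
  genome[[pos$chrom]][[pos$idx]] <- l2
  log_event(env, branch, event, l2, detail = mode)
  genome
}

delete_at <- function(env, genome, pos, branch, event) {
  l <- genome[[pos$chrom]][[pos$idx]]
  log_event(env, branch, event, l)
  genome[[pos$chrom]][[pos$idx]] <- NULL
  genome
}

translocate_at <- function(env, genome, pos, branch, event) {
  l <- genome[[pos$chrom]][[pos$idx]]
  genome[[pos$chrom]][[pos$idx]] <- NULL
  dest <- sample(names(genome), 1)
  at <- sample(0:length(genome[[dest]]), 1)
  genome[[dest]] <- append(genome[[dest]], list(l), after = at)
  log_event(env, branch, event, l, detail = paste0("to_", dest))
  genome
}

erode_and_translocate <- function(env, genome, sym, branch, radius = 21) {
  hits <- find_loci(genome, sym)
  if (length(hits) == 0) return(genome)
  h <- hits[[1]]
  loci <- genome[[h$chrom]]
  nb_idx <- seq(max(1, h$idx - radius), min(length(loci), h$idx + radius))
  nb <- loci[nb_idx]
  is_bg_gene <- vapply(nb, function(l) l$type == "gene" && is.na(l$symbol),
                       logical(1))
  erode_fams <- unique(vapply(nb[is_bg_gene], `[[`, "", "fam"))
  move_uids <- vapply(Filter(function(l) l$type == "gene" &&
                               !is.na(l$symbol), nb), `[[`, 0L, "uid")
  # every copy of the eroded background families disappears genome-wide
  for (cn in names(genome)) {
    keep <- vapply(genome[[cn]], function(l)
      !(l$type == "gene" && is.na(l$symbol) && l$fam %in% erode_fams),
      logical(1))
    for (l in genome[[cn]][!keep])
      log_event(env, branch, "loss", l, detail = "synteny_erosion")
    genome[[cn]] <- genome[[cn]][keep]
  }
  # scatter the focal gene and any pathway genes caught in the region
  for (u in move_uids) {
    pos <- NULL
    for (cn in names(genome)) {
      w <- which(vapply(genome[[cn]], function(l) l$uid == u, logical(1)))
      if (length(w) > 0) { pos <- list(chrom = cn, idx = w[1]); break }
    }
    if (!is.null(pos))
      genome <- translocate_at(env, genome, pos, branch, "translocation")
  }
  genome
}

has_full_pathway <- function(genome, symbols) {
  present <- unlist(lapply(genome, function(ch)
    vapply(ch, function(l)
      if (l$type == "gene" && !is.na(l$symbol)) l$symbol else NA_character_,
      character(1))))
  all(symbols %in% present)
}

evolve_branch <- function(env, genome, branch, t_my, config, hs_symbols) {
  # 1. polyploidy at branch start
  if (branch %in% names(config$wgd_branches))
    genome <- apply_polyploidy(env, genome, config$wgd_branches[[branch]],
                               2, branch, paste0("w", branch))
  if (branch %in% names(config$wgt_branches))
    genome <- apply_polyploidy(env, genome, config$wgt_branches[[branch]],
                               3, branch, paste0("t", branch))
  # 2. scripted tandem duplications
  for (sym in names(config$tandem_dup_targets)) {
    if (config$tandem_dup_targets[[sym]] != branch) next
    hits <- find_loci(genome, sym)
    if (length(hits) == 0) next
    h <- hits[[1]]
    l <- genome[[h$chrom]][[h$idx]]
    for (k in seq_len(config$tandem_copies - 1)) {
      cp <- new_locus(env, l$fam, l$symbol, l$cds, l$exon_frac, l$strand)
      cp$dup_origin <- l$uid; cp$dup_node <- branch
      genome[[h$chrom]] <- append(genome[[h$chrom]], list(cp),
                                  after = h$idx + k - 1)
      log_event(env, branch, "tandem_copy", cp, detail = paste0("of_", l$uid))
    }
  }
  # 3. forced whole-pathway loss
  if (branch %in% config$pathway_loss_branches) {
    for (sym in hs_symbols) {
      mode <- sample(c("pseudogene", "absent"), 1)
      repeat {
        hits <- find_loci(genome, sym)
        if (length(hits) == 0) break
        if (mode == "pseudogene") {
          genome <- pseudogenize_at(env, genome, hits[[1]], branch,
                                    config$pseudogenization_mode,
                                    "pathway_loss_pseudo")
        } else {
          genome <- delete_at(env, genome, hits[[1]], branch,
                              "pathway_loss_absent")
        }
      }
    }
  }
  # 4. scripted translocations with synteny erosion: the gene moves to a
  # random locus and its syntenic context is erased (the background
  # families flanking it lose every copy in this genome; neighboring
  # pathway genes are scattered as well), so no collinear block can place
  # the gene -- the situation behind a scenario-3 call downstream.
  for (sym in names(config$translocation_targets)) {
    if (config$translocation_targets[[sym]] != branch) next
    genome <- erode_and_translocate(env, genome, sym, branch)
  }
  # 5. stochastic per-gene events
  p_loss <- 1 - exp(-config$loss_rate * t_my)
  p_pse <- 1 - exp(-config$pseudogenization_rate * t_my)
  p_tra <- 1 - exp(-config$translocation_rate * t_my)
  if (p_loss + p_pse + p_tra > 0) {
    for (cn in names(genome)) {
      i <- 1
      while (i <= length(genome[[cn]])) {
        l <- genome[[cn]][[i]]
        if (l$type == "gene") {
          u <- runif(3)
          if (u[1] < p_loss) {
            genome <- delete_at(env, genome, list(chrom = cn, idx = i),
                                branch, "loss")
            next
          } else if (u[2] < p_pse) {
            genome <- pseudogenize_at(env, genome, list(chrom = cn, idx = i),
                                      branch, config$pseudogenization_mode,
                                      "pseudogenization")
          } else if (u[3] < p_tra) {
            genome <- translocate_at(env, genome, list(chrom = cn, idx = i),
                                     branch, "translocation")
            next
          }
        }
        i <- i + 1
      }
    }
  }
  # 6. sequence evolution over the branch
  for (cn in names(genome)) {
    for (i in seq_along(genome[[cn]])) {
      l <- genome[[cn]][[i]]
      if (l$type == "gene") {
        genome[[cn]][[i]]$cds <- evolve_cds(l$cds, t_my, config$syn_rate,
                                            config$nonsyn_rate)
      } else {
        genome[[cn]][[i]]$seq_res <- neutral_evolve(l$seq_res, t_my,
                                                    config$syn_rate)
      }
    }
  }
  genome
}

# ---------------------------------------------------------------------------
# Dataset generation

#' Generate a synthetic clade dataset
#'
#' Evolves an ancestral genome along `tree` under `config` and returns
#' per-leaf annotations, sequences and the full ground truth. Deterministic
#' for a fixed seed.
#'
#' @param tree rooted `phylo` (or newick string) with branch lengths in
#'   million years; at least 3 leaves.
#' @param config a [sim_config()].
#' @param model pathway model, default [load_pathway()].
#' @return object of class `sim_dataset`: `leaves` (per species: `ann`
#'   data.frame, `cds`/`protein` named vectors, `genomic` named per-chrom
#'   vector, `residuals` data.frame), `truth` (`scenario` matrix,
#'   `loss_edges`, `wgd_pairs`, `event_log`, `families`, `phenotype`),
#'   `pathway_refs` (ancestral enzyme proteins), `tree`, `config`, `model`.
#' @export
generate_dataset <- function(tree, config = sim_config(),
                             model = load_pathway()) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (length(tree$tip.label) < 3) stop("tree must have at least 3 leaves")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("tree must have positive branch lengths")
  tree <- stats::reorder(tree, "cladewise")
  tree <- label_nodes(tree)
  lab <- c(tree$tip.label, tree$node.label)
  branch_ids <- lab[tree$edge[, 2]]
  refd <- c(names(config$wgd_branches), names(config$wgt_branches),
            config$pathway_loss_branches,
            unname(config$tandem_dup_targets),
            unname(config$translocation_targets),
            config$ref_proteome_node)
  bad <- setdiff(refd, branch_ids)
  if (length(bad) > 0)
    stop("config refers to branch id(s) not in tree: ",
         paste(bad, collapse = ", "))
  set.seed(config$seed)
  env <- new.env(parent = emptyenv())
  env$uid <- 0L
  env$events <- list()
  env$loss_edges <- character()
  env$leaves <- list()
  hs_symbols <- hs_exclusive_steps(model)$enzyme
  symbols <- model$steps$enzyme
  ancestor <- build_ancestor(env, config, model)
  if (config$wgt_at_root)
    ancestor <- apply_polyploidy(env, ancestor, config$wgt_retention, 3,
                                 lab[length(tree$tip.label) + 1L], "twgt0")
  env$pathway_refs <- pathway_ref_proteins(ancestor, symbols)
  ntip <- length(tree$tip.label)
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  recurse <- function(node, genome, functional) {
    for (e in children_of[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      branch <- lab[child]
      g2 <- evolve_branch(env, genome, branch, tree$edge.length[e], config,
                          hs_symbols)
      f2 <- has_full_pathway(g2, symbols)
      if (functional && !f2)
        env$loss_edges <- c(env$loss_edges, branch)
      if (child <= ntip) {
        env$leaves[[lab[child]]] <- finalize_leaf(env, lab[child], g2, config)
      } else {
        if (identical(lab[child], config$ref_proteome_node))
          env$pathway_refs <- pathway_ref_proteins(g2, symbols)
        recurse(child, g2, f2)
      }
    }
  }
  root <- ntip + 1L
  recurse(root, ancestor, has_full_pathway(ancestor, symbols))
  truth <- build_truth(env, tree, config, model)
  structure(list(leaves = env$leaves[tree$tip.label], truth = truth,
                 pathway_refs = env$pathway_refs, tree = tree,
                 config = config, model = model,
                 reference_species = config$reference_species %||%
                   tree$tip.label[1]),
            class = "sim_dataset")
}

pathway_ref_proteins <- function(genome, symbols) {
  refs <- setNames(character(length(symbols)), symbols)
  for (cn in names(genome))
    for (l in genome[[cn]])
      if (l$type == "gene" && !is.na(l$symbol) && refs[[l$symbol]] == "")
        refs[[l$symbol]] <- translate_cds(l$cds)
  refs
}

translate_cds <- function(cds) translate_fast(cds)

finalize_leaf <- function(env, leaf, genome, config) {
  ann <- list(); cds <- character(); residuals <- list()
  genomic <- character(); fam <- character(); uid_of <- character()
  sym <- character()
  gi <- 0L; ri <- 0L
  # chromosomes in lexicographic order, matching annotation read-back
  for (cn in sort(names(genome))) {
    pos <- 0L
    pieces <- character()
    for (l in genome[[cn]]) {
      spacer <- random_dna(config$intergenic_bp)
      locus_seq <- if (l$type == "gene") l$cds else l$seq_res
      if (l$strand == "-") locus_seq <- revcomp(locus_seq)
      start <- pos + config$intergenic_bp + 1L
      end <- start + nchar(locus_seq) - 1L
      if (l$type == "gene") {
        gi <- gi + 1L
        gid <- sprintf("%s_g%04d", leaf, gi)
        ann[[length(ann) + 1]] <- data.frame(
          gene_id = gid, chrom = cn, start = start, end = end,
          strand = l$strand, stringsAsFactors = FALSE)
        cds[[gid]] <- l$cds
        fam[[gid]] <- l$fam
        uid_of[[gid]] <- as.character(l$uid)
        sym[[gid]] <- l$symbol %||% NA_character_
      } else {
        ri <- ri + 1L
        residuals[[length(residuals) + 1]] <- data.frame(
          residual_id = sprintf("%s_ps%03d", leaf, ri), chrom = cn,
          start = start, end = end, strand = l$strand,
          symbol = l$symbol %||% NA_character_, family = l$fam,
          stringsAsFactors = FALSE)
      }
      pieces <- c(pieces, spacer, locus_seq)
      pos <- end
    }
    pieces <- c(pieces, random_dna(config$intergenic_bp))
    genomic[[cn]] <- paste(pieces, collapse = "")
  }
  ann <- do.call(rbind, ann)
  prot <- vapply(cds, translate_cds, character(1))
  residuals <- if (length(residuals) > 0) do.call(rbind, residuals) else
    data.frame(residual_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               symbol = character(), family = character(),
               stringsAsFactors = FALSE)
  list(ann = ann, cds = cds, protein = prot, genomic = genomic,
       residuals = residuals, family = fam, uid = uid_of, symbol = sym)
}

build_truth <- function(env, tree, config, model) {
  leaves <- env$leaves
  symbols <- model$steps$enzyme
  scen <- matrix("absent", nrow = length(symbols), ncol = length(leaves),
                 dimnames = list(symbols, names(leaves)))
  for (lf in names(leaves)) {
    lv <- leaves[[lf]]
    for (s in symbols) {
      if (any(!is.na(lv$symbol) & lv$symbol == s)) scen[s, lf] <- "intact"
      else if (any(!is.na(lv$residuals$symbol) & lv$residuals$symbol == s))
        scen[s, lf] <- "pseudogene"
    }
  }
  phen <- vapply(colnames(scen), function(lf)
    as.integer(producer_phenotype(model, setNames(scen[, lf], rownames(scen)))),
    integer(1))
  events <- if (length(env$events) > 0) do.call(rbind, env$events) else
    data.frame(branch = character(), event = character(), uid = integer(),
               symbol = character(), family = character(),
               detail = character(), stringsAsFactors = FALSE)
  fams <- do.call(rbind, lapply(names(leaves), function(lf)
    data.frame(gene_id = names(leaves[[lf]]$family),
               family_id = unname(leaves[[lf]]$family), species = lf,
               symbol = unname(leaves[[lf]]$symbol),
               stringsAsFactors = FALSE)))
  wgd_pairs <- build_wgd_pairs(env, tree, config)
  list(scenario = scen, phenotype = phen,
       loss_edges = sort(unique(env$loss_edges)),
       event_log = events, families = fams, wgd_pairs = wgd_pairs)
}

build_wgd_pairs <- function(env, tree, config) {
  lab <- c(tree$tip.label, tree$node.label)
  depth <- ape::node.depth.edgelength(tree)
  names(depth) <- lab
  max_d <- max(depth[tree$tip.label])
  events <- if (length(env$events) > 0) do.call(rbind, env$events) else NULL
  out <- list()
  if (is.null(events)) events <- data.frame()
  wgd_ev <- if (nrow(events) > 0)
    events[events$event %in% c("wgd_copy", "tandem_copy"), , drop = FALSE]
  else events
  if (nrow(wgd_ev) > 0)
    wgd_ev$origin <- as.integer(sub("^of_", "", wgd_ev$detail))
  for (lf in names(env$leaves)) {
    lv <- env$leaves[[lf]]
    uid2gene <- setNames(names(lv$uid), unname(lv$uid))
    if (nrow(wgd_ev) == 0) next
    for (k in seq_len(nrow(wgd_ev))) {
      a <- unname(uid2gene[as.character(wgd_ev$uid[k])])
      b <- unname(uid2gene[as.character(wgd_ev$origin[k])])
      if (is.na(a) || is.na(b)) next
      br <- wgd_ev$branch[k]
      parent_node <- lab[tree$edge[match(match(br, lab), tree$edge[, 2]), 1]]
      age <- max_d - depth[[parent_node]]
      out[[length(out) + 1]] <- data.frame(
        species = lf, gene_a = a, gene_b = b, event = wgd_ev$event[k],
        branch = br, age_my = age,
        true_ks = 2 * config$syn_rate * 1e6 * age,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(species = character(), gene_a = character(),
                      gene_b = character(), event = character(),
                      branch = character(), age_my = numeric(),
                      true_ks = numeric(), stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}
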