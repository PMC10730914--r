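# Dollo-parsimony loss inference and marginal ancestral reconstruction.
#
# Under Dollo parsimony a complex trait (here: a functional multi-gene
# pathway) arises once, at the root of the clade carrying it, and can only
# be lost thereafter. With a single gain fixed at the origin, the
# loss-minimal labeling sets every internal node to 1 exactly when some
# descendant leaf is 1; the loss edges are the 1 -> 0 transitions.
#
# Marginal ancestral reconstruction uses Felsenstein's pruning algorithm on
# a single alignment column and the standard outside pass, equivalent to
# re-rooting at every node, under a Poisson (equal-rates, equal-frequency)
# amino-acid model by default or a user-supplied 20x20 rate matrix.

#' Dollo-parsimony loss events for a binary trait
#'
#' @param tree rooted `phylo` tree (ape). Branch ids are the child node's
#'   label (tip label for terminal branches, node label for internal ones;
#'   unlabeled internal nodes get `"n<number>"`).
#' @param traits named 0/1 vector covering every tip (1 = trait present).
#' @return list of class `dollo_result`: `origin`, `node_states` (named over
#'   tips + internal nodes), `loss_edges` (data.frame `parent`, `child`,
#'   `branch_id`), `loss_count`.
#' @export
dollo_losses <- function(tree, traits) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree <- stats::reorder(tree, "cladewise")
  tree <- label_nodes(tree)
  traits <- unlist(traits)
  miss <- setdiff(tree$tip.label, names(traits))
  if (length(miss) > 0)
    stop("trait state missing for tip(s): ", paste(miss, collapse = ", "))
  if (!all(traits[tree$tip.label] %in% c(0, 1)))
    stop("traits must be 0/1")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  lab <- c(tree$tip.label, tree$node.label)
  state <- integer(ntip + nnode)
  state[seq_len(ntip)] <- as.integer(traits[tree$tip.label])
  # postorder: node state 1 iff any descendant leaf is 1
  for (i in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    if (state[ch] == 1) state[p] <- 1L
  }
  loss <- tree$edge[state[tree$edge[, 1]] == 1 & state[tree$edge[, 2]] == 0,
                    , drop = FALSE]
  loss_edges <- data.frame(parent = lab[loss[, 1]], child = lab[loss[, 2]],
                           branch_id = lab[loss[, 2]],
                           stringsAsFactors = FALSE)
  loss_edges <- loss_edges[order(loss_edges$branch_id), , drop = FALSE]
  structure(list(origin = lab[ntip + 1L],
                 node_states = setNames(state, lab),
                 loss_edges = loss_edges,
                 loss_count = nrow(loss_edges)),
            class = "dollo_result")
}

#' @export
print.dollo_result <- function(x, ...) {
  cat("dollo_result:", x$loss_count, "loss event(s)",
      if (x$loss_count > 0)
        paste0("on branch(es) ", paste(x$loss_edges$branch_id, collapse = ", "))
      else "", "\n")
  invisible(x)
}

label_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyNA(tree$node.label)) {
    lab <- tree$node.label %||% rep("", tree$Nnode)
    fix <- !nzchar(lab) | is.na(lab)
    lab[fix] <- paste0("n", which(fix) + ntip)
    tree$node.label <- lab
  }
  tree
}

#' Pathway-loss report from a presence matrix
#'
#' Derives the producer phenotype of every species from the matrix (via
#' [producer_phenotype()]), runs Dollo parsimony on the phenotype (its loss
#' edges are the "starred" branches: independent pathway losses) and on
#' every gene, both at the functional level (intact = 1) and at the locus
#' level (intact or pseudogene = 1, supporting the retained-synteny
#' argument for ancestral presence).
#'
#' @param matrix a `presence_matrix` from [build_matrix()] (rows enzymes,
#'   columns species, cells `"intact"`/`"pseudogene"`/`"absent"`).
#' @param tree rooted `phylo` covering all matrix species.
#' @param model a [pathway_model][load_pathway].
#' @return list of class `loss_report`: `phenotype` (named 0/1),
#'   `phenotype_dollo`, `per_gene` and `per_gene_locus` (lists of
#'   `dollo_result`), `starred_branches`.
#' @export
pathway_loss_report <- function(matrix, tree, model) {
  mat <- unclass_matrix(matrix)
  miss <- setdiff(colnames(mat), tree$tip.label)
  if (length(miss) > 0)
    stop("species in matrix missing from tree: ", paste(miss, collapse = ", "))
  keep_tips <- intersect(tree$tip.label, colnames(mat))
  if (length(keep_tips) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep_tips)
  phen <- vapply(colnames(mat), function(sp)
    as.integer(producer_phenotype(model, setNames(mat[, sp], rownames(mat)))),
    integer(1))
  phen_dollo <- dollo_losses(tree, phen)
  per_gene <- lapply(rownames(mat), function(g)
    dollo_losses(tree, setNames(as.integer(mat[g, ] == "intact"),
                                colnames(mat))))
  per_gene_locus <- lapply(rownames(mat), function(g)
    dollo_losses(tree, setNames(as.integer(mat[g, ] != "absent"),
                                colnames(mat))))
  names(per_gene) <- names(per_gene_locus) <- rownames(mat)
  structure(list(phenotype = phen, phenotype_dollo = phen_dollo,
                 per_gene = per_gene, per_gene_locus = per_gene_locus,
                 starred_branches = phen_dollo$loss_edges$branch_id),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("loss_report:", sum(x$phenotype == 1), "producer /",
      sum(x$phenotype == 0), "non-producer species;",
      x$phenotype_dollo$loss_count, "independent pathway loss(es)\n")
  if (length(x$starred_branches) > 0)
    cat("  starred branches:", paste(x$starred_branches, collapse = ", "), "\n")
  invisible(x)
}

#' Newick with loss branches starred
#'
#' Writes the tree with `*` appended to the labels of nodes whose parent
#' branch carries a pathway loss.
#' @param tree rooted `phylo`.
#' @param report a `loss_report`.
#' @param path output path.
#' @export
write_starred_newick <- function(tree, report, path) {
  tree <- label_nodes(tree)
  star <- report$starred_branches
  tree$tip.label <- ifelse(tree$tip.label %in% star,
                           paste0(tree$tip.label, "*"), tree$tip.label)
  tree$node.label <- ifelse(tree$node.label %in% star,
                            paste0(tree$node.label, "*"), tree$node.label)
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Marginal ancestral reconstruction

poisson_pmat <- function(t) {
  # 20-state equal-rates model normalized to 1 substitution/site/unit time
  e <- exp(-20 * t / 19)
  P <- matrix((1 - e) / 20, 20, 20)
  diag(P) <- 1 / 20 + 19 * e / 20
  P
}

q_pmat_factory <- function(Q) {
  stopifnot(is.matrix(Q), nrow(Q) == 20, ncol(Q) == 20)
  eg <- eigen(Q)
  V <- eg$vectors; Vi <- solve(V)
  function(t) {
    P <- Re(V %*% diag(exp(eg$values * t)) %*% Vi)
    P[P < 0] <- 0
    P
  }
}

#' Marginal ancestral amino-acid posteriors at one alignment column
#'
#' Felsenstein pruning (post-order conditional likelihoods with
#' `P(t) = exp(Qt)`) followed by the standard outside pass, giving the
#' marginal posterior distribution over the 20 residues at every internal
#' node. Default model: Poisson with equal stationary frequencies (rate
#' normalized to one substitution per site per unit branch length); a
#' custom 20x20 rate matrix can be supplied. Gaps and missing tips
#' contribute a flat likelihood.
#'
#' @param tree rooted `phylo` with branch lengths in expected substitutions
#'   per site. Trees in other units (e.g. Mya) must be rescaled via
#'   `rate_scale` (branch length is multiplied by it).
#' @param column named character vector: tip -> residue (single letters;
#'   `"-"`, `"X"` or `NA` treated as missing).
#' @param rate_scale multiplier applied to branch lengths, default 1.
#' @param Q optional custom rate matrix (rows/cols in the order of the
#'   20-letter alphabet `A R N D C Q E G H I L K M F P S T W Y V`).
#' @return list of class `ancestral_posterior`: `posterior` (matrix nodes x
#'   20 residues), `log_likelihood`, `states` (MAP residue per node).
#' @export
marginal_ancestral <- function(tree, column, rate_scale = 1, Q = NULL) {
  if (!inherits(tree, "phylo") || !ape::is.rooted(tree))
    stop("tree must be a rooted phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree <- stats::reorder(ape::as.phylo(tree), "cladewise")
  tree <- label_nodes(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  lab <- c(tree$tip.label, tree$node.label)
  alpha <- AA_ALPHABET20
  pmat <- if (is.null(Q)) poisson_pmat else q_pmat_factory(Q)
  pi0 <- rep(1 / 20, 20)
  bl <- tree$edge.length * rate_scale
  # tip conditionals
  D <- matrix(1, ntip + nnode, 20)
  for (i in seq_len(ntip)) {
    res <- toupper(column[[tree$tip.label[i]]] %||% NA_character_)
    if (!is.na(res) && res %in% alpha)
      D[i, ] <- as.numeric(alpha == res)
  }
  edges <- tree$edge
  Pm <- lapply(seq_len(nrow(edges)), function(e) pmat(bl[e]))
  # postorder (edges of ape trees from root outward; reverse order works)
  child_edges <- split(seq_len(nrow(edges)), edges[, 1])
  po <- rev(seq_len(nrow(edges)))
  for (e in po) {
    ch <- edges[e, 2]
    if (ch > ntip) {
      for (ce in child_edges[[as.character(ch)]])
        D[ch, ] <- D[ch, ] * (Pm[[ce]] %*% D[edges[ce, 2], ])
    }
  }
  root <- ntip + 1L
  D[root, ] <- 1
  for (ce in child_edges[[as.character(root)]])
    D[root, ] <- D[root, ] * (Pm[[ce]] %*% D[edges[ce, 2], ])
  lik <- sum(pi0 * D[root, ])
  if (lik <= 0)
    stop("zero likelihood: conflicting tip states on zero-length branches")
  # outside pass
  O <- matrix(0, ntip + nnode, 20)
  O[root, ] <- pi0
  preorder <- seq_len(nrow(edges))  # parent always precedes child in ape edge
  for (e in preorder) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    contrib <- O[p, ]
    for (se in child_edges[[as.character(p)]]) {
      if (se == e) next
      contrib <- contrib * as.numeric(Pm[[se]] %*% D[edges[se, 2], ])
    }
    O[ch, ] <- as.numeric(t(Pm[[e]]) %*% contrib)
  }
  post <- O * D
  post <- post / rowSums(post)
  rownames(post) <- lab
  colnames(post) <- alpha
  structure(list(posterior = post, log_likelihood = log(lik),
                 states = setNames(alpha[apply(post, 1, which.max)], lab)),
            class = "ancestral_posterior")
}

#' Ancestral posteriors for a set of alignment sites
#'
#' Runs [marginal_ancestral()] at each requested column of a protein
#' alignment (sites indexed on the alignment/reference coordinate).
#'
#' @param tree rooted `phylo` with branch lengths (see
#'   [marginal_ancestral()]).
#' @param alignment named character vector of equal-length aligned protein
#'   sequences (tips).
#' @param sites integer alignment positions, default the five tropinone-
#'   binding-pocket sites of TRI (109, 155, 167, 201, 243).
#' @param ... passed to [marginal_ancestral()].
#' @return named list of `ancestral_posterior`, one per site.
#' @export
ancestral_sites <- function(tree, alignment, sites = c(109, 155, 167, 201, 243),
                            ...) {
  len <- unique(nchar(alignment))
  if (length(len) != 1) stop("alignment sequences must have equal length")
  if (any(sites < 1 | sites > len)) stop("site index outside alignment")
  out <- lapply(sites, function(s) {
    col <- setNames(substring(alignment, s, s), names(alignment))
    marginal_ancestral(tree, col, ...)
  })
  names(out) <- as.character(sites)
  out
}
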