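# Codon bookkeeping shared by the simulator and the Ks estimator.
#
# Site counting follows Nei & Gojobori (1986): at each codon position the
# synonymous site fraction is the share of the three possible nucleotide
# changes that preserve the amino acid; mutations creating a stop codon are
# counted as nonsynonymous. Difference counting enumerates all minimal
# substitution pathways between two codons, drops pathways that pass through
# a stop codon and renormalizes over the survivors; if every pathway is
# blocked the stop exclusion is lifted for that pair (stop steps then count
# as nonsynonymous) so the pair is still usable.

BASES <- c("T", "C", "A", "G")

codon_universe <- function() {
  if (!is.null(.pkg_cache$codons)) return(.pkg_cache$codons)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  info <- list(codons = codons, aa = aa, is_stop = aa == "*",
               sense = codons[aa != "*"])
  .pkg_cache$codons <- info
  info
}

codon_aa <- function(codon) {
  u <- codon_universe()
  u$aa[match(codon, u$codons)]
}

# Per-codon NG86 synonymous-site count (sum over three positions of the
# synonymous fraction among the three possible changes).
ng86_sites <- function() {
  if (!is.null(.pkg_cache$ng86_s)) return(.pkg_cache$ng86_s)
  u <- codon_universe()
  s <- setNames(numeric(length(u$sense)), u$sense)
  for (cd in u$sense) {
    nt <- strsplit(cd, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      nsyn <- 0
      for (b in setdiff(BASES, nt[p])) {
        alt <- nt; alt[p] <- b
        alt <- paste(alt, collapse = "")
        if (!codon_universe()$is_stop[match(alt, u$codons)] &&
            codon_aa(alt) == codon_aa(cd))
          nsyn <- nsyn + 1
      }
      tot <- tot + nsyn / 3
    }
    s[cd] <- tot
  }
  .pkg_cache$ng86_s <- s
  s
}

# Enumerate minimal substitution pathways between two codons and average the
# synonymous / nonsynonymous step counts. Returns c(sd, nd).
ng86_pair_counts <- function(c1, c2) {
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  diffpos <- which(n1 != n2)
  d <- length(diffpos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- perms_of(diffpos)
  score_path <- function(ord, allow_stop) {
    cur <- n1; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- n2[p]
      a1 <- codon_aa(paste(cur, collapse = ""))
      a2 <- codon_aa(paste(nxt, collapse = ""))
      if (a2 == "*" && !allow_stop) return(NULL)
      if (a1 == a2 && a2 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, score_path, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    res <- lapply(perms, score_path, allow_stop = TRUE)
  m <- Reduce(`+`, res) / length(res)
  c(sd = m[1], nd = m[2])
}

perms_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# Full 61 x 61 Sd / Nd lookup tables (built once, cached).
ng86_tables <- function() {
  if (!is.null(.pkg_cache$ng86_tab)) return(.pkg_cache$ng86_tab)
  u <- codon_universe()
  n <- length(u$sense)
  Sd <- matrix(0, n, n, dimnames = list(u$sense, u$sense))
  Nd <- Sd
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cnt <- ng86_pair_counts(u$sense[i], u$sense[j])
      Sd[i, j] <- cnt[1]; Nd[i, j] <- cnt[2]
    }
  }
  .pkg_cache$ng86_tab <- list(Sd = Sd, Nd = Nd, sites = ng86_sites())
  .pkg_cache$ng86_tab
}

# Mutation neighborhoods for the simulator: for each sense codon, the single
# nucleotide changes that do not create a stop, with their NG86 class.
codon_neighbors <- function() {
  if (!is.null(.pkg_cache$nbrs)) return(.pkg_cache$nbrs)
  u <- codon_universe()
  nb <- vector("list", length(u$sense))
  names(nb) <- u$sense
  for (cd in u$sense) {
    nt <- strsplit(cd, "")[[1]]
    tos <- character(); syn <- logical()
    for (p in 1:3) for (b in setdiff(BASES, nt[p])) {
      alt <- nt; alt[p] <- b
      alt <- paste(alt, collapse = "")
      if (codon_aa(alt) == "*") next
      tos <- c(tos, alt)
      syn <- c(syn, codon_aa(alt) == codon_aa(cd))
    }
    nb[[cd]] <- list(to = tos, syn = syn)
  }
  .pkg_cache$nbrs <- nb
  nb
}

# Fast vectorized translation via the standard genetic code table
# (Biostrings::GENETIC_CODE); unknown codons become X, stops "*".
translate_fast <- function(cds) {
  gc_tab <- codon_universe()
  cods <- split_codons(toupper(cds))
  aa <- gc_tab$aa[match(cods, gc_tab$codons)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}
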