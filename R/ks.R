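# Synonymous-divergence (Ks) estimation and WGD dating.
#
# Per-pair Ks/Ka uses Nei-Gojobori (1986) counting with the Jukes-Cantor
# multiple-hit correction Ks = -(3/4) ln(1 - 4 ps / 3). Collinear pairs come
# from synteny blocks; their codon alignments are threaded through the
# protein alignment. Peaks of the Ks distribution mark polyploidy events and
# are converted to ages with T = Ks_mode / (2 r).

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori counts and corrected distances for one codon pair alignment
#'
#' Counts synonymous and nonsynonymous sites and differences over a pair of
#' aligned, gap-stripped coding sequences and applies the Jukes-Cantor
#' correction. Codon columns containing a stop codon or a non-ACGT character
#' are dropped. An estimate is flagged invalid when fewer than 30 codons
#' remain or when `ps >= 3/4` (the correction is undefined there).
#'
#' @param cds_a,cds_b equal-length coding sequences (characters, no gaps).
#' @return list of class `ks_estimate` with fields `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `codons`, `valid`.
#' @export
estimate_ks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned coding sequences must have equal length")
  ca <- split_codons(toupper(cds_a))
  cb <- split_codons(toupper(cds_b))
  u <- codon_universe()
  ia <- match(ca, u$sense)
  ib <- match(cb, u$sense)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  tab <- ng86_tables()
  S <- (sum(tab$sites[ia]) + sum(tab$sites[ib])) / 2
  N <- 3 * length(ia) - S
  Sd <- sum(tab$Sd[cbind(ia, ib)])
  Nd <- sum(tab$Nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  valid <- length(ia) >= 30 && ps < 0.75
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = jc_correct(ps), Ka = jc_correct(pn),
                 codons = length(ia), valid = valid),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("ks_estimate: %d codons, S=%.1f N=%.1f Sd=%.2f Nd=%.2f Ks=%.4f Ka=%.4f%s\n",
              x$codons, x$S, x$N, x$Sd, x$Nd, x$Ks, x$Ka,
              if (x$valid) "" else " (invalid)"))
  invisible(x)
}

# Thread the codons of two coding sequences through the local protein
# alignment of their translations; returns the two gapless codon strings
# restricted to aligned (match/mismatch) protein columns.
codon_align <- function(cds_a, cds_b, params = align_params()) {
  pa <- sub("\\*$", "", translate_fast(cds_a))
  pb <- sub("\\*$", "", translate_fast(cds_b))
  r <- cpp_local_align(pa, pb, blosum62_az(), params$gap_open,
                       params$gap_extend)
  if (r$score <= 0) return(list(a = "", b = ""))
  qa <- r$q_aligned; sa <- r$s_aligned
  list(a = paste(substring(cds_a, 3 * qa + 1, 3 * qa + 3), collapse = ""),
       b = paste(substring(cds_b, 3 * sa + 1, 3 * sa + 3), collapse = ""))
}

#' Median Ks of a synteny block
#'
#' Estimates Ks for every anchor pair of a block (protein-guided codon
#' alignment, then [estimate_ks()]) and returns the median over valid pairs.
#'
#' @param block a `synteny_block` from [chain_anchors()].
#' @param cds named character vector holding the coding sequence of every
#'   gene appearing in the block.
#' @param params alignment parameters for the protein-guided codon threading.
#' @return median Ks (numeric), or `NA` with a warning when no pair is valid.
#' @export
block_ks <- function(block, cds, params = align_params()) {
  est <- pair_ks(block$anchors$gene_a, block$anchors$gene_b, cds, params)
  ok <- est$valid & !is.na(est$Ks)
  if (!any(ok)) {
    warning("block ", block$block_id, " has no valid Ks estimate; excluded")
    return(NA_real_)
  }
  median(est$Ks[ok])
}

# Vectorized per-pair Ks for anchor lists; returns a data.frame.
pair_ks <- function(genes_a, genes_b, cds, params = align_params()) {
  n <- length(genes_a)
  out <- data.frame(gene_a = genes_a, gene_b = genes_b,
                    S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                    ps = NA_real_, pn = NA_real_, Ka = NA_real_,
                    Ks = NA_real_, valid = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    al <- codon_align(cds[[genes_a[i]]], cds[[genes_b[i]]], params)
    if (nchar(al$a) == 0) next
    e <- estimate_ks(al$a, al$b)
    out[i, c("S", "N", "Sd", "Nd", "ps", "pn", "Ka", "Ks")] <-
      list(e$S, e$N, e$Sd, e$Nd, e$ps, e$pn, e$Ka, e$Ks)
    out$valid[i] <- e$valid
  }
  out
}

#' Detect peaks of a Ks distribution
#'
#' Gaussian kernel density over Ks values inside `range` (Silverman's
#' rule-of-thumb bandwidth unless overridden); local maxima are reported as
#' modes ordered by basin weight. Each peak's spread (`component_sd`) is
#' estimated from the half-width at half-maximum inside the peak's basin.
#'
#' @param ks numeric vector of per-pair or per-block Ks values.
#' @param range inclusive lower/upper bounds of usable Ks, default
#'   `c(0.005, 2)`; values at or below the lower bound (allelic or identical
#'   pairs) and above the upper (saturated pairs) are discarded.
#' @param bandwidth kernel bandwidth; default Silverman (`stats::bw.nrd0`).
#' @param min_n minimum number of usable values, default 50.
#' @return data.frame with columns `mode`, `component_sd`, `weight`, ordered
#'   by decreasing weight. Empty (with a warning) when input is too sparse.
#' @export
detect_ks_peaks <- function(ks, range = c(0.005, 2), bandwidth = NULL,
                            min_n = 50) {
  empty <- data.frame(mode = numeric(), component_sd = numeric(),
                      weight = numeric())
  ks <- ks[!is.na(ks) & ks > range[1] & ks <= range[2]]
  if (length(ks) < min_n) {
    warning("too few Ks values in range (", length(ks), " < ", min_n,
            "); no peaks reported")
    return(empty)
  }
  bw <- bandwidth %||% stats::bw.nrd0(ks)
  d <- density(ks, bw = bw, from = range[1], to = range[2], n = 512)
  y <- d$y; x <- d$x
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) == 0) is_max <- which.max(y)
  is_min <- c(1, which(diff(sign(diff(y))) == 2) + 1, n)
  peaks <- lapply(is_max, function(i) {
    lo <- max(is_min[is_min < i]); hi <- min(is_min[is_min > i])
    mass <- sum(y[lo:hi]) * (x[2] - x[1])
    half <- y[i] / 2
    li <- i; while (li > lo && y[li] > half) li <- li - 1
    ri <- i; while (ri < hi && y[ri] > half) ri <- ri + 1
    hwhm <- max(x[ri] - x[i], x[i] - x[li])
    data.frame(mode = x[i], component_sd = hwhm / sqrt(2 * log(2)),
               weight = mass)
  })
  out <- do.call(rbind, peaks)
  # drop numerical ripples carrying (essentially) no mass
  out <- out[out$weight >= 0.01 * sum(out$weight), , drop = FALSE]
  out[order(-out$weight), , drop = FALSE]
}

#' Date a whole-genome duplication from a Ks mode
#'
#' Converts a synonymous-divergence mode to an age with `T = mode / (2 r)`
#' and a normal-approximation 95% interval from the peak's spread.
#'
#' @param mode Ks mode (substitutions per synonymous site).
#' @param component_sd spread of the peak component (same units as `mode`).
#' @param r synonymous substitution rate per site per year.
#' @return list of class `wgd_event` with `ks_mode`, `component_sd`, `rate`,
#'   `T_mya`, `ci95_mya`.
#' @export
#' @examples
#' date_wgd(0.15, 0.04, 5.6e-9)$T_mya  # ~13.4
date_wgd <- function(mode, component_sd = 0, r) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    stop("synonymous rate r must be a positive number")
  if (mode < 0) stop("Ks mode must be non-negative")
  T_mya <- mode / (2 * r) / 1e6
  ci <- pmax(0, c(mode - 1.96 * component_sd, mode + 1.96 * component_sd)) /
    (2 * r) / 1e6
  structure(list(ks_mode = mode, component_sd = component_sd, rate = r,
                 T_mya = T_mya, ci95_mya = ci),
            class = "wgd_event")
}

#' @export
print.wgd_event <- function(x, ...) {
  cat(sprintf("wgd_event: Ks mode %.3f -> %.2f Mya (95%% CI %.2f-%.2f), r=%.2e\n",
              x$ks_mode, x$T_mya, x$ci95_mya[1], x$ci95_mya[2], x$rate))
  invisible(x)
}
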