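---
title: "Inferring the single origin and repeated loss of a biosynthetic pathway from microsynteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the single origin and repeated loss of a biosynthetic pathway from microsynteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the inference strategy

Hyoscyamine and scopolamine (HS), two medicinal tropane alkaloids, are
produced by several phylogenetically distant lineages of the Solanaceae but
not by the lineages between them. Two evolutionary histories can produce
such a scattered distribution: the twelve-enzyme biosynthetic pathway arose
independently several times (convergence), or it arose once in the common
ancestor and was lost repeatedly. The two histories leave different genomic
footprints. Under a single origin, non-producing genomes should still carry
the *syntenic context* of the pathway genes — the conserved gene
neighborhoods — often with recognizable pseudogene remnants at the expected
loci, and the functional copies in producers should be paraphyletic rather
than forming the monophyletic clusters convergence would produce.

`synteloss` implements that footprint-reading pipeline as a set of
composable stages:

1. **Homology** — all-vs-all protein comparison by exact affine-gap local
   alignment (Gotoh dynamic programming under BLOSUM62, gap costs 11/1),
   with Karlin–Altschul bit scores and E-values (gapped BLOSUM62 constants
   λ = 0.267, K = 0.041) and the conventional E ≤ 1e-5 retention filter.
   Retained hits are clustered into families by single-linkage connected
   components (≥30% identity, ≥50% query coverage).
2. **Synteny** — cross-genome gene pairs sharing a family become anchors
   addressed by gene *rank* (order along the chromosome); anchors are
   chained into collinear blocks by dynamic programming (score
   `10·anchors − 1·rank gaps`, gaps capped at 25 ranks, greedy best-first
   extraction, blocks of ≥5 anchors kept). Rank coordinates make chaining
   independent of physical scale. Modal syntenic depth ratios (how many
   regions of genome B cover a region of genome A) read out ploidy history:
   2:1 after a lineage-specific whole-genome duplication (WGD).
3. **Scenario cascade** — for each pathway gene of each reference genome,
   the flanking window (100 kb, or ±20 genes) is located in every other
   genome through the blocks carrying at least 3 window anchors.
   Scenario 1: a family ortholog lies in the located region (synteny
   supports presence). Scenario 2: the region exists but holds no ortholog
   (synteny supports absence); a six-frame translated scan of the region
   then separates pseudogene from clean absence. Scenario 3: no block finds
   the region at all; a genome-wide family search catches translocated but
   intact copies, and a genome-wide translated scan is the last resort.
   Calls from the reference genomes are merged per cell with precedence
   intact > pseudogene > absent.
4. **Ks dating** — synonymous divergence of collinear pairs by
   Nei–Gojobori (1986) counting with Jukes–Cantor correction
   (`Ks = −(3/4)·ln(1 − 4·ps/3)`); kernel-density modes of the per-pair Ks
   distribution mark polyploidy events, dated by `T = Ks_mode / (2r)`.
5. **Loss inference** — the per-species producer phenotype (every
   non-dispensable enzyme intact) is analysed under Dollo parsimony: the
   pathway arises once at the root and can only be lost; with the gain
   fixed, the loss-minimal labeling marks an internal node functional
   exactly when some descendant leaf is, and the 1→0 edges are the
   independent losses. Marginal ancestral reconstruction (Felsenstein
   pruning plus the outside pass) recovers per-node posteriors for key
   catalytic residues.

## The pathway model

The bundled model transcribes the twelve enzymes of HS biosynthesis,
indexed over compounds 1–14: the tropane-ring segment (PMT, MPO, PYKS,
CYP82M3, compounds 1→5), the phenyllactylglucoside branch (ArAT4, PPAR,
UGT1, compounds 7→10), and the terminal medicinal segment beginning at TRI
(TRI 5→6, LS 6+10→11, CYP80F1 11→12, HDH 12→13, H6H 13→14). The
spontaneous cyclization between compounds 3 and 4 is not enzyme-catalyzed,
so steps are enzyme-indexed — twelve enzymes, not twelve reactions. The
five steps from TRI onward are exclusive to HS production and define the
forced-loss set in the simulator.

HDH deserves a note: silencing it does not measurably reduce hyoscyamine,
so it may be catalytically dispensable. The default keeps HDH required for
the producer phenotype (every known producer carries it); passing
`dispensable = "HDH"` to `load_pathway()` flips that interpretation without
touching anything else.

## What the simulator emulates — and what it does not

`generate_dataset()` evolves an ancestral genome (three chromosomes of 30
single-copy background genes, 300 bp coding sequences, 2 kb intergenic
spacers, plus the 12 pathway genes at fixed interior loci) along a rooted,
Mya-scaled tree. The 2 kb spacing is deliberate: a 100 kb scan window then
spans roughly ±20 genes, so the window logic can be exercised in both bp
and gene-rank units at desk scale.

Coding sequences evolve by a per-codon Gillespie process. Each codon's
total substitution rate is `r_s·s + r_n·n`, where `s` and `n` are its
synonymous and nonsynonymous neighbor counts under the same site partition
the NG86 estimator uses; mutations that would create a stop codon are
rejected. Waiting times are exponential, so multiple hits per site occur at
realistic frequency and the Jukes–Cantor correction is the matched
estimator. The default rates are `r_s = 5.6e-9` and `r_n = 1.4e-9`
substitutions/site/year. The synonymous rate is a stated assumption — the
kind of value used for Solanaceae-scale dating — not a measured constant;
with it, a duplication 13.41 My ago leaves a Ks peak at
`2·r_s·2T ≈ 0.150`.

Structural events:

* **Polyploidy** duplicates (or triplicates) every chromosome, then each
  duplicated chromosome retains one *contiguous* segment holding the
  configured `retention` fraction of its genes. Contiguity matters: it is
  the pattern block-wise fractionation leaves behind, and it keeps
  surviving homeologous segments local. Independent per-gene retention
  would instead scatter thin anchor chains across every chromosome and
  inflate syntenic depth everywhere.
* **Pseudogenization** converts a gene to an unannotated residual at the
  same locus: either the 3′-most exon fraction survives
  (`"truncate-5prime-2-exons"`, the default — pathway genes carry a
  notional 30/30/40% three-exon structure) or the full sequence stays with
  a premature stop knocked in (`"premature-stop"`). Residuals continue to
  evolve neutrally and are what the translated scan is meant to find.
* **Forced pathway loss** on designated branches removes or pseudogenizes
  *every* copy of the five HS-exclusive genes — the simulated analogue of
  a lineage abandoning the trait.
* **Scripted translocation with synteny erosion** moves the focal gene to
  a random locus and deletes every genomic copy of the background families
  that flanked it. The erosion step is essential: moving the gene alone
  leaves its old neighborhood collinear, so the cascade would still locate
  the (now empty) region and stop at scenario 2. Only when the syntenic
  context itself is gone does the classification fall through to
  scenario 3, which is exactly the situation reported for PPAR in real
  genomes.
* Background Poisson event rates (loss, pseudogenization, translocation
  per gene per My) exist for stress-testing; the bundled preset sets them
  to zero so its ground truth is a deterministic function of the scripted
  events alone.

The bundled `preset_clade17()` builds a 17-species ultrametric clade: two
outgroup species (split 60 Mya), a 15-species ingroup radiating from
27 Mya, a shared triplication on the ingroup stem (retention 0.2), two
lineage-specific WGDs on terminal branches (`wgdA` at 13.41 Mya, `wgdM` at
11 Mya, retention 0.75), a fourfold tandem expansion of TRI on one
producer branch, the PPAR erosion-translocation on one non-producer
terminal, and three forced pathway losses (branch `lossA` covering a
three-leaf clade, plus terminals `n4` and `n5`) — 12 producers, 5
non-producers. Reference enzyme proteins are snapshotted at the ingroup
ancestor (27 My from every ingroup leaf), mirroring the role of a
functionally characterized close relative; snapshotting at the root
instead would leave reference identity hovering at the 80% identification
threshold.

What the simulator does **not** model: introns as evolving sequence
(exon structure exists only as the truncation bookkeeping), indels,
repeats and transposons, annotation error, rate variation among sites or
lineages, and gene conversion between duplicates. Passing tests therefore
show that the pipeline's logic is correct on clean, fully observed
genomes; on real data the same stages inherit the error modes of their
inputs (mis-annotation, assembly gaps, repeat-driven spurious anchors —
the last partially addressed by the 20-copies-per-genome anchor cap).

## Numerical and design choices

* **Block-size threshold**: tool conventions put the collinearity cutoff
  at 5 anchors (`-s 5`) even where prose says "more than five"; the
  implementation keeps ≥5.
* **Greedy best-first chain extraction** with deterministic tie-breaking
  (chromosome pair, then smallest starting rank) rather than simultaneous
  k-best — the standard collinearity-tool behavior, and exactly
  reproducible. Both orientations compete for one shared anchor pool per
  chromosome pair, so blocks are anchor-disjoint. The chain optimum found
  each round is invariant under joint reversal of both gene orders; the
  *membership* of a tied optimum, and hence later greedy rounds, can
  legitimately differ between mirror-image inputs. There is no
  block-level E-value; `min_block_size` plus `max_gap` play that role.
* **Translated-scan thresholds**: pseudogene evidence needs ≥40% merged
  identity and ≥30% reference coverage, plus a lesion — coverage below
  80%, a premature stop interrupting a same-frame coding run, or a
  frameshift break. Per-segment hits must additionally pass an E-value
  cutoff (1e-3) computed against the *whole* translated search space (the
  standard database-length correction, not the single segment); without
  it, chance 15–30 residue matches in a 100 kb window accumulate into
  apparent "coverage" and deleted loci masquerade as pseudogenes. These
  are operating thresholds, configurable
  in `scenario_config()`; pseudogene calls on real genomes were
  historically made by manual structural inspection.
* **Consensus precedence** intact > pseudogene > absent when merging
  reference genomes: synteny-supported presence is the strongest evidence
  class, and a locus visible from any reference is a locus.
* **Window sides**: the flanking-anchor quorum may be met on either side
  of the target (`flank_sides = "either"`), since genes at block edges
  legitimately have one-sided support; `"both"` is available for stricter
  calls.
* **NG86 details**: site counts treat mutations to stops as
  nonsynonymous; difference counts average over all minimal substitution
  pathways excluding those through stop codons (renormalizing over the
  survivors, and lifting the exclusion in the rare codon pairs where
  every pathway is blocked). Estimates are invalid below 30 aligned
  codons or at `ps ≥ 3/4` where the correction diverges. Codon alignments
  are threaded through the local protein alignment; columns gapped in
  either protein are dropped.
* **Peak detection** uses a Gaussian KDE with Silverman bandwidth on Ks in
  (0.005, 2]; local maxima are reported with a component spread estimated
  from the half-width at half-maximum and a basin weight; ripples below 1%
  of total mass are discarded. The 95% interval on a dated event is a
  normal approximation from that spread — the method behind published
  intervals is typically unstated, so this one is explicit and simple.
* **Dollo**: with the gain fixed at the root, the loss-minimal labeling is
  closed-form (a node is functional iff some descendant leaf is); this is
  verified against brute-force minimization over all single-gain
  labelings. One property worth knowing: the loss *count* is not monotone
  in the set of trait-free leaves — losing the last carrier of a region
  merges sibling loss edges into one stem loss — so the package tests the
  partition property (loss edges bipartition exactly the trait-free
  leaves) rather than a monotonicity that does not hold.
* **Ancestral reconstruction** defaults to the Poisson (equal-rates,
  equal-frequency) amino-acid model with branch lengths in substitutions
  per site; a tree in Mya needs an explicit `rate_scale` (the
  demonstration uses 0.0015 subs/site/My, consistent with ~82% TRI
  identity across a ~60 My clade). A custom 20×20 rate matrix is accepted
  for JTT-like behavior. Marginal posteriors come from conditional
  likelihoods plus the standard outside pass; the total likelihood is
  invariant to the rooting used for computation, which the tests assert
  to 1e-9.
* **Coordinates** are 1-based inclusive everywhere (the GFF3/GRanges
  convention native to R's genomics stack).

## Problem sizes

The bundled clade keeps every stage exact but desk-sized: 17 genomes of
102–250 genes, ~2,500 proteins in the all-vs-all comparison, ~1,700
collinear blocks, 612 scenario classifications, and ~1,200 collinear Ks
pairs. A full simulate-plus-analyse cycle runs in about two minutes on one
CPU; the oracle-equivalence suites (exhaustive chaining, Dollo, NG86 over
all 61×61 sense-codon pairs, exhaustive local alignment and 3-taxon
ancestral summation) add a few minutes more.

## Known limitations

Single-linkage families can chain through promiscuous domains on real
proteomes (MCL-style clustering would be the upgrade path); the scenario
cascade trusts the annotation for "intact" (an annotated but frameshifted
model would be believed); WGD dating inherits the molecular-clock
assumption wholesale; and the translated scan reports evidence, not gene
models — it deliberately does not re-annotate exon structure.
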