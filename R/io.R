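# Standard-format I/O: GFF3 (rtracklayer), FASTA (Biostrings), Newick
# (ape), plus the simulated-dataset writer. Annotations are 1-based
# inclusive throughout (GFF3/GRanges convention).

write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(unlist(seqs))
       else Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a gene annotation as GFF3
#'
#' Emits gene, mRNA and CDS features (one CDS per gene; the simulator's
#' gene models are single-exon).
#' @param ann annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  mk <- function(type, ids, parents) {
    GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(start = ann$start, end = ann$end),
      strand = ann$strand, type = type, ID = ids,
      phase = if (type == "CDS") 0L else NA_integer_,
      Parent = if (is.null(parents)) S4Vectors::List(rep(list(character()),
                                                         nrow(ann)))
               else S4Vectors::List(as.list(parents)))
  }
  gr <- c(mk("gene", ann$gene_id, NULL),
          mk("mRNA", paste0(ann$gene_id, ".t1"), ann$gene_id),
          mk("CDS", paste0(ann$gene_id, ".cds"),
             paste0(ann$gene_id, ".t1")))
  rtracklayer::export(sort(gr), path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Returns the gene features as an annotation data.frame (1-based
#' inclusive coordinates) ordered by chromosome and start.
#' @param path GFF3 path.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  g <- gr[gr$type == "gene"]
  ann <- data.frame(gene_id = as.character(g$ID),
                    chrom = as.character(GenomicRanges::seqnames(g)),
                    start = GenomicRanges::start(g),
                    end = GenomicRanges::end(g),
                    strand = as.character(GenomicRanges::strand(g)),
                    stringsAsFactors = FALSE)
  ann[order(ann$chrom, ann$start), , drop = FALSE]
}

#' Write a simulated dataset to disk
#'
#' Produces, per species, a GFF3 annotation and protein/CDS/genomic FASTA
#' files, plus the tree (newick), the pathway definition, the reference
#' enzyme proteins, the ground-truth tables and a `manifest.yaml` tying
#' everything together (the input of [load_workspace()]).
#'
#' @param dataset a `sim_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  manifest <- list(species = list(), tree = "tree.nwk",
                   pathway = "pathway.tsv",
                   pathway_refs = "pathway_refs.faa",
                   reference_species = as.list(dataset$reference_species),
                   seed = dataset$config$seed)
  for (sp in names(dataset$leaves)) {
    lv <- dataset$leaves[[sp]]
    paths <- list(gff = paste0(sp, ".gff3"),
                  protein = paste0(sp, ".prot.faa"),
                  cds = paste0(sp, ".cds.fna"),
                  genomic = paste0(sp, ".genomic.fna"))
    write_gff3(lv$ann, file.path(dir, paths$gff))
    write_fasta(lv$protein, file.path(dir, paths$protein), "AA")
    write_fasta(lv$cds, file.path(dir, paths$cds), "DNA")
    write_fasta(lv$genomic, file.path(dir, paths$genomic), "DNA")
    manifest$species[[sp]] <- paths
  }
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_tsv(dataset$model$steps, file.path(dir, "pathway.tsv"))
  write_fasta(dataset$pathway_refs, file.path(dir, "pathway_refs.faa"), "AA")
  tr <- dataset$truth
  scen <- data.frame(enzyme = rownames(tr$scenario), tr$scenario,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(scen, file.path(dir, "truth", "scenario.tsv"))
  writeLines(tr$loss_edges, file.path(dir, "truth", "loss_edges.txt"))
  write_tsv(tr$event_log, file.path(dir, "truth", "event_log.tsv"))
  write_tsv(tr$families, file.path(dir, "truth", "families.tsv"))
  write_tsv(tr$wgd_pairs, file.path(dir, "truth", "wgd_pairs.tsv"))
  write_tsv(data.frame(species = names(tr$phenotype),
                       producer = unname(tr$phenotype)),
            file.path(dir, "truth", "phenotype.tsv"))
  res <- do.call(rbind, lapply(dataset$leaves, `[[`, "residuals"))
  write_tsv(res, file.path(dir, "truth", "residuals.tsv"))
  cfg <- unclass(dataset$config)
  cfg <- lapply(cfg, function(x) if (is.null(x)) NULL else x)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}

#' Load a workspace from a manifest
#'
#' Reads and cross-validates all inputs of the pipeline: per-species GFF3 +
#' protein/CDS/genomic FASTA, the species tree, the pathway definition and
#' the reference enzyme proteins. Validation failures (id mismatches
#' between GFF3 and FASTA, coding lengths not divisible by 3, proteins
#' that are not the translation of their CDS, manifest species missing
#' from the tree) are collected and reported together.
#'
#' @param manifest path to a `manifest.yaml` (see [write_dataset()]).
#' @return object of class `workspace`: `species` (per species: `ann`,
#'   `protein`, `cds`, `genomic`), `tree`, `model`, `pathway_refs`,
#'   `reference_species`, `dir`, `seed`.
#' @export
load_workspace <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  base <- dirname(normalizePath(manifest))
  errs <- character()
  tree <- ape::read.tree(file.path(base, m$tree))
  tree <- label_nodes(stats::reorder(tree, "cladewise"))
  model <- load_pathway(file.path(base, m$pathway))
  refs <- read_fasta(file.path(base, m$pathway_refs), "AA")
  species <- list()
  for (sp in names(m$species)) {
    p <- m$species[[sp]]
    ann <- read_gff3(file.path(base, p$gff))
    prot <- read_fasta(file.path(base, p$protein), "AA")
    cds <- read_fasta(file.path(base, p$cds), "DNA")
    genomic <- read_fasta(file.path(base, p$genomic), "DNA")
    if (!sp %in% tree$tip.label)
      errs <- c(errs, paste0("species ", sp, " missing from tree"))
    mism <- union(setdiff(ann$gene_id, names(prot)),
                  setdiff(names(prot), ann$gene_id))
    if (length(mism) > 0)
      errs <- c(errs, paste0(sp, ": GFF3/FASTA id mismatch for ",
                             paste(sort(mism), collapse = ", ")))
    badlen <- names(cds)[nchar(cds) %% 3 != 0]
    if (length(badlen) > 0)
      errs <- c(errs, paste0(sp, ": CDS length not divisible by 3 for ",
                             paste(sort(badlen), collapse = ", ")))
    common <- intersect(names(cds)[nchar(cds) %% 3 == 0], names(prot))
    tr <- vapply(cds[common], translate_cds, character(1))
    bad <- common[sub("\\*$", "", tr) != sub("\\*$", "", prot[common])]
    if (length(bad) > 0)
      errs <- c(errs, paste0(sp, ": protein is not the CDS translation for ",
                             paste(sort(bad), collapse = ", ")))
    species[[sp]] <- list(ann = ann, protein = prot, cds = cds,
                          genomic = genomic)
  }
  if (length(errs) > 0)
    stop("workspace validation failed:\n  ", paste(errs, collapse = "\n  "))
  structure(list(species = species, tree = tree, model = model,
                 pathway_refs = refs,
                 reference_species = unlist(m$reference_species),
                 dir = base, seed = m$seed %||% NA_integer_),
            class = "workspace")
}

#' Turn a simulated dataset into an in-memory workspace
#'
#' Shortcut equivalent to [write_dataset()] + [load_workspace()] without
#' touching disk.
#' @param dataset a `sim_dataset`.
#' @return a `workspace`.
#' @export
as_workspace <- function(dataset) {
  species <- lapply(dataset$leaves, function(lv)
    list(ann = lv$ann, protein = lv$protein, cds = lv$cds,
         genomic = lv$genomic))
  structure(list(species = species, tree = dataset$tree,
                 model = dataset$model, pathway_refs = dataset$pathway_refs,
                 reference_species = dataset$reference_species,
                 dir = NA_character_, seed = dataset$config$seed),
            class = "workspace")
}

#' @export
print.workspace <- function(x, ...) {
  cat("workspace:", length(x$species), "species,",
      length(x$pathway_refs), "reference enzymes; references:",
      paste(x$reference_species, collapse = ", "), "\n")
  invisible(x)
}
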