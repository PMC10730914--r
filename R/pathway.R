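# The hyoscyamine/scopolamine (HS) pathway model.
#
# Twelve enzymes carry putrescine (compound 1) to scopolamine (compound 14).
# The tropane-ring segment (PMT, MPO, PYKS, CYP82M3) and the phenyllactyl
# glucoside branch (ArAT4, PPAR, UGT1) feed shared metabolites; the terminal
# "medicinal" segment starting at TRI (TRI, LS, CYP80F1, HDH, H6H) is
# exclusive to HS production. The spontaneous cyclization between compounds
# 3 and 4 is not enzyme-catalyzed, so steps are indexed by enzyme, not by
# reaction.

PATHWAY_SEGMENTS <- c("tropane-ring", "PLA-glucoside", "medicinal")

#' Load a pathway model
#'
#' Reads a pathway definition TSV with columns `index`, `enzyme`,
#' `substrate`, `product`, `segment` and validates it. With no argument the
#' bundled 12-enzyme HS pathway is returned.
#'
#' Compound ids are small integers (1-14 for the bundled pathway). Within a
#' segment, consecutive steps must chain: each step's product equals the next
#' step's substrate (the condensation step LS consumes tropine, compound 6,
#' together with phenyllactylglucose, compound 10; its `substrate` field
#' records the tropane-side input so the medicinal chain stays closed).
#'
#' @param path path to a pathway TSV; `NULL` for the bundled HS pathway.
#' @param dispensable character vector of enzyme symbols whose loss does not
#'   abolish the end product (see [producer_phenotype()]). Default none.
#' @return object of class `pathway_model`: list with elements `steps`
#'   (data.frame) and `dispensable_enzymes`.
#' @export
#' @examples
#' pw <- load_pathway()
#' nrow(pw$steps)  # 12
load_pathway <- function(path = NULL, dispensable = character()) {
  if (is.null(path))
    path <- system.file("extdata", "hs_pathway.tsv", package = "synteloss")
  steps <- tryCatch(read_tsv(path), error = function(e)
    stop("malformed pathway definition file: ", conditionMessage(e)))
  need <- c("index", "enzyme", "substrate", "product", "segment")
  if (!all(need %in% names(steps)))
    stop("malformed pathway definition file: missing column(s) ",
         paste(setdiff(need, names(steps)), collapse = ", "))
  steps <- steps[order(steps$index), need]
  if (!identical(sort(steps$index), seq_len(nrow(steps))) ||
      anyDuplicated(steps$enzyme) > 0)
    stop("malformed pathway definition file: indices must be 1..n, enzymes unique")
  if (!all(steps$segment %in% PATHWAY_SEGMENTS))
    stop("malformed pathway definition file: unknown segment tag(s): ",
         paste(setdiff(steps$segment, PATHWAY_SEGMENTS), collapse = ", "))
  cmpd <- c(steps$substrate, steps$product)
  if (any(cmpd < 1) || any(cmpd != round(cmpd)))
    stop("malformed pathway definition file: compound ids must be positive integers")
  for (seg in unique(steps$segment)) {
    s <- steps[steps$segment == seg, ]
    if (nrow(s) > 1 && !all(s$product[-nrow(s)] == s$substrate[-1]))
      stop("malformed pathway definition file: segment '", seg,
           "' is not a substrate->product chain")
  }
  model <- structure(list(steps = steps,
                          dispensable_enzymes = unique(dispensable)),
                     class = "pathway_model")
  validate_pathway(model)
  model
}

validate_pathway <- function(model) {
  st <- model$steps
  bad <- setdiff(model$dispensable_enzymes, st$enzyme)
  if (length(bad) > 0)
    stop("dispensable enzyme(s) not in pathway: ", paste(bad, collapse = ", "))
  med <- st[st$segment == "medicinal", ]
  if (nrow(med) > 0 && !"TRI" %in% med$enzyme && "TRI" %in% st$enzyme)
    stop("the exclusive terminal segment must begin at TRI")
  invisible(model)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("pathway_model:", nrow(x$steps), "enzymatic steps\n")
  for (seg in PATHWAY_SEGMENTS) {
    s <- x$steps[x$steps$segment == seg, ]
    if (nrow(s) == 0) next
    cat(sprintf("  %-14s %s\n", seg,
                paste(sprintf("%s(%d>%d)", s$enzyme, s$substrate, s$product),
                      collapse = " ")))
  }
  if (length(x$dispensable_enzymes) > 0)
    cat("  dispensable:", paste(x$dispensable_enzymes, collapse = ", "), "\n")
  invisible(x)
}

#' Steps exclusive to end-product biosynthesis
#'
#' Returns the terminal segment (segment tag `"medicinal"`) beginning at the
#' TRI step: the five steps TRI, LS, CYP80F1, HDH, H6H in the bundled
#' pathway. These are the steps whose joint loss defines a non-producer.
#'
#' @param model a [pathway_model][load_pathway].
#' @return data.frame of steps in chain order (possibly empty, with warning).
#' @export
hs_exclusive_steps <- function(model) {
  st <- model$steps
  med <- st[st$segment == "medicinal", ]
  if (nrow(med) == 0) {
    warning("pathway has no exclusive terminal segment")
    return(med)
  }
  if (nrow(med) < nrow(st) && !"TRI" %in% med$enzyme)
    stop("model error: TRI step missing from the exclusive segment")
  # order by the substrate->product chain, starting from the step whose
  # substrate is produced nowhere inside the segment
  first <- which(!med$substrate %in% med$product)[1]
  ord <- first
  while (length(ord) < nrow(med)) {
    nxt <- which(med$substrate == med$product[ord[length(ord)]])
    if (length(nxt) == 0) { # disjoint chain pieces: append remaining by index
      ord <- c(ord, setdiff(seq_len(nrow(med)), ord))
      break
    }
    ord <- c(ord, nxt[1])
  }
  med[ord, ]
}

#' Species producer phenotype from per-gene functional states
#'
#' A species is called a producer when every non-dispensable enzyme of the
#' pathway is functionally intact; pseudogenes and absent loci both count as
#' non-functional. HDH can be declared dispensable (silencing it does not
#' measurably reduce hyoscyamine) via the `dispensable` argument of
#' [load_pathway()]; by default it is required.
#'
#' @param model a [pathway_model][load_pathway].
#' @param states named character vector or list mapping every enzyme symbol
#'   to one of `"intact"`, `"pseudogene"`, `"absent"`.
#' @return logical scalar.
#' @export
producer_phenotype <- function(model, states) {
  states <- unlist(states)
  enz <- model$steps$enzyme
  missing <- setdiff(enz, names(states))
  if (length(missing) > 0)
    stop("functional state missing for enzyme(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(states[enz]), c("intact", "pseudogene", "absent"))
  if (length(bad) > 0)
    stop("unknown functional state(s): ", paste(bad, collapse = ", "))
  required <- setdiff(enz, model$dispensable_enzymes)
  all(states[required] == "intact")
}
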