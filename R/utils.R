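# Internal helpers shared across modules.

.pkg_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

#' BLOSUM62 scoring matrix over the 26-letter alphabet
#'
#' Taken from the matrix shipped with Biostrings, reindexed to plain A-Z.
#' Ambiguity code X is scored 0 against everything; letters with no BLOSUM
#' entry (B, Z, J, O, U) fall back to 0 as well.
#' @return integer 26 x 26 matrix, dimnames LETTERS.
#' @keywords internal
blosum62_az <- function() {
  if (!is.null(.pkg_cache$blosum)) return(.pkg_cache$blosum)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  M <- matrix(0L, 26, 26, dimnames = list(LETTERS, LETTERS))
  common <- intersect(LETTERS, rownames(B))
  M[common, common] <- B[common, common]
  M["X", ] <- 0L
  M[, "X"] <- 0L
  .pkg_cache$blosum <- M
  M
}

assert_protein <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(AA_ALPHABET20, "X"))
  if (length(bad) > 0)
    stop("illegal character(s) in ", what, ": ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Statistical mode of a positive integer vector (smallest value on ties).
int_mode <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) return(0L)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

# Deterministic TSV writer (no quotes, no row names).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
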