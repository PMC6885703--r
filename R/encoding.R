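#' Amino-acid alphabet
#'
#' The 20 standard residues in fixed alphabetical one-letter order, plus the
#' wildcard symbol `X` used for unknown residues and insertion padding in
#' binding cores. All peptide/pseudo-sequence encodings in the package index
#' residues against this ordering.
#'
#' @return A list with `residues` (character vector of length 20) and
#'   `wildcard` (`"X"`).
#' @export
aa_alphabet <- function() {
  list(residues = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], wildcard = "X")
}

.aa_full <- function() c(aa_alphabet()$residues, aa_alphabet()$wildcard)

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI BLOSUM/PAM text layout: comment lines starting
#' with `#`, a header row of residue one-letter codes, then one labelled row
#' per residue.
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with residue dimnames.
#' @export
read_blosum <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, character(1), 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(m) <- list(lab, header)
  m
}

#' BLOSUM50 substitution matrix
#'
#' Retrieved from the Biostrings package (scores on the standard integer
#' scale, half-bits).
#'
#' @return Numeric matrix with residue dimnames.
#' @export
blosum50 <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for the built-in BLOSUM50 matrix")
  e <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = e)
  e$BLOSUM50
}

#' Residue encoding matrix
#'
#' Builds the 21 x 20 input encoding: one row per standard residue (the
#' residue's substitution-matrix row against the 20 standard residues, divided
#' by `scale`) plus an all-zero wildcard row.
#'
#' @param sub Substitution matrix (default BLOSUM50).
#' @param scale Divisor applied to the scores (default 5, the NNAlign
#'   convention).
#' @return List with `values` (21 x 20 matrix, rownames include `X`) and
#'   `name`.
#' @export
encoding_matrix <- function(sub = blosum50(), scale = 5) {
  res <- aa_alphabet()$residues
  if (!all(res %in% rownames(sub)))
    stop("substitution matrix misses standard residues")
  m <- sub[res, res, drop = FALSE] / scale
  m <- rbind(m, X = 0)
  storage.mode(m) <- "double"
  list(values = m, name = sprintf("%s/%s", "blosum50", scale))
}

# residue index (1-based into the 21-symbol alphabet); errors on illegal symbols
.res_index <- function(chars) {
  idx <- match(chars, .aa_full())
  if (anyNA(idx)) {
    stop("illegal symbol(s): ", paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  idx
}
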