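#' Read an MHC pseudo-sequence table
#'
#' Two-column whitespace-separated text, `ALLELE_NAME PSEUDOSEQ` (the
#' NetMHCpan `MHC_pseudo.dat` dialect). All pseudo-sequences must have the
#' same length; residues must come from the 21-symbol alphabet.
#'
#' @param path File path.
#' @param expected_length Optional required pseudo-sequence length (34 is the
#'   class I convention). If `NULL`, the length of the first entry is used.
#' @return Named character vector, `names` = allele, values = pseudo-sequence.
#' @export
read_pseudosequence_table <- function(path, expected_length = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed pseudo-sequence table at line ", bad[1])
  ps <- vapply(parts, `[`, character(1), 2L)
  names(ps) <- vapply(parts, `[`, character(1), 1L)
  validate_pseudosequences(ps, expected_length)
  ps
}

validate_pseudosequences <- function(ps, expected_length = NULL) {
  len <- nchar(ps)
  if (is.null(expected_length)) expected_length <- len[1]
  if (!all(len == expected_length))
    stop("pseudo-sequences must all have length ", expected_length)
  invisible(lapply(strsplit(ps, ""), .res_index))
  invisible(ps)
}

#' Distance between two MHC molecules
#'
#' Computed from the sequence similarity of the two pseudo-sequences:
#' `d(a, b) = 1 - s(a, b) / sqrt(s(a, a) * s(b, b))` where `s` is the summed
#' substitution-matrix similarity over aligned pseudo-sequence positions.
#' Symmetric, and `d(a, a) = 0`.
#'
#' @param a,b Pseudo-sequence strings of equal length.
#' @param sub Substitution matrix (default BLOSUM50).
#' @return Non-negative distance (0 for identical pseudo-sequences).
#' @export
allele_distance <- function(a, b, sub = blosum50()) {
  if (nchar(a) != nchar(b))
    stop("pseudo-sequences must have equal length")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  s_ab <- sum(sub[cbind(ca, cb)])
  s_aa <- sum(sub[cbind(ca, ca)])
  s_bb <- sum(sub[cbind(cb, cb)])
  1 - s_ab / sqrt(s_aa * s_bb)
}

#' Distance of an MHC molecule to a training set
#'
#' The closest [allele_distance()] to any molecule in the training set.
#'
#' @param a Pseudo-sequence string.
#' @param training Character vector of training pseudo-sequences (non-empty).
#' @param sub Substitution matrix.
#' @export
distance_to_training_set <- function(a, training, sub = blosum50()) {
  if (length(training) == 0)
    stop("training set must be non-empty")
  min(vapply(training, allele_distance, numeric(1), a = a, sub = sub))
}
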