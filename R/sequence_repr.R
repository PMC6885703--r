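#' Task configuration (class I / class II)
#'
#' Bundles the fixed representational choices of a prediction task: the
#' binding-core length (9 for both MHC classes), the allowed peptide length
#' range (8-14 class I, 13-21 class II) and whether class II peptide-flanking
#' region features are added to the input encoding.
#'
#' @param task `"classI"` or `"classII"`.
#' @return List with `task`, `core_len`, `len_min`, `len_max`, `class2`.
#' @export
task_config <- function(task = c("classI", "classII")) {
  task <- match.arg(task)
  if (task == "classI") {
    list(task = task, core_len = 9L, len_min = 8L, len_max = 14L, class2 = FALSE)
  } else {
    list(task = task, core_len = 9L, len_min = 13L, len_max = 21L, class2 = TRUE)
  }
}

#' Enumerate candidate binding cores of a peptide
#'
#' For a peptide of length `L` and core length `k`: `L == k` yields the
#' peptide itself; `L > k` yields one core per contiguous deletion block of
#' `L - k` residues placed at every start position (termini included),
#' deduplicated; `L < k` yields one core per insertion of a wildcard (`X`)
#' stretch of `k - L` at each interior position, deduplicated. The list is
#' deterministic (first occurrence kept).
#'
#' @param peptide Peptide string over the 21-symbol alphabet.
#' @param core_len Core length (default 9).
#' @param len_min,len_max Permitted peptide length bounds.
#' @return data.frame with columns `core`, `deletion_length`, `deletion_start`,
#'   `insertion_length`, `insertion_start` (0-based start offsets).
#' @export
enumerate_cores <- function(peptide, core_len = 9L, len_min = 1L, len_max = 10000L) {
  L <- nchar(peptide)
  if (L < len_min || L > len_max)
    stop("peptide length ", L, " outside bounds [", len_min, ", ", len_max, "]")
  as.data.frame(cpp_enumerate_cores(peptide, as.integer(core_len)),
                stringsAsFactors = FALSE)
}

# Build the flat encoded-input container consumed by the C++ trainer.
# records: data.frame with peptide, target, assay, (optional) allele annotation
#   as index into `alleles`, partition.
# pseudo: named character vector of pseudo-sequences defining the allele space.
encode_dataset <- function(records, pseudo, enc = encoding_matrix(),
                           tcfg = task_config("classI")) {
  validate_pseudosequences(pseudo)
  encd <- cpp_encode_dataset(records$peptide, tcfg$core_len, tcfg$len_min,
                             tcfg$len_max, tcfg$class2, t(enc$values))
  allele_enc <- vapply(pseudo, function(p) {
    idx <- .res_index(strsplit(p, "")[[1]])
    as.vector(t(enc$values[idx, , drop = FALSE]))
  }, numeric(nchar(pseudo[[1]]) * 20L))
  out <- ifelse(records$assay == "EL", 1L, 0L)
  structure(list(
    core_res = encd$core_res, core_aux = encd$core_aux,
    core_off = encd$core_off, n_aux = encd$n_aux, core_len = encd$core_len,
    enc_t = t(enc$values), allele_enc = allele_enc,
    target = as.double(records$target), out = as.integer(out),
    n_rec = nrow(records), n_in = tcfg$core_len * 20L + encd$n_aux +
      nchar(pseudo[[1]]) * 20L,
    allele_names = names(pseudo), peptides = records$peptide,
    tcfg = tcfg
  ), class = "encoded_dataset")
}

# 0-based allele vector for C++ (NA -> -1)
.ra0 <- function(allele_idx) {
  a <- as.integer(allele_idx) - 1L
  a[is.na(a)] <- -1L
  a
}

# residue strings of selected global core indices (0-based) in an encoded set
.core_strings <- function(data, core_idx0) {
  full <- .aa_full()
  k <- data$core_len
  vapply(core_idx0, function(c0) {
    res <- data$core_res[(c0 * k + 1):(c0 * k + k)] + 1L
    paste(full[res], collapse = "")
  }, character(1))
}

#' Encode one (core, allele) example as a numeric input vector
#'
#' Produces the exact fixed-length vector the network consumes:
#' `[core block | auxiliary block | pseudo-sequence block]`. The core block is
#' the per-position residue encoding (wildcard rows are zero), the auxiliary
#' block holds the peptide length one-hot plus insertion/deletion features
#' (and class II flanking features), and the pseudo-sequence block is the
#' per-position encoding of the allele's contact residues.
#'
#' @param core_index Which candidate core of `peptide` (row of
#'   [enumerate_cores()]).
#' @param peptide Peptide string.
#' @param pseudo Pseudo-sequence string of the allele.
#' @param enc Encoding matrix from [encoding_matrix()].
#' @param tcfg Task configuration from [task_config()].
#' @return Numeric vector.
#' @export
encode_example <- function(core_index, peptide, pseudo,
                           enc = encoding_matrix(),
                           tcfg = task_config("classI")) {
  rec <- data.frame(peptide = peptide, target = 0, assay = "EL",
                    stringsAsFactors = FALSE)
  data <- encode_dataset(rec, c(ALLELE = pseudo), enc, tcfg)
  n_cores <- data$core_off[2]
  if (core_index < 1 || core_index > n_cores)
    stop("core_index out of range (peptide has ", n_cores, " cores)")
  k <- data$core_len
  c0 <- core_index - 1L
  res <- data$core_res[(c0 * k + 1):(c0 * k + k)] + 1L
  core_block <- as.vector(t(enc$values[res, , drop = FALSE]))
  aux <- data$core_aux[(c0 * data$n_aux + 1):(c0 * data$n_aux + data$n_aux)]
  c(core_block, aux, data$allele_enc[, 1])
}
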