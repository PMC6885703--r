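#' Construct a peptide dataset
#'
#' The central container: one row per peptide record with its regression /
#' classification target, label (allele name for single-allele data, cell-line
#' id for multi-allele data), assay type, origin, cross-validation partition
#' and current allele annotation.
#'
#' @param peptide Character vector of peptide sequences.
#' @param target Numeric targets in `[0, 1]` (eluted-ligand targets must be 0/1).
#' @param label Allele name (SA) or cell-line id (MA).
#' @param assay `"BA"` or `"EL"` (recycled).
#' @param origin `"SA"` or `"MA"` (recycled).
#' @param partition Optional integer partition (0-based), `NA` if unassigned.
#' @param annotation Optional allele annotation (MA only), `NA` if unassigned.
#' @param tcfg Task configuration ([task_config()]); supplies length bounds.
#' @param length_bounds Optional explicit inclusive length bounds overriding
#'   `tcfg` (e.g. `c(9, 9)` for a 9mer-only dataset).
#' @return A `peptide_dataset` (data.frame subclass) with attributes
#'   `length_bounds` and `task`.
#' @export
peptide_dataset <- function(peptide, target, label, assay = "EL", origin = "SA",
                            partition = NA_integer_, annotation = NA_character_,
                            tcfg = task_config("classI"), length_bounds = NULL) {
  d <- data.frame(peptide = as.character(peptide), target = as.numeric(target),
                  label = as.character(label), assay = rep_len(assay, length(peptide)),
                  origin = rep_len(origin, length(peptide)),
                  partition = rep_len(as.integer(partition), length(peptide)),
                  annotation = rep_len(as.character(annotation), length(peptide)),
                  stringsAsFactors = FALSE)
  if (is.null(length_bounds)) length_bounds <- c(tcfg$len_min, tcfg$len_max)
  attr(d, "length_bounds") <- as.integer(length_bounds)
  attr(d, "task") <- tcfg$task
  class(d) <- c("peptide_dataset", "data.frame")
  validate_dataset(d)
}

length_bounds <- function(d) attr(d, "length_bounds")

validate_dataset <- function(d) {
  stopifnot(all(c("peptide", "target", "label", "assay", "origin") %in% names(d)))
  if (!all(d$assay %in% c("BA", "EL"))) stop("assay must be BA or EL")
  if (!all(d$origin %in% c("SA", "MA"))) stop("origin must be SA or MA")
  if (any(d$target < 0 | d$target > 1, na.rm = TRUE))
    stop("targets must lie in [0, 1]")
  el <- d$assay == "EL"
  if (any(!(d$target[el] %in% c(0, 1))))
    stop("EL targets must be 0 or 1")
  lb <- length_bounds(d)
  len <- nchar(d$peptide)
  if (any(len < lb[1] | len > lb[2]))
    stop("peptide lengths outside bounds [", lb[1], ", ", lb[2], "]")
  invisible(lapply(strsplit(d$peptide, ""), .res_index))
  d
}

# rbind peptide_datasets preserving attributes (bounds widened to cover both)
bind_datasets <- function(...) {
  ds <- list(...)
  ds <- ds[!vapply(ds, is.null, logical(1))]
  lb <- range(unlist(lapply(ds, length_bounds)))
  out <- do.call(rbind, lapply(ds, function(x) as.data.frame(unclass(x))))
  rownames(out) <- NULL
  attr(out, "length_bounds") <- as.integer(lb)
  attr(out, "task") <- attr(ds[[1]], "task")
  class(out) <- c("peptide_dataset", "data.frame")
  out
}

#' Read a peptide table
#'
#' Tab-separated `peptide<TAB>target<TAB>label`. Records whose peptide length
#' falls outside the task bounds are dropped with a message; malformed rows and
#' out-of-range targets are errors.
#'
#' @param path File path.
#' @param assay `"BA"` or `"EL"`.
#' @param origin `"SA"` or `"MA"`.
#' @param tcfg Task configuration.
#' @param quiet Suppress the dropped-record message.
#' @return A [peptide_dataset()].
#' @export
read_peptide_table <- function(path, assay, origin, tcfg = task_config("classI"),
                               quiet = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed row at line ", bad[1], " of ", path)
  pep <- vapply(parts, `[`, character(1), 1L)
  tgt <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(tgt))
    stop("non-numeric target at line ", which(is.na(tgt))[1], " of ", path)
  if (any(tgt < 0 | tgt > 1))
    stop("target outside [0, 1] at line ", which(tgt < 0 | tgt > 1)[1], " of ", path)
  lab <- vapply(parts, `[`, character(1), 3L)
  len <- nchar(pep)
  keep <- len >= tcfg$len_min & len <= tcfg$len_max
  if (any(!keep) && !quiet)
    message("dropped ", sum(!keep), " record(s) outside length bounds")
  peptide_dataset(pep[keep], tgt[keep], lab[keep], assay = assay,
                  origin = origin, tcfg = tcfg)
}

#' Write a prediction table
#'
#' Columns: `peptide, label, annotation, score_EL, score_BA, zscore, partition`.
#'
#' @param x data.frame with (a subset of) those columns.
#' @param path Output path.
#' @export
write_prediction_table <- function(x, path) {
  cols <- c("peptide", "label", "annotation", "score_EL", "score_BA",
            "zscore", "partition")
  for (cn in setdiff(cols, names(x))) x[[cn]] <- NA
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cell-line panel table
#'
#' `cell_line<TAB>comma-separated allele names`. Each allele must be present
#' in the pseudo-sequence table if one is supplied.
#'
#' @param path File path.
#' @param pseudo Optional named pseudo-sequence vector for validation.
#' @return Named list: cell line -> character vector of allele names.
#' @export
read_cell_line_panels <- function(path, pseudo = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed panel row at line ", bad[1])
  panels <- lapply(parts, function(p) trimws(strsplit(p[2], ",")[[1]]))
  names(panels) <- vapply(parts, `[`, character(1), 1L)
  validate_panels(panels, pseudo)
  panels
}

validate_panels <- function(panels, pseudo = NULL) {
  if (any(lengths(panels) < 1L)) stop("every panel needs at least one allele")
  if (!is.null(pseudo)) {
    miss <- setdiff(unique(unlist(panels)), names(pseudo))
    if (length(miss))
      stop("panel alleles missing from pseudo-sequence table: ",
           paste(miss, collapse = ", "))
  }
  invisible(panels)
}

#' Transform an IC50 binding affinity to a [0, 1] training target
#'
#' `1 - log(ic50) / log(50000)`, clipped to `[0, 1]`.
#'
#' @param ic50_nM Positive IC50 value(s) in nM.
#' @export
ba_transform <- function(ic50_nM) {
  if (any(ic50_nM <= 0)) stop("IC50 must be positive")
  pmin(1, pmax(0, 1 - log(ic50_nM) / log(50000)))
}

#' Read a proteome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA files")
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a proteome FASTA
#'
#' @param proteome Named character vector.
#' @param path Output path.
#' @export
write_proteome <- function(proteome, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to write FASTA files")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

# Sample n random substrings of length `len` from a proteome (uniform over all
# valid start positions across proteins). Returns character vector.
sample_natural_peptides <- function(proteome, len, n) {
  plen <- nchar(proteome)
  nstart <- pmax(0L, plen - len + 1L)
  if (sum(nstart) < 1L)
    stop("proteome has no window of length ", len)
  pidx <- sample.int(length(proteome), n, replace = TRUE,
                     prob = nstart / sum(nstart))
  starts <- 1L + floor(stats::runif(n) * nstart[pidx])
  substr(rep(unname(proteome[pidx]), 1L), starts, starts + len - 1L)
}

#' Enrich an eluted-ligand dataset with random natural negatives
#'
#' For each label (individual dataset) and for every length within the
#' dataset's bounds, appends exactly `5 x` (count of the most abundant positive
#' length for that label) uniformly sampled proteome substrings with target 0.
#' Sampling is without replacement within a (label, length) stratum;
#' collisions with same-label positives are resampled.
#'
#' @param positives A `peptide_dataset` of EL positives (target 1).
#' @param proteome Named character vector of protein sequences.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param factor Enrichment factor (default 5).
#' @return The dataset with negatives appended.
#' @export
enrich_negatives <- function(positives, proteome, seed, factor = 5L) {
  if (nrow(positives) == 0) stop("positive set must be non-empty")
  lb <- length_bounds(positives)
  lengths_all <- lb[1]:lb[2]
  withr::with_seed(as.integer(seed), {
    out <- list(as.data.frame(unclass(positives)))
    for (lab in unique(positives$label)) {
      pos <- positives[positives$label == lab, ]
      n_per_len <- factor * max(table(factor(nchar(pos$peptide),
                                             levels = lengths_all)))
      pos_seqs <- unique(pos$peptide)
      for (len in lengths_all) {
        got <- character(0)
        tries <- 0L
        while (length(got) < n_per_len && tries < 50L) {
          cand <- sample_natural_peptides(proteome, len,
                                          2L * (n_per_len - length(got)))
          cand <- setdiff(unique(cand), c(pos_seqs, got))
          got <- c(got, utils::head(cand, n_per_len - length(got)))
          tries <- tries + 1L
        }
        if (length(got) < n_per_len)
          stop("could not sample ", n_per_len, " unique negatives of length ", len)
        out[[length(out) + 1L]] <- data.frame(
          peptide = got, target = 0, label = lab,
          assay = "EL", origin = pos$origin[1],
          partition = NA_integer_, annotation = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "length_bounds") <- lb
  attr(res, "task") <- attr(positives, "task")
  class(res) <- c("peptide_dataset", "data.frame")
  res
}

#' Remove SA records duplicated in MA data
#'
#' Every SA record whose peptide sequence occurs anywhere in the MA data is
#' removed (exact sequence identity, irrespective of label); the MA data is
#' left untouched.
#'
#' @param sa,ma `peptide_dataset`s.
#' @return The filtered SA dataset.
#' @export
dedupe_sa_vs_ma <- function(sa, ma) {
  keep <- !(sa$peptide %in% unique(ma$peptide))
  out <- sa[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "length_bounds") <- length_bounds(sa)
  attr(out, "task") <- attr(sa, "task")
  class(out) <- class(sa)
  out
}
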