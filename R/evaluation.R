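#' Area under the ROC curve
#'
#' Mann-Whitney formulation with average ranks, so tied scores count 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Partial AUC to false-positive rate 0.1
#'
#' Area under the ROC curve for FPR in `[0, 0.1]`, normalized by 0.1 so a
#' perfect classifier scores 1 (a random one about 0.05). Tied scores advance
#' the curve diagonally; the curve is interpolated linearly at FPR = 0.1.
#'
#' @inheritParams auc
#' @param fpr_max Upper false-positive-rate bound (default 0.1).
#' @return Normalized partial AUC in `[0, 1]`.
#' @export
auc01 <- function(scores, labels, fpr_max = 0.1) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(!duplicated(s)) # distinct-score groups, descending
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- which(!duplicated(grp, fromLast = TRUE)) # end of each tie group
  fpr <- c(0, fp[last] / n_neg)
  tpr <- c(0, tp[last] / n_pos)
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) { # interpolate at the cutoff
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area / fpr_max
}

#' In-silico digestion of a protein
#'
#' All overlapping substrings of the given lengths, deduplicated by sequence
#' (first occurrence kept).
#'
#' @param antigen Protein sequence string.
#' @param lengths Integer vector of peptide lengths (8:14 for class I; the
#'   epitope's own length for class II).
#' @return Character vector of unique peptides.
#' @export
digest_protein <- function(antigen, lengths = 8:14) {
  L <- nchar(antigen)
  peps <- unlist(lapply(lengths, function(k) {
    if (L < k) return(character(0))
    substring(antigen, 1:(L - k + 1), k:L)
  }))
  unique(peps)
}

#' Frank score of an epitope
#'
#' The source protein is digested into overlapping peptides
#' ([digest_protein()]); the Frank score is the proportion of digested
#' peptides (the epitope excluded from the denominator) whose prediction
#' score is strictly greater than the epitope's. 0 means the epitope is
#' top-ranked; the expectation under random scoring is 0.5.
#'
#' @param epitope Epitope sequence (must occur in `antigen`).
#' @param antigen Source protein sequence.
#' @param scorer Function `f(peptides) -> scores`, or a named numeric vector
#'   of precomputed scores covering all digested peptides.
#' @param lengths Digestion lengths.
#' @return Frank score in `[0, 1]`.
#' @export
frank_score <- function(epitope, antigen, scorer, lengths = 8:14) {
  peps <- digest_protein(antigen, lengths)
  if (!epitope %in% peps)
    stop("epitope does not occur in the antigen at a digested length")
  scores <- if (is.function(scorer)) scorer(peps) else {
    if (!all(peps %in% names(scorer))) stop("scores missing for some peptides")
    unname(scorer[peps])
  }
  e <- match(epitope, peps)
  sum(scores[-e] > scores[e]) / (length(peps) - 1)
}

#' Concatenated cross-validation evaluation
#'
#' Out-of-fold predictions of every eluted-ligand record are concatenated and
#' an AUC / AUC0.1 pair is computed per label. Multi-allele records are scored
#' as the maximum prediction over the alleles of their cell line. Labels with
#' a single class are skipped with a message.
#'
#' @param model An `ma_model`.
#' @return data.frame: `label`, `origin`, `n_pos`, `n_neg`, `auc`, `auc01`.
#' @export
evaluate_concatenated <- function(model) {
  records <- model$records
  data <- encode_dataset(records, model$pseudo, model$enc, model$tcfg)
  el <- which(records$assay == "EL")
  out <- list()
  for (lab in unique(records$label[el])) {
    idx <- el[records$label[el] == lab]
    y <- records$target[idx]
    if (length(unique(y)) < 2) {
      message("skipping label ", lab, ": single class")
      next
    }
    alleles <- if (records$origin[idx[1]] == "MA") sort(model$panels[[lab]]) else lab
    m <- vapply(alleles, function(a)
      oof_scores_model(model, idx, a, "EL", data), numeric(length(idx)))
    sc <- apply(matrix(m, nrow = length(idx)), 1, max)
    out[[lab]] <- data.frame(label = lab, origin = records$origin[idx[1]],
                             n_pos = sum(y == 1), n_neg = sum(y == 0),
                             auc = auc(sc, y), auc01 = auc01(sc, y),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-allele Pearson correlation on binding-affinity data
#'
#' Concatenated out-of-fold BA predictions against the transformed targets.
#'
#' @param model An `ma_model`.
#' @return data.frame: `allele`, `n`, `pcc`.
#' @export
ba_correlation <- function(model) {
  records <- model$records
  data <- encode_dataset(records, model$pseudo, model$enc, model$tcfg)
  ba <- which(records$assay == "BA")
  out <- list()
  for (a in unique(records$label[ba])) {
    idx <- ba[records$label[ba] == a]
    if (length(idx) < 3) next
    sc <- oof_scores_model(model, idx, a, "BA", data)
    out[[a]] <- data.frame(allele = a, n = length(idx),
                           pcc = stats::cor(sc, records$target[idx]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positive predictive value per deconvoluted motif
#'
#' For one cell line: `N` is the number of ligands annotated to each allele;
#' all records of the cell line (positives and enriched negatives) are ranked
#' by their out-of-fold score against that allele, and the PPV is the fraction
#' of true ligands among the top `floor(N * 0.95)` predictions (the 5%
#' tolerance absorbs expected noise in eluted-ligand data). Alleles with
#' `N = 0` are skipped with a message.
#'
#' @param model An `ma_model`.
#' @param cell_line MA label to evaluate.
#' @param tolerance Fraction of `N` kept (default 0.95).
#' @return data.frame: `allele`, `n_assigned`, `n_top`, `ppv`.
#' @export
ppv_per_motif <- function(model, cell_line, tolerance = 0.95) {
  records <- model$records
  ann <- model$annotation
  idx <- which(records$origin == "MA" & records$label == cell_line)
  if (!length(idx)) stop("unknown cell line: ", cell_line)
  data <- encode_dataset(records, model$pseudo, model$enc, model$tcfg)
  alleles <- sort(model$panels[[cell_line]])
  out <- list()
  for (a in alleles) {
    N <- sum(ann$label == cell_line & ann$target == 1 &
               ann$annotation == a, na.rm = TRUE)
    if (N == 0) {
      message("allele ", a, ": no assigned ligands, skipped")
      next
    }
    sc <- oof_scores_model(model, idx, a, "EL", data)
    out[[a]] <- data.frame(allele = a, n_assigned = N,
                           n_top = floor(N * tolerance),
                           ppv = ppv(sc, records$target[idx] == 1, N, tolerance),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-epitope Frank report
#'
#' Computes the Frank score of each epitope against its stated restriction,
#' digesting the source antigen into overlapping 8-14mers (class I) or
#' epitope-length windows (class II).
#'
#' @param model An `ma_model` (or any scorer accepted via `scorer`).
#' @param epitopes data.frame with columns `epitope`, `antigen_id`, `allele`.
#' @param antigens Named character vector of antigen sequences.
#' @param scorer Optional function `f(peptides, allele) -> scores` overriding
#'   the model.
#' @return The epitope table with a `frank` column and the digested pool size.
#' @export
frank_report <- function(model, epitopes, antigens, scorer = NULL) {
  stopifnot(all(c("epitope", "antigen_id", "allele") %in% names(epitopes)))
  miss <- setdiff(unique(epitopes$antigen_id), names(antigens))
  if (length(miss)) stop("antigen(s) missing: ", paste(miss, collapse = ", "))
  if (is.null(scorer))
    scorer <- function(peptides, allele)
      predict_peptides(model, peptides, allele, "EL")
  class2 <- !is.null(model$tcfg) && isTRUE(model$tcfg$class2)
  out <- epitopes
  out$n_digested <- NA_integer_
  out$frank <- NA_real_
  for (i in seq_len(nrow(epitopes))) {
    ant <- antigens[[epitopes$antigen_id[i]]]
    lens <- if (class2) nchar(epitopes$epitope[i]) else 8:14
    peps <- digest_protein(ant, lens)
    out$n_digested[i] <- length(peps)
    out$frank[i] <- frank_score(epitopes$epitope[i], ant,
                                function(p) scorer(p, epitopes$allele[i]),
                                lens)
  }
  out
}

#' Positive predictive value at an assigned-ligand cutoff
#'
#' Ranks all records by score and reports the fraction of true ligands among
#' the top `floor(n_assigned * tolerance)`.
#'
#' @param scores Numeric scores.
#' @param labels Binary ligand labels.
#' @param n_assigned The motif's assigned-ligand count `N`.
#' @param tolerance Fraction of `N` kept (default 0.95).
#' @export
ppv <- function(scores, labels, n_assigned, tolerance = 0.95) {
  n_top <- floor(n_assigned * tolerance)
  if (n_top < 1) stop("n_assigned too small for the requested tolerance")
  labels <- as.integer(as.logical(labels))
  mean(labels[order(scores, decreasing = TRUE)][seq_len(n_top)] == 1)
}

# position x residue frequency + KL matrices from core strings
motif_from_cores <- function(cores, allele = NA_character_, support_min = 20L,
                             mode = NA_character_) {
  res <- aa_alphabet()$residues
  k <- nchar(cores[1])
  mat <- do.call(rbind, strsplit(cores, ""))
  freq <- matrix(0, k, 20, dimnames = list(NULL, res))
  kl <- freq
  for (p in seq_len(k)) {
    obs <- mat[, p]
    obs <- obs[obs != "X"]
    n <- length(obs)
    cnt <- table(factor(obs, levels = res))
    # flat pseudocount with weight 1/(n+1)
    f <- (as.numeric(cnt) + 1 / 20) / (n + 1)
    freq[p, ] <- f
    ic <- log2(20) + sum(f * log2(f))
    kl[p, ] <- ic * f
  }
  m <- list(allele = allele, freq = freq, kl = kl,
            support = length(cores), mode = mode,
            low_support = length(cores) < support_min)
  class(m) <- "mhc_motif"
  m
}

#' Construct a binding motif from a trained model
#'
#' `random_top` mode scores `n_random` random natural peptides (9mers class I,
#' 15mers class II) against the allele and builds the motif from the
#' ensemble-selected binding cores of the top `top_frac` fraction (the
#' default 0.1% of 200,000 gives a support of 200). `annotated_ligands` mode
#' uses the out-of-fold predicted cores of the multi-allele ligands currently
#' annotated to the allele.
#'
#' @param model An `ma_model`.
#' @param allele Allele name.
#' @param mode `"random_top"` or `"annotated_ligands"`.
#' @param proteome Required for `random_top`.
#' @param n_random,top_frac Random-peptide mode parameters.
#' @param seed Seed for the random-peptide draw.
#' @param support_min Below this support the motif is flagged low-support.
#' @return An `mhc_motif`: `freq` (core_len x 20 row-stochastic matrix), `kl`
#'   (KL-weighted matrix), `support`, `low_support`.
#' @export
build_motif <- function(model, allele, mode = c("random_top", "annotated_ligands"),
                        proteome = NULL, n_random = 200000L, top_frac = 0.001,
                        seed = 1L, support_min = 20L) {
  mode <- match.arg(mode)
  if (mode == "random_top") {
    if (is.null(proteome)) stop("proteome required for random_top mode")
    len <- if (model$tcfg$class2) 15L else model$tcfg$core_len
    peps <- withr::with_seed(as.integer(seed),
                             sample_natural_peptides(proteome, len, n_random))
    d <- encode_dataset(data.frame(peptide = peps, target = 0, assay = "EL",
                                   stringsAsFactors = FALSE),
                        model$pseudo, model$enc, model$tcfg)
    a1 <- match(allele, names(model$pseudo))
    if (is.na(a1)) stop("unknown allele: ", allele)
    cs <- 0
    for (net in model$nets)
      cs <- cs + cpp_predict_cores(net$W1, net$b1, net$W2, net$b2, d,
                                   seq_len(d$n_rec) - 1L,
                                   rep(a1 - 1L, d$n_rec), 1L)
    cs <- cs / length(model$nets)
    off <- d$core_off
    score <- numeric(d$n_rec)
    core0 <- integer(d$n_rec)
    for (r in seq_len(d$n_rec)) {
      seg <- cs[(off[r] + 1L):off[r + 1L]]
      k <- which.max(seg)
      score[r] <- seg[k]
      core0[r] <- off[r] + k - 1L
    }
    top <- order(score, decreasing = TRUE)[seq_len(ceiling(n_random * top_frac))]
    cores <- .core_strings(d, core0[top])
  } else {
    ma_rows <- which(model$records$origin == "MA")
    keep <- ma_rows[model$annotation$annotation %in% allele &
                      model$annotation$target == 1]
    if (!length(keep)) stop("no ligands annotated to ", allele)
    pr <- oof_scores_model(model, keep, allele, "EL", return_cores = TRUE)
    cores <- .core_strings(pr$data, pr$core)
  }
  motif_from_cores(cores, allele, support_min, mode)
}

#' Pearson correlation between two motifs
#'
#' Correlation of the flattened core_len x 20 frequency matrices.
#'
#' @param a,b `mhc_motif` objects or bare position x residue matrices of
#'   equal dimensions.
#' @return PCC in `[-1, 1]`.
#' @export
motif_pcc <- function(a, b) {
  ma <- if (inherits(a, "mhc_motif")) a$freq else a
  mb <- if (inherits(b, "mhc_motif")) b$freq else b
  if (!all(dim(ma) == dim(mb))) stop("motif dimensions differ")
  va <- as.vector(ma); vb <- as.vector(mb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero-variance motif: correlation undefined")
  stats::cor(va, vb)
}

#' Write a motif matrix as TSV
#'
#' @param motif An `mhc_motif`.
#' @param path Output path.
#' @param what `"freq"` or `"kl"`.
#' @export
write_motif <- function(motif, path, what = c("freq", "kl")) {
  what <- match.arg(what)
  m <- motif[[what]]
  df <- data.frame(position = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-panel locus shares of annotated ligands
#'
#' For each cell line, the fraction of positive records annotated to an
#' allele of each locus. Fractions sum to 1 per panel.
#'
#' @param annotation data.frame with `label`, `target`, `annotation` (e.g.
#'   `model$annotation`).
#' @param panels Named list of panels.
#' @param locus_map Named character vector allele -> locus.
#' @return Matrix (panels x loci) of shares.
#' @export
locus_shares <- function(annotation, panels, locus_map) {
  pos <- annotation[annotation$target == 1 & !is.na(annotation$annotation), ]
  miss <- setdiff(unique(pos$annotation), names(locus_map))
  if (length(miss))
    stop("allele(s) missing from locus map: ", paste(miss, collapse = ", "))
  loci <- sort(unique(locus_map))
  labs <- names(panels)
  m <- matrix(0, length(labs), length(loci), dimnames = list(labs, loci))
  for (lab in labs) {
    sub <- pos[pos$label == lab, ]
    if (!nrow(sub)) next
    t <- table(factor(locus_map[sub$annotation], levels = loci))
    m[lab, ] <- as.numeric(t) / nrow(sub)
  }
  m
}
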