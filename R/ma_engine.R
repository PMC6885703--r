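#' Training configuration for the semi-supervised MA loop
#'
#' Defaults follow the class I setting: ensembles over hidden sizes \{56, 66\}
#' with 5 seeds each and 5 cross-validation folds, learning rate 0.05, 200
#' iterations with early stopping, burn-in 20, and score rescaling with the
#' sigmoid blending schedule (shift 75, scale 10) estimated from 10,000 random
#' natural 9mers. Class II uses hidden sizes \{2, 10, 20, 40, 60\}, 10 seeds,
#' 400 iterations without early stopping. Tests and desk-scale runs shrink the
#' ensemble via these fields.
#'
#' @param task `"classI"` or `"classII"`.
#' @param hidden_sizes,seeds_per_size,n_parts Ensemble layout.
#' @param lr Learning rate.
#' @param n_iter Training iterations (epochs).
#' @param burn_in Iterations trained on single-allele data only.
#' @param early_stopping Keep best stop-set snapshots.
#' @param rescale Use z-score rescaling for MA annotation (raw scores if
#'   `FALSE`).
#' @param shift,scale Blending schedule parameters ([blend_weight()]).
#' @param n_random_rescale Random natural peptides per score-distribution
#'   estimate.
#' @param motif_len Common-motif partitioning length (8 class I, 9 class II).
#' @param seed Master seed; all internal seeds derive from it.
#' @return List of class `ma_config`.
#' @export
ma_config <- function(task = "classI",
                      hidden_sizes = if (task == "classI") c(56L, 66L)
                                     else c(2L, 10L, 20L, 40L, 60L),
                      seeds_per_size = if (task == "classI") 5L else 10L,
                      n_parts = 5L,
                      lr = 0.05,
                      n_iter = if (task == "classI") 200L else 400L,
                      burn_in = 20L,
                      early_stopping = (task == "classI"),
                      rescale = TRUE,
                      shift = 75, scale = 10,
                      n_random_rescale = 10000L,
                      motif_len = if (task == "classI") 8L else 9L,
                      seed = 1L) {
  stopifnot(burn_in < n_iter, lr > 0, scale > 0, n_parts >= 2)
  cfg <- list(task = task, hidden_sizes = as.integer(hidden_sizes),
              seeds_per_size = as.integer(seeds_per_size),
              n_parts = as.integer(n_parts), lr = lr,
              n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              early_stopping = early_stopping, rescale = rescale,
              shift = shift, scale = scale,
              n_random_rescale = as.integer(n_random_rescale),
              motif_len = as.integer(motif_len), seed = as.integer(seed))
  class(cfg) <- "ma_config"
  cfg
}

#' Annotate multi-allele records to single alleles
#'
#' Each positive MA record is assigned the panel allele with the highest
#' (rescaled) eluted-ligand score: `z = (p - p') / sigma'` when rescaling
#' statistics are supplied, the raw score otherwise. Ties go to the
#' lexicographically smallest allele name. Each negative record is assigned a
#' uniformly random allele of its panel.
#'
#' @param scorer Function `f(peptides, allele) -> scores` or an `ma_model`.
#' @param ma A `peptide_dataset` of MA records.
#' @param panels Named list: cell line -> allele names.
#' @param stats Optional data.frame with `allele`, `p_bar`, `sigma` (from
#'   [estimate_score_distribution()]); blended via [blend_stats()] at
#'   `iteration`.
#' @param iteration Iteration index used for the blending schedule.
#' @param seed Seed for the random annotation of negatives.
#' @param shift,scale Blending schedule parameters.
#' @return data.frame: `peptide`, `label`, `target`, `annotation`, `score`
#'   (z or raw scale).
#' @export
annotate_ma <- function(scorer, ma, panels, stats = NULL, iteration = 0,
                        seed = 1L, shift = 75, scale = 10) {
  miss <- setdiff(unique(ma$label), names(panels))
  if (length(miss)) stop("no panel for label(s): ", paste(miss, collapse = ", "))
  sfun <- if (is.function(scorer)) scorer else
    function(peptides, allele) predict_peptides(scorer, peptides, allele, "EL")
  if (!is.null(stats)) stats <- blend_stats(stats, iteration, shift, scale)
  ann <- rep(NA_character_, nrow(ma))
  sc <- rep(NA_real_, nrow(ma))
  for (lab in unique(ma$label)) {
    alleles <- sort(panels[[lab]])
    pos <- which(ma$label == lab & ma$target == 1)
    neg <- which(ma$label == lab & ma$target == 0)
    if (length(pos)) {
      m <- vapply(alleles, function(a) {
        p <- sfun(ma$peptide[pos], a)
        if (is.null(stats)) p else {
          i <- match(a, stats$allele)
          if (is.na(i)) stop("no rescaling stats for allele ", a)
          (p - stats$p_prime[i]) / stats$sigma_prime[i]
        }
      }, numeric(length(pos)))
      m <- matrix(m, nrow = length(pos))
      best <- max.col(m, ties.method = "first")
      ann[pos] <- alleles[best]
      sc[pos] <- m[cbind(seq_along(pos), best)]
    }
    if (length(neg)) {
      ann[neg] <- withr::with_seed(.derive_seed(seed, match(lab, names(panels))),
        alleles[sample.int(length(alleles), length(neg), replace = TRUE)])
    }
  }
  data.frame(peptide = ma$peptide, label = ma$label, target = ma$target,
             annotation = ann, score = sc, stringsAsFactors = FALSE)
}

#' Train the semi-supervised multi-allele deconvolution model
#'
#' Implements the full training loop: a burn-in phase on single-allele data
#' only; then, in every subsequent iteration, per-allele score distributions
#' are re-estimated on random natural peptides, every multi-allele record is
#' annotated to one allele of its cell-line panel via rescaled eluted-ligand
#' scores (out-of-fold models only), the annotated MA data are merged with the
#' SA data respecting the cross-validation partitioning, and each network is
#' trained for one further epoch. Fully reproducible from the configuration
#' seed.
#'
#' @param sa Single-allele `peptide_dataset` (BA and/or EL records; non-empty).
#' @param ma Multi-allele `peptide_dataset` (may be `NULL`/empty).
#' @param panels Named list mapping each MA label to its candidate alleles.
#' @param pseudo Named pseudo-sequence vector covering all alleles.
#' @param config An [ma_config()].
#' @param proteome Named character vector used to draw the random natural
#'   peptides for score rescaling (required when MA data are present and
#'   rescaling is enabled).
#' @param enc Encoding matrix.
#' @param sa_only Drop all MA records before training (the single-allele
#'   reference model; identical trajectory to passing empty `ma`).
#' @param score_bias Optional named numeric vector (allele -> additive bias)
#'   applied to raw eluted-ligand scores during MA annotation and during the
#'   score-distribution estimation. A benchmarking hook that emulates an
#'   allele with a depressed score distribution (an MHC molecule far from the
#'   single-allele training data): z-score rescaling is invariant to such a
#'   shift, raw-score annotation is not.
#' @param verbose Print one line per iteration.
#' @return An object of class `ma_model`: ensemble networks, final annotation
#'   state, per-iteration training log, configuration and inputs needed for
#'   downstream evaluation.
#' @export
ma_deconvolute <- function(sa, ma = NULL, panels = list(), pseudo,
                           config = ma_config(), proteome = NULL,
                           enc = encoding_matrix(), sa_only = FALSE,
                           score_bias = NULL, verbose = FALSE) {
  tcfg <- task_config(config$task)
  if (is.null(sa) || nrow(sa) == 0) stop("SA data must be non-empty")
  if (!is.null(ma) && nrow(ma) == 0) ma <- NULL
  if (!is.null(ma)) {
    validate_panels(panels, pseudo)
    miss <- setdiff(unique(ma$label), names(panels))
    if (length(miss)) stop("no panel for MA label(s): ", paste(miss, collapse = ", "))
  }
  miss_sa <- setdiff(unique(sa$label), names(pseudo))
  if (length(miss_sa))
    stop("SA allele(s) missing from pseudo-sequence table: ",
         paste(miss_sa, collapse = ", "))
  records <- bind_datasets(sa, ma)
  if (anyNA(records$partition))
    records <- common_motif_partition(records, config$motif_len,
                                      config$n_parts, config$seed)
  if (sa_only) {
    records <- records[records$origin == "SA", , drop = FALSE]
    rownames(records) <- NULL
    ma <- NULL
  }
  data <- encode_dataset(records, pseudo, enc, tcfg)
  rec_allele <- ifelse(records$origin == "SA",
                       match(records$label, names(pseudo)), NA_integer_)
  part <- records$partition
  is_ma <- records$origin == "MA"
  ma_alleles <- sort(unique(unlist(panels[unique(records$label[is_ma])])))
  use_rescale <- config$rescale && any(is_ma)

  # random natural peptides for score-distribution estimation (drawn once)
  rand_data <- NULL
  if (use_rescale) {
    if (is.null(proteome)) stop("proteome required for score rescaling")
    peps <- withr::with_seed(.derive_seed(config$seed, 77),
      sample_natural_peptides(proteome, tcfg$core_len, config$n_random_rescale))
    rand_data <- encode_dataset(
      data.frame(peptide = peps, target = 0, assay = "EL",
                 stringsAsFactors = FALSE), pseudo, enc, tcfg)
  }

  # ensemble layout
  grid <- expand.grid(fold = seq_len(config$n_parts) - 1L,
                      rep = seq_len(config$seeds_per_size),
                      hidden = config$hidden_sizes)
  nets <- lapply(seq_len(nrow(grid)), function(i)
    new_network(data$n_in, grid$hidden[i],
                .derive_seed(config$seed, grid$hidden[i], grid$rep[i],
                             grid$fold[i])))
  net_seeds <- vapply(nets, function(n) n$seed, integer(1))
  best_err <- rep(Inf, length(nets))
  best_nets <- vector("list", length(nets))
  fold_nets <- split(seq_along(nets), grid$fold) # names "0".."k-1"

  oof_score <- function(d, rec_idx, allele_idx1, f) {
    # mean EL score over the nets whose held-out fold is f
    ids <- fold_nets[[as.character(f)]]
    s <- 0
    for (i in ids)
      s <- s + predict_net(nets[[i]], d, rec_idx,
                           rep(allele_idx1, length(rec_idx)), "EL")$score
    s <- s / length(ids)
    if (!is.null(score_bias)) {
      b <- score_bias[names(pseudo)[allele_idx1]]
      if (!is.na(b)) s <- s + as.numeric(b)
    }
    s
  }

  log <- vector("list", config$n_iter)
  ann_state <- NULL
  for (it in seq_len(config$n_iter)) {
    w_it <- blend_weight(it, config$shift, config$scale)
    if (any(is_ma) && it > config$burn_in) {
      for (f in seq_len(config$n_parts) - 1L) {
        stats_f <- NULL
        if (use_rescale) {
          stats_f <- data.frame(allele = ma_alleles,
                                p_bar = NA_real_, sigma = NA_real_)
          for (k in seq_along(ma_alleles)) {
            a1 <- match(ma_alleles[k], names(pseudo))
            sc <- oof_score(rand_data, seq_len(rand_data$n_rec), a1, f)
            fit <- fit_trimmed_normal(sc)
            stats_f$p_bar[k] <- fit$p_bar
            stats_f$sigma[k] <- fit$sigma
          }
          stats_f <- blend_stats(stats_f, it, config$shift, config$scale)
        }
        for (lab in unique(records$label[is_ma & part == f])) {
          alleles <- sort(panels[[lab]])
          pos <- which(is_ma & part == f & records$label == lab &
                         records$target == 1)
          if (!length(pos)) next
          m <- matrix(NA_real_, length(pos), length(alleles))
          for (k in seq_along(alleles)) {
            a1 <- match(alleles[k], names(pseudo))
            p <- oof_score(data, pos, a1, f)
            m[, k] <- if (use_rescale) {
              i <- match(alleles[k], stats_f$allele)
              (p - stats_f$p_prime[i]) / stats_f$sigma_prime[i]
            } else p
          }
          best <- max.col(m, ties.method = "first")
          rec_allele[pos] <- match(alleles[best], names(pseudo))
        }
      }
      # negatives: re-randomized to a panel allele each round
      withr::with_seed(.derive_seed(config$seed, 31, it), {
        for (lab in unique(records$label[is_ma])) {
          alleles <- sort(panels[[lab]])
          neg <- which(is_ma & records$label == lab & records$target == 0)
          rec_allele[neg] <- match(
            alleles[sample.int(length(alleles), length(neg), replace = TRUE)],
            names(pseudo))
        }
      })
    }
    errs <- rep(NA_real_, length(nets))
    for (i in seq_along(nets)) {
      f <- grid$fold[i]
      idx <- which(part != f & !is.na(rec_allele))
      nets[[i]] <- epoch_step(nets[[i]], data, idx, rec_allele, config$lr,
                              .derive_seed(net_seeds[i], it))
      stop_idx <- which(part == f & !is.na(rec_allele))
      if (length(stop_idx)) {
        errs[i] <- stop_error(nets[[i]], data, stop_idx, rec_allele)
        if (config$early_stopping && errs[i] < best_err[i]) {
          best_err[i] <- errs[i]
          best_nets[[i]] <- nets[[i]]
        }
      }
    }
    n_ann <- sum(is_ma & !is.na(rec_allele))
    log[[it]] <- data.frame(iteration = it, w = w_it,
                            n_ma_annotated = n_ann,
                            stop_error = mean(errs, na.rm = TRUE))
    if (verbose)
      message(sprintf("iter %3d  w=%.4f  ma_annotated=%d  stop_err=%.5f",
                      it, w_it, n_ann, mean(errs, na.rm = TRUE)))
  }
  final_nets <- nets
  if (config$early_stopping)
    for (i in seq_along(nets))
      if (!is.null(best_nets[[i]])) final_nets[[i]] <- best_nets[[i]]

  ann_state <- data.frame(peptide = records$peptide, label = records$label,
                          target = records$target, origin = records$origin,
                          partition = part,
                          annotation = ifelse(is.na(rec_allele), NA_character_,
                                              names(pseudo)[rec_allele]),
                          stringsAsFactors = FALSE)
  model <- list(nets = final_nets, stop_fold = grid$fold,
                hidden = grid$hidden, config = config, pseudo = pseudo,
                enc = enc, tcfg = tcfg, panels = panels,
                records = records, rec_allele = rec_allele,
                annotation = ann_state[is_ma, , drop = FALSE],
                log = do.call(rbind, log))
  class(model) <- "ma_model"
  model
}

#' @export
print.ma_model <- function(x, ...) {
  cat("ma_model:", length(x$nets), "networks (",
      paste(unique(x$hidden), collapse = "/"), "hidden ),",
      x$config$n_parts, "folds,", x$config$n_iter, "iterations\n")
  cat("  alleles:", length(x$pseudo), " MA records:", nrow(x$annotation), "\n")
  invisible(x)
}

#' Score peptides with a trained model
#'
#' Ensemble-mean max-core prediction of every peptide against one allele.
#'
#' @param model An `ma_model`.
#' @param peptides Character vector.
#' @param allele Allele name present in the model's pseudo-sequence table.
#' @param output `"EL"` or `"BA"`.
#' @return Numeric score vector.
#' @export
predict_peptides <- function(model, peptides, allele, output = "EL") {
  a1 <- match(allele, names(model$pseudo))
  if (is.na(a1)) stop("unknown allele: ", allele)
  d <- encode_dataset(data.frame(peptide = peptides, target = 0,
                                 assay = output, stringsAsFactors = FALSE),
                      model$pseudo, model$enc, model$tcfg)
  s <- 0
  for (net in model$nets)
    s <- s + predict_net(net, d, seq_len(d$n_rec),
                         rep(a1, d$n_rec), output)$score
  s / length(model$nets)
}

# out-of-fold ensemble-mean scores for rows of model$records against an allele
oof_scores_model <- function(model, rec_idx, allele, output = "EL",
                             data = NULL, return_cores = FALSE) {
  if (is.null(data))
    data <- encode_dataset(model$records, model$pseudo, model$enc, model$tcfg)
  a1 <- match(allele, names(model$pseudo))
  if (is.na(a1)) stop("unknown allele: ", allele)
  part <- model$records$partition
  out <- numeric(length(rec_idx))
  cores <- integer(length(rec_idx))
  oidx <- .out_idx(output)
  for (f in unique(part[rec_idx])) {
    sel <- which(part[rec_idx] == f)
    ids <- which(model$stop_fold == f)
    if (!length(ids)) stop("no model held out for fold ", f)
    if (return_cores) {
      # ensemble-mean score of every candidate core, then argmax
      cs <- 0
      for (i in ids) {
        net <- model$nets[[i]]
        cs <- cs + cpp_predict_cores(net$W1, net$b1, net$W2, net$b2, data,
                                     as.integer(rec_idx[sel]) - 1L,
                                     rep(a1 - 1L, length(sel)), oidx)
      }
      cs <- cs / length(ids)
      off <- data$core_off
      pos <- 1L
      for (j in seq_along(sel)) {
        r <- rec_idx[sel[j]]
        nc <- off[r + 1L] - off[r]
        seg <- cs[pos:(pos + nc - 1L)]
        k <- which.max(seg)
        out[sel[j]] <- seg[k]
        cores[sel[j]] <- off[r] + k - 1L # 0-based global core index
        pos <- pos + nc
      }
    } else {
      acc <- 0
      for (i in ids) {
        pr <- predict_net(model$nets[[i]], data, rec_idx[sel],
                          rep(a1, length(sel)), output)
        acc <- acc + pr$score
      }
      out[sel] <- acc / length(ids)
    }
  }
  if (return_cores) list(score = out, core = cores, data = data) else out
}
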