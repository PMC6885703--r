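#' Initialize a network
#'
#' One hidden layer, logistic activations throughout, and two output neurons
#' sharing the input->hidden weights: output 1 predicts the binding-affinity
#' target, output 2 the eluted-ligand likelihood. Weights are initialized
#' uniform(-0.1, 0.1) from `seed`.
#'
#' @param n_in Input dimensionality (see [encode_example()]).
#' @param n_hidden Hidden-layer size.
#' @param seed Integer seed.
#' @return An object of class `mhc_net` (list of weight arrays).
#' @export
new_network <- function(n_in, n_hidden, seed) {
  withr::with_seed(as.integer(seed), {
    net <- list(
      W1 = matrix(stats::runif(n_in * n_hidden, -0.1, 0.1), n_in, n_hidden),
      b1 = stats::runif(n_hidden, -0.1, 0.1),
      W2 = matrix(stats::runif(n_hidden * 2, -0.1, 0.1), n_hidden, 2),
      b2 = stats::runif(2, -0.1, 0.1),
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      seed = as.integer(seed))
  })
  class(net) <- "mhc_net"
  net
}

.out_idx <- function(output) {
  output <- match.arg(output, c("BA", "EL"))
  if (output == "BA") 0L else 1L
}

# low-level max-core prediction on an encoded dataset
predict_net <- function(net, data, rec_idx, allele_idx, output = "EL") {
  r <- cpp_predict(net$W1, net$b1, net$W2, net$b2, data,
                   as.integer(rec_idx) - 1L, .ra0(allele_idx),
                   .out_idx(output))
  list(score = r$score, core = r$core) # core is a 0-based global core index
}

# one SGD epoch over record indices `idx` (1-based), shuffled with `shuffle_seed`
epoch_step <- function(net, data, idx, rec_allele, lr, shuffle_seed) {
  ord <- withr::with_seed(as.integer(shuffle_seed), sample(idx))
  upd <- cpp_epoch(net$W1, net$b1, net$W2, net$b2, data,
                   as.integer(ord) - 1L, .ra0(rec_allele), lr)
  net[c("W1", "b1", "W2", "b2")] <- upd[c("W1", "b1", "W2", "b2")]
  net
}

# mean per-output squared error (average of the BA-mean and EL-mean; outputs
# with no records are ignored)
stop_error <- function(net, data, idx, rec_allele) {
  s <- cpp_sse(net$W1, net$b1, net$W2, net$b2, data,
               as.integer(idx) - 1L, .ra0(rec_allele[idx]))
  mses <- c(if (s[2] > 0) s[1] / s[2], if (s[4] > 0) s[3] / s[4])
  if (!length(mses)) stop("stop set is empty")
  mean(mses)
}

#' Forward pass with max-core selection
#'
#' Scores every candidate binding core of the peptide through the network and
#' returns the maximum of the requested output neuron together with the
#' selected core (ties broken by lowest core index).
#'
#' @param net An `mhc_net`.
#' @param peptide Peptide string.
#' @param pseudo Allele pseudo-sequence string.
#' @param output `"EL"` (default) or `"BA"`.
#' @param enc,tcfg Encoding matrix and task configuration.
#' @return List with `score`, `core` (row of [enumerate_cores()]) and
#'   `core_index` (1-based).
#' @export
net_forward <- function(net, peptide, pseudo, output = "EL",
                        enc = encoding_matrix(), tcfg = task_config("classI")) {
  rec <- data.frame(peptide = peptide, target = 0, assay = output,
                    stringsAsFactors = FALSE)
  data <- encode_dataset(rec, c(A = pseudo), enc, tcfg)
  r <- predict_net(net, data, 1L, 1L, output)
  cores <- enumerate_cores(peptide, tcfg$core_len)
  ci <- r$core + 1L
  list(score = r$score, core = cores[ci, , drop = FALSE], core_index = ci)
}

#' One stochastic-gradient update on a single example
#'
#' Backpropagates the squared-error gradient of the relevant output neuron
#' (BA for affinity examples, EL for ligand examples) through the argmax core
#' only; the input->hidden weights are shared between the two outputs, each
#' output's private hidden->output weights are touched only by its own data
#' type.
#'
#' @param net An `mhc_net`.
#' @param peptide Peptide string.
#' @param pseudo Allele pseudo-sequence.
#' @param target Target value in `[0, 1]`.
#' @param output `"BA"` or `"EL"`.
#' @param lr Learning rate.
#' @param enc,tcfg Encoding matrix and task configuration.
#' @return The updated network.
#' @export
sgd_update <- function(net, peptide, pseudo, target, output, lr = 0.05,
                       enc = encoding_matrix(), tcfg = task_config("classI")) {
  rec <- data.frame(peptide = peptide, target = target, assay = output,
                    stringsAsFactors = FALSE)
  data <- encode_dataset(rec, c(A = pseudo), enc, tcfg)
  upd <- cpp_epoch(net$W1, net$b1, net$W2, net$b2, data, 0L, 0L, lr)
  net[c("W1", "b1", "W2", "b2")] <- upd[c("W1", "b1", "W2", "b2")]
  net
}

#' Train one cross-validation fold
#'
#' Iterates epochs of shuffled per-example SGD over the training records; with
#' early stopping, retains the weight snapshot with the best stop-set error
#' (mean per-output squared error, evaluated every iteration).
#'
#' @param data Encoded dataset (internal container from `encode_dataset`).
#' @param train_idx,stop_idx Disjoint 1-based record indices.
#' @param rec_allele Integer allele index per record (into the dataset's
#'   allele space).
#' @param n_hidden Hidden-layer size.
#' @param seed Seed for weight initialization and epoch shuffles.
#' @param lr Learning rate (default 0.05).
#' @param n_iter Number of training iterations (epochs).
#' @param early_stopping Keep the best stop-set snapshot (default TRUE).
#' @return The trained `mhc_net`; attribute `stop_trace` holds the per-iteration
#'   stop-set error.
#' @export
train_fold <- function(data, train_idx, stop_idx, rec_allele, n_hidden,
                       seed, lr = 0.05, n_iter = 200L, early_stopping = TRUE) {
  if (!length(train_idx)) stop("empty training set")
  if (length(intersect(train_idx, stop_idx)))
    stop("train and stop sets must be disjoint")
  net <- new_network(data$n_in, n_hidden, seed)
  best <- NULL
  best_err <- Inf
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    net <- epoch_step(net, data, train_idx, rec_allele, lr,
                      .derive_seed(seed, it))
    if (length(stop_idx)) {
      err <- stop_error(net, data, stop_idx, rec_allele)
      trace[it] <- err
      if (early_stopping && err < best_err) {
        best_err <- err
        best <- net
      }
    }
  }
  out <- if (early_stopping && !is.null(best)) best else net
  attr(out, "stop_trace") <- trace
  out
}

# deterministic sub-seed derivation, kept below 2^31
.derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}

#' Average predictions of an ensemble
#'
#' @param ensemble List of `mhc_net` objects (non-empty).
#' @param peptide Peptide string.
#' @param pseudo Allele pseudo-sequence.
#' @param output `"EL"` or `"BA"`.
#' @param enc,tcfg Encoding matrix and task configuration.
#' @return Arithmetic mean of the member max-core scores.
#' @export
ensemble_predict <- function(ensemble, peptide, pseudo, output = "EL",
                             enc = encoding_matrix(),
                             tcfg = task_config("classI")) {
  if (!length(ensemble)) stop("ensemble must be non-empty")
  mean(vapply(ensemble, function(net)
    net_forward(net, peptide, pseudo, output, enc, tcfg)$score, numeric(1)))
}

#' Serialize a model to JSON
#'
#' Full-precision round trip of all weights, seeds and configuration.
#'
#' @param model An `mhc_net` or `ma_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

serialize_model <- function(model) {
  if (inherits(model, "mhc_net")) {
    list(type = "mhc_net", version = 1L,
         W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
         n_in = model$n_in, n_hidden = model$n_hidden, seed = model$seed)
  } else if (inherits(model, "ma_model")) {
    list(type = "ma_model", version = 1L,
         config = unclass(model$config), pseudo = as.list(model$pseudo),
         stop_fold = model$stop_fold, hidden = model$hidden,
         panels = model$panels,
         records = as.list(as.data.frame(unclass(model$records))),
         length_bounds = length_bounds(model$records),
         rec_allele = model$rec_allele,
         nets = lapply(model$nets, serialize_model))
  } else stop("unsupported model type")
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON model file.
#' @export
load_model <- function(path) {
  deserialize_model(jsonlite::read_json(path, simplifyVector = TRUE,
                                        simplifyDataFrame = FALSE))
}

deserialize_model <- function(x) {
  if (identical(x$type, "mhc_net")) {
    net <- list(W1 = matrix(as.numeric(x$W1), as.integer(x$n_in),
                            as.integer(x$n_hidden)),
                b1 = as.numeric(x$b1),
                W2 = matrix(as.numeric(x$W2), as.integer(x$n_hidden), 2L),
                b2 = as.numeric(x$b2),
                n_in = as.integer(x$n_in), n_hidden = as.integer(x$n_hidden),
                seed = as.integer(x$seed))
    class(net) <- "mhc_net"
    net
  } else if (identical(x$type, "ma_model")) {
    records <- NULL
    if (!is.null(x$records)) {
      records <- as.data.frame(lapply(x$records, unlist),
                               stringsAsFactors = FALSE)
      attr(records, "length_bounds") <- as.integer(unlist(x$length_bounds))
      attr(records, "task") <- x$config$task
      class(records) <- c("peptide_dataset", "data.frame")
    }
    cfg <- x$config
    class(cfg) <- "ma_config"
    panels <- lapply(x$panels, unlist)
    is_ma <- records$origin == "MA"
    rec_allele <- as.integer(unlist(x$rec_allele))
    pseudo <- unlist(x$pseudo)
    ann <- data.frame(peptide = records$peptide, label = records$label,
                      target = records$target, origin = records$origin,
                      partition = records$partition,
                      annotation = ifelse(is.na(rec_allele), NA_character_,
                                          names(pseudo)[rec_allele]),
                      stringsAsFactors = FALSE)[is_ma, , drop = FALSE]
    m <- list(nets = lapply(x$nets, deserialize_model),
              stop_fold = as.integer(unlist(x$stop_fold)),
              hidden = as.integer(unlist(x$hidden)),
              config = cfg, pseudo = pseudo, panels = panels,
              records = records, rec_allele = rec_allele, annotation = ann,
              enc = encoding_matrix(),
              tcfg = task_config(cfg$task))
    class(m) <- "ma_model"
    m
  } else stop("unknown model type in file")
}
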