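test_that("forward pass equals the R reference and max-core selection", {
  enc <- encoding_matrix()
  ps <- test_pseudo(5)
  net <- new_network(872, 7, seed = 3)
  # single-core peptide: score equals the plain forward pass
  x <- encode_example(1, "ACDEFGHIK", ps, enc)
  for (out in c("BA", "EL")) {
    k <- if (out == "BA") 1 else 2
    ref <- r_forward(net, x, k)$o
    got <- net_forward(net, "ACDEFGHIK", ps, out)
    expect_equal(got$score, ref, tolerance = 1e-12)
    expect_equal(got$core_index, 1)
  }
  # multi-core peptide: max over exhaustively scored cores
  pep <- "ACDEFGHIKLMW"
  cores <- enumerate_cores(pep, 9)
  ref_scores <- vapply(seq_len(nrow(cores)), function(i)
    r_forward(net, encode_example(i, pep, ps, enc), 2)$o, numeric(1))
  got <- net_forward(net, pep, ps, "EL")
  expect_equal(got$score, max(ref_scores), tolerance = 1e-12)
  expect_equal(got$core_index, which.max(ref_scores))
  expect_true(all(ref_scores > 0 & ref_scores < 1))
})

test_that("SGD gradients match central finite differences", {
  enc <- encoding_matrix()
  ps <- test_pseudo(6)
  pep <- "ACDEFGHIK"
  x <- encode_example(1, pep, ps, enc)
  for (s in 1:3) {
    net <- new_network(length(x), 5, seed = s)
    for (out in c("BA", "EL")) {
      k <- if (out == "BA") 1 else 2
      target <- 0.3
      up <- sgd_update(net, pep, ps, target, out, lr = 1)
      # analytic gradient recovered from the unit-lr update
      gW1 <- net$W1 - up$W1
      gW2 <- net$W2 - up$W2
      loss_W1 <- function(W1) {
        n2 <- net; n2$W1 <- W1
        0.5 * (r_forward(n2, x, k)$o - target)^2
      }
      eps <- 1e-6
      idx <- c(1L, 103L, 872L * 5L - 3L)
      for (i in idx) {
        Wp <- net$W1; Wp[i] <- Wp[i] + eps
        Wm <- net$W1; Wm[i] <- Wm[i] - eps
        g_num <- (loss_W1(Wp) - loss_W1(Wm)) / (2 * eps)
        expect_equal(gW1[i], g_num, tolerance = 1e-5)
      }
      # the other output's private weights are untouched
      other <- 3 - k
      expect_identical(up$W2[, other], net$W2[, other])
      expect_identical(up$b2[other], net$b2[other])
      expect_false(identical(up$W2[, k], net$W2[, k]))
    }
  }
  # zero error -> no update
  net <- new_network(length(x), 5, seed = 9)
  cur <- net_forward(net, pep, ps, "EL")$score
  up0 <- sgd_update(net, pep, ps, cur, "EL", lr = 0.5)
  expect_identical(up0$W1, net$W1)
  expect_identical(up0$b1, net$b1)
})

test_that("train_fold converges, is deterministic and honors early stopping", {
  enc <- encoding_matrix()
  ps <- c(AL = test_pseudo(7))
  # separable fixture: anchored positives vs random negatives
  pssm <- matrix(1 / 20, 9, 20, dimnames = list(NULL, aa_alphabet()$residues))
  pssm[2, ] <- 0.01 / 19
  pssm[2, "L"] <- 0.99
  pssm[9, ] <- 0.01 / 19
  pssm[9, "V"] <- 0.99
  pssm <- pssm / rowSums(pssm)
  pos <- sample_el_positives(pssm, 120, c("9" = 1), seed = 8)
  neg <- random_peptides(240, 9, 41)
  recs <- data.frame(peptide = c(pos, neg),
                     target = rep(c(1, 0), c(length(pos), length(neg))),
                     assay = "EL", stringsAsFactors = FALSE)
  data <- mhcdecon:::encode_dataset(recs, ps, enc)
  ra <- rep(1L, nrow(recs))
  stop_idx <- seq(1, nrow(recs), by = 4)
  train_idx <- setdiff(seq_len(nrow(recs)), stop_idx)
  net <- train_fold(data, train_idx, stop_idx, ra, n_hidden = 5, seed = 2,
                    n_iter = 50, early_stopping = FALSE)
  sc <- mhcdecon:::predict_net(net, data, train_idx, ra[train_idx], "EL")$score
  expect_gt(auc(sc, recs$target[train_idx]), 0.99)

  # bit-identical trajectory under the same seed
  net2 <- train_fold(data, train_idx, stop_idx, ra, n_hidden = 5, seed = 2,
                     n_iter = 50, early_stopping = FALSE)
  expect_identical(net$W1, net2$W1)

  # early stopping returns a snapshot no worse than the final iterate
  es <- train_fold(data, train_idx, stop_idx, ra, n_hidden = 5, seed = 2,
                   n_iter = 50, early_stopping = TRUE)
  err_es <- mhcdecon:::stop_error(es, data, stop_idx, ra)
  err_end <- mhcdecon:::stop_error(net, data, stop_idx, ra)
  expect_lte(err_es, err_end + 1e-12)
  expect_equal(min(attr(es, "stop_trace")), err_es, tolerance = 1e-12)

  expect_error(train_fold(data, integer(0), stop_idx, ra, 5, 1), "empty")
  expect_error(train_fold(data, train_idx, train_idx[1], ra, 5, 1),
               "disjoint")
})

test_that("ensembles average member predictions order-independently", {
  ps <- test_pseudo(8)
  nets <- lapply(1:3, function(s) new_network(872, 4, seed = s))
  pep <- "ACDEFGHIKL"
  member <- vapply(nets, function(n) net_forward(n, pep, ps, "EL")$score,
                   numeric(1))
  expect_equal(ensemble_predict(nets, pep, ps, "EL"), mean(member))
  expect_equal(ensemble_predict(rev(nets), pep, ps, "EL"), mean(member))
  expect_equal(ensemble_predict(nets[1], pep, ps, "EL"), member[1])
  expect_error(ensemble_predict(list(), pep, ps), "non-empty")
})

test_that("model serialization round-trips exactly", {
  net <- new_network(872, 6, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(net, f)
  net2 <- load_model(f)
  expect_identical(unclass(net2), unclass(net))
})
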