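test_that("worlds are pure functions of their spec and meet separation", {
  spec <- tiny_world_spec(81L)
  w1 <- make_world(spec)
  w2 <- make_world(spec)
  expect_identical(w1$pssms, w2$pssms)
  expect_identical(w1$pseudo, w2$pseudo)
  expect_identical(w1$proteome, w2$proteome)
  # rejection contract: all pairwise motif PCCs below the separation target
  pcc <- combn(length(w1$pssms), 2, function(ij)
    motif_pcc(w1$pssms[[ij[1]]], w1$pssms[[ij[2]]]))
  expect_true(all(pcc <= spec$separation))
  # PSSM rows are stochastic
  for (p in w1$pssms) expect_equal(rowSums(p), rep(1, 9), tolerance = 1e-9)
  # the MA-only allele receives no SA data downstream
  sa <- build_sa_datasets(w1, seed = 1)
  ma_only <- names(w1$pssms)[spec$ma_only]
  expect_false(ma_only %in% sa$el$label)
  expect_false(ma_only %in% sa$ba$label)
  # pseudo-sequence distance is informative: identical-motif allele is closest
  d_self <- allele_distance(w1$pseudo[1], w1$pseudo[1])
  d_other <- allele_distance(w1$pseudo[1], w1$pseudo[2])
  expect_lt(d_self, d_other)
})

test_that("EL positives reproduce their generating PSSM", {
  res <- aa_alphabet()$residues
  pssm <- matrix(1 / 20, 9, 20, dimnames = list(NULL, res))
  pssm[2, ] <- 0.1 / 19
  pssm[2, "L"] <- 0.9
  pssm <- pssm / rowSums(pssm)
  peps <- sample_el_positives(pssm, 1000, c("9" = 1), seed = 9)
  expect_true(all(nchar(peps) == 9))
  p2 <- substr(peps, 2, 2)
  expect_lt(abs(mean(p2 == "L") - 0.9), 0.03)
  # empirical frequency matrix converges to the PSSM
  peps5k <- sample_el_positives(pssm, 5000, c("9" = 1), seed = 10)
  emp <- t(vapply(1:9, function(p)
    as.numeric(table(factor(substr(peps5k, p, p), levels = res))) / 5000,
    numeric(20)))
  expect_gt(motif_pcc(emp, pssm), 0.98)
  # mixed lengths stay within bounds and respect core semantics
  ld <- c("8" = 0.2, "9" = 0.5, "10" = 0.2, "11" = 0.1)
  mix <- sample_el_positives(pssm, 400, ld, seed = 11)
  expect_true(all(nchar(mix) %in% 8:11))
  expect_error(sample_el_positives(pssm, 0, c("9" = 1), 1), "positive")
  # determinism
  expect_identical(peps, sample_el_positives(pssm, 1000, c("9" = 1), seed = 9))
})

test_that("MA datasets follow their abundance weights with hidden truth", {
  spec <- world_spec(n_alleles = 3L,
                     panels = list(P1 = c(1L, 2L), P2 = c(2L, 3L)),
                     weights = list(P1 = c(0.5, 0.5), P2 = c(1, 0)),
                     ma_only = 3L, low_abundance = 1L,
                     n_ma = 2000L, length_dist = c("9" = 1),
                     length_bounds = c(9L, 9L), proteome_len = 30000L,
                     n_proteins = 3L, seed = 83L)
  world <- make_world(spec)
  b <- build_ma_dataset(world, "P1", 2000, seed = 3)
  expect_equal(nrow(b$data), 2000)
  counts <- table(b$truth)
  expect_lt(abs(counts[["SYN-01"]] - 1000), 70)
  expect_true(all(b$truth %in% world$panels$P1))
  # degenerate weight: everything from one allele
  b2 <- build_ma_dataset(world, "P2", 300, seed = 4)
  expect_true(all(b2$truth == "SYN-02"))
})

test_that("BA targets are monotone in the PSSM score", {
  spec <- tiny_world_spec(84L, n_sa_ba = 60L)
  world <- make_world(spec)
  sa0 <- build_sa_datasets(world, noise_sd = 0, seed = 5)
  ba <- sa0$ba[sa0$ba$label == "SYN-01", ]
  s <- vapply(ba$peptide, mhcdecon:::pssm_score, numeric(1),
              pssm = world$pssms[["SYN-01"]])
  expect_equal(cor(s, ba$target, method = "spearman"), 1)
  # with noise the ranking degrades but stays strongly positive
  sa1 <- build_sa_datasets(world, noise_sd = 0.1, seed = 5)
  ba1 <- sa1$ba[sa1$ba$label == "SYN-01", ]
  expect_gt(cor(s, ba1$target, method = "spearman"), 0.7)
})

test_that("planted epitopes are unique and antigens deterministic", {
  pe <- plant_epitope(300, "ACDEFGHIK", seed = 12)
  expect_equal(nchar(pe$antigen), 300)
  hits <- gregexpr("ACDEFGHIK", pe$antigen, fixed = TRUE)[[1]]
  expect_length(hits, 1)
  pe2 <- plant_epitope(300, "ACDEFGHIK", seed = 12)
  expect_identical(pe$antigen, pe2$antigen)
  expect_error(plant_epitope(5, "ACDEFGHIK", 1), "shorter")
  # digestion count arithmetic before deduplication
  n_digested <- sum(vapply(8:14, function(k) 300 - k + 1, numeric(1)))
  expect_lte(length(digest_protein(pe$antigen, 8:14)), n_digested)
})

test_that("simulated worlds wire SA, MA, truth and files together", {
  spec <- tiny_world_spec(85L)
  world <- make_world(spec)
  sim <- simulate_world_data(world)
  expect_equal(length(sim$truth), nrow(sim$ma))
  pos <- sim$ma$target == 1
  expect_true(all(!is.na(sim$truth[pos])))
  expect_true(all(is.na(sim$truth[!pos])))
  # negatives: 5x modal length count per length and label
  for (lab in names(sim$panels)) {
    n_pos <- sum(sim$ma$label == lab & sim$ma$target == 1)
    n_neg <- sum(sim$ma$label == lab & sim$ma$target == 0)
    expect_equal(n_neg, 5 * n_pos) # single length, 9mers only
  }
  # SA EL contains no sequence duplicated in MA
  sa_el <- sim$sa[sim$sa$assay == "EL", ]
  expect_length(intersect(sa_el$peptide, sim$ma$peptide), 0)
  # fixture directory round trip
  dir <- withr::local_tempdir()
  write_world(sim, dir, spec)
  expect_true(all(file.exists(file.path(dir,
    c("sa_ba.tsv", "sa_el.tsv", "ma_el.tsv", "panels.tsv", "pseudoseq.dat",
      "proteome.fasta", "truth.tsv", "world_spec.json")))))
  ma2 <- read_peptide_table(file.path(dir, "ma_el.tsv"), "EL", "MA",
                            quiet = TRUE)
  expect_equal(sort(ma2$peptide), sort(sim$ma$peptide))
})
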