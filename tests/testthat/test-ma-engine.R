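test_that("annotation follows argmax-z with the documented tie rule", {
  panels <- list(L1 = c("AL-B", "AL-A"), L2 = "AL-C")
  ma <- peptide_dataset(c(random_peptides(4, 9, 61), random_peptides(2, 9, 62)),
                        c(1, 1, 1, 0, 1, 1),
                        c(rep("L1", 4), rep("L2", 2)), origin = "MA")
  # single-allele panel: everything goes there regardless of score
  const_scorer <- function(peptides, allele) rep(0.5, length(peptides))
  ann <- annotate_ma(const_scorer, ma, panels, seed = 3)
  expect_true(all(ann$annotation[ann$label == "L2"] == "AL-C"))
  # exact ties resolve to the lexicographically smallest allele
  expect_true(all(ann$annotation[ann$label == "L1" & ann$target == 1] == "AL-A"))
  # negatives are drawn from the panel
  expect_true(all(ann$annotation[ann$target == 0] %in% panels$L1))
  # conservation: every record annotated within its panel
  expect_true(all(mapply(function(a, l) a %in% panels[[l]],
                         ann$annotation, ann$label)))
  # rescaling statistics can flip the winner
  biased <- function(peptides, allele)
    rep(if (allele == "AL-A") 0.30 else 0.25, length(peptides))
  stats <- data.frame(allele = c("AL-A", "AL-B"),
                      p_bar = c(0.30, 0.10), sigma = c(0.05, 0.05))
  ma_l1 <- ma[ma$label == "L1", ]
  raw <- annotate_ma(biased, ma, panels, seed = 3)
  resc <- annotate_ma(biased, ma_l1, panels["L1"], stats = stats,
                      iteration = 0, seed = 3, shift = 1e6)
  pos1 <- raw$label == "L1" & raw$target == 1
  expect_true(all(raw$annotation[pos1] == "AL-A"))     # raw argmax
  expect_true(all(resc$annotation[resc$target == 1] == "AL-B")) # z argmax
  expect_error(annotate_ma(const_scorer, ma, panels["L1"], seed = 1),
               "no panel")
})

test_that("a trained model separates two disjoint synthetic motifs", {
  spec <- tiny_world_spec(91L, n_ma = 120L, n_sa_el = 80L, n_sa_ba = 40L)
  world <- make_world(spec)
  sim <- simulate_world_data(world)
  cfg <- quick_cfg(seed = 21L)
  m <- ma_deconvolute(sim$sa, sim$ma, sim$panels, sim$pseudo, cfg,
                      sim$proteome)
  ann <- m$annotation
  # conservation at the final iteration: all MA records annotated in-panel
  expect_true(all(!is.na(ann$annotation)))
  expect_true(all(mapply(function(a, l) a %in% sim$panels[[l]],
                         ann$annotation, ann$label)))
  # positives recover their generating allele well above the 2-allele chance
  truth <- sim$truth[!is.na(sim$truth)]
  acc <- mean(ann$annotation[ann$target == 1] == truth)
  expect_gt(acc, 0.6)
  # training log is complete and the schedule was followed
  expect_equal(nrow(m$log), cfg$n_iter)
  expect_equal(m$log$w, blend_weight(seq_len(cfg$n_iter)))
  expect_equal(m$log$n_ma_annotated[cfg$burn_in], 0)
  expect_gt(m$log$n_ma_annotated[cfg$n_iter], 0)
  # reproducibility from config seeds
  m2 <- ma_deconvolute(sim$sa, sim$ma, sim$panels, sim$pseudo, cfg,
                       sim$proteome)
  expect_identical(m$nets[[1]]$W1, m2$nets[[1]]$W1)
  expect_identical(m$annotation$annotation, m2$annotation$annotation)
})

test_that("cross-validation hygiene holds structurally", {
  spec <- tiny_world_spec(92L)
  world <- make_world(spec)
  sim <- simulate_world_data(world)
  cfg <- quick_cfg(seed = 22L, n_iter = 20L, burn_in = 8L)
  m <- ma_deconvolute(sim$sa, sim$ma, sim$panels, sim$pseudo, cfg,
                      sim$proteome)
  # every fold is represented, and out-of-fold scoring uses only nets whose
  # held-out fold equals the record's partition
  expect_setequal(unique(m$stop_fold), 0:(cfg$n_parts - 1))
  data <- mhcdecon:::encode_dataset(m$records, m$pseudo, m$enc, m$tcfg)
  idx <- which(m$records$partition == 0)[1:5]
  manual <- rowMeans(vapply(which(m$stop_fold == 0), function(i)
    mhcdecon:::predict_net(m$nets[[i]], data, idx,
                           rep(1L, length(idx)), "EL")$score,
    numeric(length(idx))))
  got <- mhcdecon:::oof_scores_model(m, idx, names(m$pseudo)[1], "EL", data)
  expect_equal(got, manual, tolerance = 1e-12)
  # BA output correlates positively with the transformed affinity targets
  pcc <- ba_correlation(m)
  expect_equal(sort(pcc$allele), sort(unique(m$records$label[
    m$records$assay == "BA"])))
  expect_true(all(abs(pcc$pcc) <= 1))
  expect_gt(mean(pcc$pcc), 0)
  # model errors early if an MA allele misses a pseudo-sequence
  bad_panels <- sim$panels
  bad_panels$P1 <- c(bad_panels$P1, "MISSING-ALLELE")
  expect_error(ma_deconvolute(sim$sa, sim$ma, bad_panels, sim$pseudo, cfg,
                              sim$proteome), "missing")
})
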