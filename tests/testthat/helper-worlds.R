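# Shared fixture builders. Every helper is a pure function of its seed.

# minimal 3-allele, 9mer-only world: two panels sharing the MA-only allele 3
tiny_world_spec <- function(seed, n_ma = 40L, n_sa_el = 40L, n_sa_ba = 20L,
                            weights = list(P1 = c(0.5, 0.5),
                                           P2 = c(0.5, 0.5))) {
  world_spec(n_alleles = 3L, panels = list(P1 = c(1L, 3L), P2 = c(2L, 3L)),
             weights = weights, ma_only = 3L, low_abundance = 1L,
             n_ma = n_ma, n_sa_el = n_sa_el, n_sa_ba = n_sa_ba,
             length_dist = c("9" = 1), length_bounds = c(9L, 9L),
             proteome_len = 30000L, n_proteins = 3L, seed = seed)
}

# co-occurrence fixture of the acceptance suite (two panels share exactly one
# allele, which carries the only unexplained motif)
co_world_spec <- function(seed) {
  world_spec(n_alleles = 3L, panels = list(P1 = c(1L, 3L), P2 = c(2L, 3L)),
             weights = list(P1 = c(0.5, 0.5), P2 = c(0.5, 0.5)),
             ma_only = 3L, low_abundance = 1L,
             n_ma = 120L, n_sa_el = 80L, n_sa_ba = 40L,
             length_dist = c("9" = 1), length_bounds = c(9L, 9L),
             proteome_len = 60000L, n_proteins = 5L, seed = seed)
}

quick_cfg <- function(seed = 11L, ...) {
  args <- list(hidden_sizes = 10L, seeds_per_size = 1L, n_parts = 3L,
               n_iter = 40L, burn_in = 15L, n_random_rescale = 500L,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(ma_config, args)
}

# R reference forward pass (independent of the C++ path): logistic units,
# weights applied to an explicitly encoded input vector
r_forward <- function(net, x, out_idx) {
  h <- stats::plogis(drop(t(net$W1) %*% x) + net$b1)
  o <- stats::plogis(drop(t(net$W2) %*% h) + net$b2)
  list(h = h, o = o[out_idx])
}

# split a partitioned combined dataset back into SA/MA peptide_datasets
split_partitioned <- function(comb) {
  out <- lapply(c("SA", "MA"), function(or) {
    d <- comb[comb$origin == or, , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "length_bounds") <- attr(comb, "length_bounds")
    attr(d, "task") <- attr(comb, "task")
    class(d) <- class(comb)
    d
  })
  names(out) <- c("sa", "ma")
  out
}

random_peptides <- function(n, len, seed) {
  res <- aa_alphabet()$residues
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(res, len, replace = TRUE), collapse = ""), character(1)))
}

# a fixed 34-residue pseudo-sequence for single-allele tests
test_pseudo <- function(seed = 1L) {
  paste(withr::with_seed(seed, sample(aa_alphabet()$residues, 34,
                                      replace = TRUE)), collapse = "")
}
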