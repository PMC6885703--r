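#' Blending schedule weight
#'
#' `w = 1 / (1 + exp((x - shift) / scale))`: close to 1 just after the burn-in
#' (x = 20), exactly 0.5 at `x = shift` (default 75), and converging to 0 as
#' the iteration count passes 100. Controls how fast per-allele rescaling
#' statistics are blended toward their across-allele averages.
#'
#' @param x Training iteration index (>= 0).
#' @param shift Schedule midpoint (tunable; similar behaviour in 50-100).
#' @param scale Schedule width (> 0).
#' @return Weight in (0, 1), strictly decreasing in `x`.
#' @export
blend_weight <- function(x, shift = 75, scale = 10) {
  stopifnot(scale > 0, all(x >= 0))
  1 / (1 + exp((x - shift) / scale))
}

#' Trimmed normal fit of a score distribution
#'
#' Mean and standard deviation estimated from a positive normal fit with
#' iterative outlier exclusion: records with |z| > 3 under the current fit are
#' removed and the fit recomputed, until no further exclusions (at most
#' `max_iter` rounds).
#'
#' @param scores Numeric scores.
#' @param z_cut Exclusion threshold (default 3).
#' @param max_iter Maximum trimming rounds (default 20).
#' @return List with `p_bar`, `sigma`, `n_used`.
#' @export
fit_trimmed_normal <- function(scores, z_cut = 3, max_iter = 20L) {
  keep <- is.finite(scores)
  x <- scores[keep]
  for (i in seq_len(max_iter)) {
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s <= .Machine$double.eps * max(1, abs(m)))
      stop("degenerate score distribution (zero spread)")
    z <- (x - m) / s
    drop <- abs(z) > z_cut
    if (!any(drop)) break
    x <- x[!drop]
  }
  list(p_bar = mean(x), sigma = stats::sd(x), n_used = length(x))
}

#' Estimate the raw score distribution of an allele
#'
#' Scores `n_random` random natural 9mers (class I; `core_len`-mers otherwise)
#' drawn from the proteome with the supplied scorer and fits a trimmed normal
#' ([fit_trimmed_normal()]). The scorer is either a function
#' `f(peptides) -> scores` or an `ma_model`, in which case the model's
#' eluted-ligand output for `allele` is used.
#'
#' @param scorer Function or `ma_model`.
#' @param proteome Named character vector of protein sequences.
#' @param n_random Number of random peptides (default 10000).
#' @param seed Seed for the peptide draw.
#' @param allele Allele name (required when `scorer` is a model).
#' @param peptide_len Length of the sampled peptides (default 9).
#' @return List with `p_bar`, `sigma`, `n_used`.
#' @export
estimate_score_distribution <- function(scorer, proteome, n_random = 10000L,
                                        seed = 1L, allele = NULL,
                                        peptide_len = 9L) {
  peps <- withr::with_seed(as.integer(seed),
                           sample_natural_peptides(proteome, peptide_len,
                                                   n_random))
  scores <- if (is.function(scorer)) {
    scorer(peps)
  } else if (inherits(scorer, "ma_model")) {
    if (is.null(allele)) stop("allele required when scoring with a model")
    predict_peptides(scorer, peps, allele, output = "EL")
  } else stop("scorer must be a function or an ma_model")
  fit_trimmed_normal(scores)
}

#' Blend per-allele rescaling statistics toward uniform values
#'
#' `p' = w * p_bar + (1 - w) * p_bar_u` and `sigma' = w * sigma +
#' (1 - w) * sigma_u`, with `w = blend_weight(x)` and the uniform values
#' defined as the averages of `p_bar` / `sigma` over all alleles of the
#' multi-allele data set.
#'
#' @param stats data.frame with columns `allele`, `p_bar`, `sigma`.
#' @param x Iteration index.
#' @param shift,scale Schedule parameters (see [blend_weight()]).
#' @return The input with columns `p_bar_u`, `sigma_u`, `w`, `p_prime`,
#'   `sigma_prime` added.
#' @export
blend_stats <- function(stats, x, shift = 75, scale = 10) {
  w <- blend_weight(x, shift, scale)
  stats$p_bar_u <- mean(stats$p_bar)
  stats$sigma_u <- mean(stats$sigma)
  stats$w <- w
  stats$p_prime <- w * stats$p_bar + (1 - w) * stats$p_bar_u
  stats$sigma_prime <- w * stats$sigma + (1 - w) * stats$sigma_u
  stats
}
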