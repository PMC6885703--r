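#' Specification of a synthetic deconvolution world
#'
#' Describes a ground-truth world: per-allele position-specific scoring
#' matrices (PSSMs) over a 9-position core, pseudo-sequences constructed so
#' that pseudo-sequence distance tracks motif dissimilarity, cell-line panels
#' with co-occurrence structure (at least one allele shared between panels and
#' at least one allele private to a single panel), a multi-allele-only allele
#' with no single-allele data, and a low-abundance allele mimicking HLA-C.
#'
#' The default scale matches the package's reference world (6 alleles, 4
#' panels, 2000 MA positives per panel, 500 SA EL + 200 SA BA per allele);
#' tests and the acceptance run use [desk_world_spec()], a smaller,
#' time-budgeted version of the same world.
#'
#' @param n_alleles Number of alleles (>= 3).
#' @param panels List of integer vectors (allele indices per panel); `NULL`
#'   builds the default 4-panel layout.
#' @param weights List of abundance-weight vectors matching `panels`.
#' @param ma_only Index of the allele excluded from SA data.
#' @param low_abundance Index of the low-abundance allele.
#' @param separation Maximum tolerated pairwise motif PCC.
#' @param n_ma Positive MA records per panel.
#' @param n_sa_el,n_sa_ba SA records per (non-left-out) allele.
#' @param length_dist Named numeric vector: peptide length -> probability.
#' @param length_bounds Inclusive dataset length bounds.
#' @param anchor_p Probability mass on each anchor residue.
#' @param proteome_len,n_proteins Random proteome dimensions.
#' @param distant Indices of alleles given a remote pseudo-sequence (and no
#'   constraint that pseudo similarity track the others), used to emulate MHC
#'   molecules far from the single-allele training data.
#' @param seed Integer seed; the whole world is a pure function of this spec.
#' @return List of class `world_spec`.
#' @export
world_spec <- function(n_alleles = 6L, panels = NULL, weights = NULL,
                       ma_only = 6L, low_abundance = 5L, separation = 0.2,
                       n_ma = 2000L, n_sa_el = 500L, n_sa_ba = 200L,
                       length_dist = c("8" = 0.08, "9" = 0.60, "10" = 0.14,
                                       "11" = 0.08, "12" = 0.05, "13" = 0.03,
                                       "14" = 0.02),
                       length_bounds = c(8L, 14L), anchor_p = 0.85,
                       proteome_len = 500000L, n_proteins = 20L,
                       distant = integer(0), seed = 42L) {
  if (is.null(panels)) {
    panels <- list(P1 = c(1L, 2L, 5L), P2 = c(2L, 3L, 6L), P3 = c(3L, 4L),
                   P4 = c(1L, 6L, 5L))
    weights <- list(P1 = c(0.50, 0.45, 0.05), P2 = c(0.30, 0.30, 0.40),
                    P3 = c(0.50, 0.50), P4 = c(0.55, 0.40, 0.05))
  }
  stopifnot(length(panels) == length(weights),
            all(vapply(weights, function(w) abs(sum(w) - 1) < 1e-8, logical(1))))
  shared <- any(table(unlist(panels)) >= 2)
  private <- any(table(unlist(panels)) == 1)
  if (!shared || !private)
    stop("panel layout must contain a shared allele and a private allele")
  spec <- list(n_alleles = as.integer(n_alleles), panels = panels,
               weights = weights, ma_only = as.integer(ma_only),
               low_abundance = as.integer(low_abundance),
               separation = separation, n_ma = as.integer(n_ma),
               n_sa_el = as.integer(n_sa_el), n_sa_ba = as.integer(n_sa_ba),
               length_dist = length_dist / sum(length_dist),
               length_bounds = as.integer(length_bounds),
               anchor_p = anchor_p, proteome_len = as.integer(proteome_len),
               n_proteins = as.integer(n_proteins),
               distant = as.integer(distant), seed = as.integer(seed))
  class(spec) <- "world_spec"
  spec
}

#' Desk-scale world specification
#'
#' The reference world of [world_spec()] scaled down to run within a
#' minutes-scale single-CPU budget (smaller datasets; same allele, panel and
#' separation structure).
#'
#' @param ... Overrides passed to [world_spec()].
#' @export
desk_world_spec <- function(...) {
  args <- list(n_ma = 300L, n_sa_el = 150L, n_sa_ba = 75L,
               proteome_len = 200000L, n_proteins = 10L)
  over <- list(...)
  args[names(over)] <- over
  do.call(world_spec, args)
}

# Dirichlet row
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha)
  g / sum(g)
}

# one random PSSM: low-entropy anchors at positions 2 and 9, near-background
# elsewhere
.sample_pssm <- function(anchor_p, core_len = 9L) {
  m <- t(vapply(seq_len(core_len), function(p) .rdirichlet(rep(5, 20)),
                numeric(20)))
  colnames(m) <- aa_alphabet()$residues
  for (p in c(2L, core_len)) {
    a <- sample.int(20, 1)
    row <- .rdirichlet(rep(1, 20)) * (1 - anchor_p)
    row[a] <- row[a] + anchor_p
    m[p, ] <- row
  }
  m
}

#' Generate a ground-truth world
#'
#' Samples allele PSSMs (rejection-resampled until all pairwise motif PCCs
#' are at most `spec$separation`), builds pseudo-sequences whose
#' anchor-determining positions copy the motif's preferred residues (so that
#' [allele_distance()] correlates with motif dissimilarity), and samples a
#' random background proteome. Deterministic given the spec seed.
#'
#' @param spec A [world_spec()].
#' @return List of class `world`: `alleles` (name, pssm, pseudo), `panels`
#'   (allele names), `weights`, `pseudo` (named vector), `proteome`, `spec`.
#' @export
make_world <- function(spec = world_spec()) {
  res <- aa_alphabet()$residues
  withr::with_seed(spec$seed, {
    pssms <- vector("list", spec$n_alleles)
    for (i in seq_len(spec$n_alleles)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        cand <- .sample_pssm(spec$anchor_p)
        prev <- pssms[seq_len(i - 1L)]
        if (all(vapply(prev, function(p) motif_pcc(p, cand) <= spec$separation,
                       logical(1)))) {
          pssms[[i]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not reach motif separation ", spec$separation)
    }
    names(pssms) <- sprintf("SYN-%02d", seq_len(spec$n_alleles))
    base <- paste(sample(res, 34, replace = TRUE), collapse = "")
    pseudo <- vapply(seq_len(spec$n_alleles), function(i) {
      if (i %in% spec$distant) {
        # remote allele: pseudo-sequence carries no motif information, like an
        # MHC molecule far from everything in the training data
        return(paste(sample(res, 34, replace = TRUE), collapse = ""))
      }
      ch <- strsplit(base, "")[[1]]
      top <- res[apply(pssms[[i]], 1, which.max)]
      # two contact positions per core position (interleaved in 1..18)
      ch[seq(1, 18, by = 2)] <- top
      ch[seq(2, 18, by = 2)] <- top
      paste(ch, collapse = "")
    }, character(1))
    names(pseudo) <- names(pssms)
    prot_len <- pmax(50L, as.integer(stats::rmultinom(
      1, spec$proteome_len, rep(1, spec$n_proteins))))
    proteome <- vapply(prot_len, function(L)
      paste(sample(res, L, replace = TRUE), collapse = ""), character(1))
    names(proteome) <- sprintf("PROT%03d", seq_along(proteome))
  })
  panels <- lapply(spec$panels, function(ix) names(pssms)[ix])
  world <- list(pssms = pssms, pseudo = pseudo, panels = panels,
                weights = spec$weights, proteome = proteome, spec = spec)
  class(world) <- "world"
  world
}

#' Sample eluted-ligand positives from an allele's PSSM
#'
#' Nine-residue cores are sampled position-wise from the PSSM; lengths other
#' than 9 are realized consistently with the binding-core semantics: longer
#' peptides insert background residues as a contiguous interior block into
#' the core, 8mers delete one interior core residue.
#'
#' @param pssm 9 x 20 row-stochastic matrix.
#' @param n Number of peptides (> 0).
#' @param length_dist Named probability vector over lengths.
#' @param seed Integer seed.
#' @return Character vector of peptides.
#' @export
sample_el_positives <- function(pssm, n, length_dist = c("9" = 1), seed = 1L) {
  if (n <= 0) stop("n must be positive")
  res <- aa_alphabet()$residues
  withr::with_seed(as.integer(seed), {
    lens <- as.integer(sample(names(length_dist), n, replace = TRUE,
                              prob = length_dist))
    cores <- vapply(seq_len(n), function(i)
      paste(vapply(seq_len(nrow(pssm)), function(p)
        sample(res, 1, prob = pssm[p, ]), character(1)), collapse = ""),
      character(1))
    vapply(seq_len(n), function(i) {
      L <- lens[i]
      core <- cores[i]
      k <- nchar(core)
      if (L == k) return(core)
      if (L > k) {
        ins <- paste(sample(res, L - k, replace = TRUE), collapse = "")
        s <- sample.int(k - 1L, 1) # interior block position
        paste0(substr(core, 1, s), ins, substr(core, s + 1, k))
      } else {
        drop <- sample(seq(2L, k - 1L), k - L) # interior deletions
        paste(strsplit(core, "")[[1]][-drop], collapse = "")
      }
    }, character(1))
  })
}

# max over candidate cores of the PSSM log-odds score (X scores 0)
pssm_score <- function(pssm, peptide, core_len = 9L) {
  cores <- cpp_enumerate_cores(peptide, core_len)$core
  bg <- 1 / 20
  max(vapply(cores, function(co) {
    ch <- strsplit(co, "")[[1]]
    s <- 0
    for (p in seq_len(core_len))
      if (ch[p] != "X") s <- s + log(pssm[p, ch[p]] / bg)
    s
  }, numeric(1)))
}

#' Build a multi-allele dataset from a panel
#'
#' Each positive is drawn from one panel allele with probability equal to its
#' abundance weight; the generating allele is recorded as hidden ground
#' truth. Negatives are added separately via [enrich_negatives()].
#'
#' @param world A [make_world()] result.
#' @param panel Panel name.
#' @param n Number of positives.
#' @param seed Integer seed.
#' @param tcfg Task configuration.
#' @return List: `data` (a `peptide_dataset`), `truth` (character vector of
#'   generating alleles).
#' @export
build_ma_dataset <- function(world, panel, n, seed = 1L,
                             tcfg = task_config("classI")) {
  alleles <- world$panels[[panel]]
  w <- world$weights[[panel]]
  spec <- world$spec
  withr::with_seed(.derive_seed(seed, 1), {
    src <- sample(alleles, n, replace = TRUE, prob = w)
  })
  peps <- character(n)
  for (a in unique(src)) {
    ix <- which(src == a)
    peps[ix] <- sample_el_positives(world$pssms[[a]], length(ix),
                                    spec$length_dist, .derive_seed(seed, 2,
                                      match(a, names(world$pssms))))
  }
  d <- peptide_dataset(peps, 1, panel, assay = "EL", origin = "MA",
                       tcfg = tcfg, length_bounds = spec$length_bounds)
  list(data = d, truth = src)
}

#' Build single-allele datasets
#'
#' EL positives are sampled from each allele's PSSM ([sample_el_positives()]);
#' BA targets are a monotone logistic transform of the PSSM log-odds score
#' (half PSSM-sampled binders, half background peptides) plus optional
#' Gaussian noise, clipped to `[0, 1]`. Left-out alleles (the MA-only set)
#' receive no SA data.
#'
#' @param world A [make_world()] result.
#' @param leave_out Allele names excluded from SA data (defaults to the
#'   spec's MA-only allele).
#' @param noise_sd BA target noise standard deviation.
#' @param seed Integer seed.
#' @param tcfg Task configuration.
#' @return List: `el`, `ba` (both `peptide_dataset`s).
#' @export
build_sa_datasets <- function(world, leave_out = NULL, noise_sd = 0.05,
                              seed = 1L, tcfg = task_config("classI")) {
  spec <- world$spec
  if (is.null(leave_out))
    leave_out <- names(world$pssms)[spec$ma_only]
  alleles <- setdiff(names(world$pssms), leave_out)
  el <- list()
  ba <- list()
  res <- aa_alphabet()$residues
  for (a in alleles) {
    i <- match(a, names(world$pssms))
    if (spec$n_sa_el > 0) {
      peps <- sample_el_positives(world$pssms[[a]], spec$n_sa_el,
                                  spec$length_dist, .derive_seed(seed, 3, i))
      el[[a]] <- peptide_dataset(peps, 1, a, assay = "EL", origin = "SA",
                                 tcfg = tcfg,
                                 length_bounds = spec$length_bounds)
    }
    if (spec$n_sa_ba > 0) {
      n_bind <- ceiling(spec$n_sa_ba / 2)
      binders <- sample_el_positives(world$pssms[[a]], n_bind,
                                     spec$length_dist, .derive_seed(seed, 4, i))
      bg <- withr::with_seed(.derive_seed(seed, 5, i), {
        lens <- as.integer(sample(names(spec$length_dist),
                                  spec$n_sa_ba - n_bind, replace = TRUE,
                                  prob = spec$length_dist))
        vapply(lens, function(L)
          paste(sample(res, L, replace = TRUE), collapse = ""), character(1))
      })
      peps <- c(binders, bg)
      s <- vapply(peps, pssm_score, numeric(1), pssm = world$pssms[[a]])
      s0 <- stats::median(s)
      k <- max(stats::sd(s), 1e-6)
      tgt <- 1 / (1 + exp(-(s - s0) / k))
      if (noise_sd > 0)
        tgt <- tgt + withr::with_seed(.derive_seed(seed, 6, i),
                                      stats::rnorm(length(tgt), 0, noise_sd))
      tgt <- pmin(1, pmax(0, tgt))
      ba[[a]] <- peptide_dataset(peps, tgt, a, assay = "BA", origin = "SA",
                                 tcfg = tcfg,
                                 length_bounds = spec$length_bounds)
    }
  }
  list(el = if (length(el)) do.call(bind_datasets, el) else NULL,
       ba = if (length(ba)) do.call(bind_datasets, ba) else NULL)
}

#' Plant an epitope in a random antigen
#'
#' Embeds the epitope at a random position of a background-sampled protein;
#' resampled until the epitope occurs exactly once.
#'
#' @param antigen_len Antigen length (>= epitope length).
#' @param epitope Epitope sequence.
#' @param seed Integer seed.
#' @return List: `antigen` (sequence string), `epitope`, `position` (1-based).
#' @export
plant_epitope <- function(antigen_len, epitope, seed = 1L) {
  k <- nchar(epitope)
  if (antigen_len < k) stop("antigen shorter than epitope")
  res <- aa_alphabet()$residues
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(100L)) {
      ant <- paste(sample(res, antigen_len, replace = TRUE), collapse = "")
      pos <- sample.int(antigen_len - k + 1L, 1)
      ant <- paste0(substr(ant, 1, pos - 1L), epitope,
                    substr(ant, pos + k, antigen_len))
      if (length(gregexpr(epitope, ant, fixed = TRUE)[[1]]) == 1L)
        return(list(antigen = ant, epitope = epitope, position = pos))
    }
  })
  stop("could not plant a unique epitope")
}

#' Simulate the full training inputs of a world
#'
#' Builds the SA (EL + BA) and MA datasets of every panel, enriches all EL
#' sets with random natural negatives (5x the most abundant positive length,
#' per individual dataset), removes SA EL records duplicated in the MA data
#' and returns everything needed to train and evaluate, together with the
#' hidden ground-truth annotation.
#'
#' @param world A [make_world()] result.
#' @param seed Integer seed (defaults to the world's spec seed).
#' @return List: `sa` (combined SA dataset), `ma` (combined MA dataset),
#'   `truth` (generating allele per MA record, `NA` for negatives), `panels`,
#'   `pseudo`, `proteome`.
#' @export
simulate_world_data <- function(world, seed = NULL) {
  spec <- world$spec
  if (is.null(seed)) seed <- spec$seed
  tcfg <- task_config("classI")
  sa <- build_sa_datasets(world, seed = .derive_seed(seed, 11), tcfg = tcfg)
  ma_parts <- lapply(names(world$panels), function(p)
    build_ma_dataset(world, p, spec$n_ma,
                     .derive_seed(seed, 12, match(p, names(world$panels))),
                     tcfg))
  names(ma_parts) <- names(world$panels)
  ma_pos <- do.call(bind_datasets, lapply(ma_parts, `[[`, "data"))
  ma <- enrich_negatives(ma_pos, world$proteome, .derive_seed(seed, 13))
  truth <- c(unlist(lapply(ma_parts, `[[`, "truth"), use.names = FALSE),
             rep(NA_character_, nrow(ma) - nrow(ma_pos)))
  sa_el <- if (!is.null(sa$el))
    enrich_negatives(sa$el, world$proteome, .derive_seed(seed, 14)) else NULL
  sa_el <- if (!is.null(sa_el)) dedupe_sa_vs_ma(sa_el, ma) else NULL
  sa_all <- do.call(bind_datasets,
                    Filter(Negate(is.null), list(sa_el, sa$ba)))
  list(sa = sa_all, ma = ma, truth = truth, panels = world$panels,
       pseudo = world$pseudo, proteome = world$proteome)
}

#' Write a simulated world to a fixture directory
#'
#' Emits the full plain-text fixture set: peptide TSVs, panel table,
#' pseudo-sequence table, proteome FASTA, ground-truth annotation TSV and a
#' JSON snapshot of the spec.
#'
#' @param sim A [simulate_world_data()] result.
#' @param dir Output directory (created; must not already contain a world).
#' @param spec The generating [world_spec()] (stored as JSON).
#' @export
write_world <- function(sim, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtab <- function(d, f) utils::write.table(
    data.frame(peptide = d$peptide, target = d$target, label = d$label),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  sa <- sim$sa
  wtab(sa[sa$assay == "BA", ], "sa_ba.tsv")
  wtab(sa[sa$assay == "EL", ], "sa_el.tsv")
  wtab(sim$ma, "ma_el.tsv")
  writeLines(paste0(names(sim$panels), "\t",
                    vapply(sim$panels, paste, character(1), collapse = ",")),
             file.path(dir, "panels.tsv"))
  writeLines(paste(names(sim$pseudo), sim$pseudo),
             file.path(dir, "pseudoseq.dat"))
  write_proteome(sim$proteome, file.path(dir, "proteome.fasta"))
  utils::write.table(
    data.frame(peptide = sim$ma$peptide, label = sim$ma$label,
               truth = sim$truth),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), file.path(dir, "world_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
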