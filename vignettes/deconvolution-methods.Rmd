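---
title: "Semi-supervised deconvolution of multi-allele MHC peptidomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised deconvolution of multi-allele MHC peptidomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mass-spectrometry immunopeptidomics measures the peptides presented by MHC
molecules on a cell surface. When the cell line expresses several MHC alleles
(the usual case: up to six class I molecules in human), every eluted ligand is
observed without knowing *which* allele presented it. Such multi-allele (MA)
data therefore mixes several binding motifs. Single-allele (SA) data — from
engineered mono-allelic cell lines or in-vitro binding-affinity (BA) assays —
carry an unambiguous allele label but cover far fewer alleles.

`mhcdecon` implements a semi-supervised scheme that uses the two together:
a pan-specific neural network is pre-trained on SA data, then MA ligands are
iteratively assigned ("annotated") to one allele of their cell line's panel
using rescaled prediction scores, merged into the training data, and the
network is retrained. At convergence the model has (i) per-allele binding
motifs for every allele occurring in any panel, including alleles with no SA
data at all, and (ii) a predictor whose allelic coverage extends to those
alleles.

## Model

Each training example is a peptide paired with an MHC pseudo-sequence — a
fixed 34-residue string of binding-groove contact residues that represents
the allele and makes the model pan-specific. A one-hidden-layer network with
logistic units maps the encoded input to **two output neurons**: one trained
on BA targets (IC50 transformed by `1 - log(ic50)/log(50000)`), one on EL
targets (0/1). The input-to-hidden weights are shared, so information flows
between the two data types; each output's hidden-to-output weights are
private and only updated by its own examples.

Peptides of length 8–14 (class I) are aligned to a 9-residue binding core by
*max-core selection*: every candidate core is scored and the maximum of the
requested output is taken. Candidate cores arise from a single contiguous
deletion block (longer peptides, block allowed at every position including
termini, deduplicated) or a wildcard insertion block at interior positions
(8mers). The wildcard `X` encodes to a zero vector. Inputs are
BLOSUM50-encoded (divided by 5), with auxiliary features: peptide-length
one-hot, scaled insertion/deletion lengths, and gross indel-position flags.
Class II (lengths 13–21) uses the same core semantics plus mean-encoded
peptide-flanking regions (3 residues per side); because the unified core
representation uses a single deletion block, flanking features are non-empty
exactly when the block touches a terminus.

Training is plain per-example stochastic gradient descent (squared error,
fixed learning rate 0.05), backpropagating through the argmax core only.
Ensembles average networks over hidden sizes, weight-initialization seeds and
five cross-validation folds; partitions are built with the common-motif rule
(peptides sharing any 8mer — 9mer for class II — are forced into the same
fold, transitively closed).

## The annotation loop

1. **Burn-in** (default 20 iterations): train on SA data only.
2. Afterwards, each iteration: for every allele appearing in an MA panel,
   estimate the distribution of raw EL scores on random natural 9mers
   (default 10,000), fitting mean and SD with iterative ±3 z-score outlier
   trimming. Using out-of-fold models only, compute for each positive MA
   record and each allele of its panel the z-score
   `z = (p − p̄′)/σ′`, assign the record to the argmax allele (ties to the
   lexicographically smallest name), tag each negative record with a random
   panel allele, merge with the SA data respecting the precomputed
   partitioning, and run one more training epoch.
3. The per-allele statistics are blended toward their across-allele averages
   on the schedule `w(x) = 1/(1 + exp((x − 75)/10))`:
   `p̄′ = w·p̄ + (1−w)·p̄_u`. Just after burn-in `w ≈ 1` (fully per-allele
   rescaling — this is what lets alleles far from the SA data compete at
   all); past ~100 iterations `w → 0` and the rescaling fades out as the MA
   data themselves anchor the score scale. The shift 75 is tunable; the
   method behaves similarly for values in 50–100.

Why rescaling matters: an allele distant from every SA allele receives
systematically lower raw scores from the pre-trained model, so raw-argmax
annotation starves it. Standardizing each allele's scores against its own
random-peptide distribution removes that offset. The engine exposes a
`score_bias` hook that depresses one allele's raw scores (annotation *and*
statistics) to demonstrate the effect deterministically: with rescaling the
depressed allele recovers its true ligand share, without it the share
collapses to zero.

## Evaluation statistics

* **AUC** (Mann–Whitney, ties 0.5) and **AUC0.1** (ROC area to FPR 0.1,
  normalized by 0.1) on concatenated out-of-fold predictions, per label; MA
  records are scored as the maximum over their panel.
* **PPV** per deconvoluted motif: with `N` ligands assigned to an allele, the
  fraction of true ligands among the top `⌊0.95·N⌋` of all records of the
  cell line ranked against that allele. The 5% slack absorbs expected MS
  noise. The ranked pool is the whole cell line (positives plus enriched
  negatives); the alternative reading (only records annotated to the allele)
  would make the tolerance meaningless.
* **Frank**: the source protein of an epitope is digested into overlapping
  8–14mers (class II: the epitope's own length), deduplicated; Frank is the
  fraction of peptides (epitope excluded from the denominator) scoring
  *strictly* higher than the epitope. Strict comparison is the only reading
  for which a perfect predictor scores exactly 0 and a random one 0.5 in
  expectation.
* **Motifs**: position × residue frequency matrices from the top 0.1% of
  200,000 scored random natural peptides (or from the predicted cores of
  annotated ligands), smoothed with a flat pseudocount of weight
  `1/(support+1)`; KL matrices weight each position's frequencies by its
  information content `log2(20) − H`. Motif similarity is the Pearson
  correlation of the flattened 9×20 frequency matrices.
* **Allele distance**: `1 − s(a,b)/√(s(a,a)·s(b,b))` over BLOSUM50
  similarities of aligned pseudo-sequence positions (the matrix underlying
  the published distance is not stated; BLOSUM50 is assumed and configurable).

## The synthetic world

Because the real training corpora are external and cluster-scale, every claim
the package tests is grounded in a generated world with known truth:

* Each allele is a 9×20 row-stochastic PSSM with two low-entropy anchors
  (positions 2 and 9, anchor mass 0.85) over a near-uniform background;
  PSSMs are rejection-resampled until all pairwise motif correlations are
  below 0.2 (well-separated motifs).
* Pseudo-sequences copy each motif's preferred residues into fixed contact
  positions of a shared random 34mer, so pseudo-sequence distance tracks
  motif dissimilarity — the substrate of pan-specific transfer. Alleles
  marked *distant* instead get a fully random pseudo-sequence (an MHC far
  from everything in training).
* The reference layout has 6 alleles and 4 panels with co-occurrence
  structure, one multi-allele-only allele (no SA data; the
  specificity-leave-out analogue), one low-abundance allele at 5% panel
  weight (the HLA-C analogue), and a private allele.
* Peptide lengths follow a 9mer-dominant class I distribution
  (8%, 60%, 14%, 8%, 5%, 3%, 2% for 8–14); EL sets are enriched with random
  proteome negatives at 5× the most abundant positive length, per length and
  per label; BA targets are a logistic transform of the PSSM log-odds score
  plus Gaussian noise (SD 0.05).

What a green test establishes: that the implementation deconvolutes mixtures
whose motifs are separable and whose pseudo-sequences are informative, at
desk scale. What it does not establish: performance on real spectra (no MS
noise model, no chromatography/FDR artifacts — deliberately out of scope),
nor the published full-scale benchmark numbers, which require the external
corpora and 50–250-network ensembles.

## Scale choices and numerical notes

* The reference world uses 2,000 MA positives per panel and 500 EL + 200 BA
  SA records per allele. The acceptance tests run a time-budgeted scale-down
  (300/150/75, 2,000 rescaling peptides, 50,000 motif peptides) with the
  mandated reduced ensemble (hidden 20, 2 seeds, 5 folds, 60 iterations,
  burn-in 20); sizes were fixed from flop estimates before any accuracy was
  measured and are not tuned.
* Weight initialization is uniform(−0.1, 0.1) per network seed (the
  published work specifies seeds but not the scheme). Early stopping keeps
  one shared snapshot per network at the best held-out mean per-output
  squared error, evaluated every iteration (per-output snapshots would be a
  defensible alternative; a single snapshot is used and flagged).
* The random 9mers used for score-distribution estimation are drawn once per
  run and re-scored each iteration; the estimation itself is repeated every
  iteration as required. "Positive normal" is read as a plain normal fit on
  the (already positive) trimmed scores, iterated to a fixpoint with a
  20-round cap.
* Degenerate inputs: a constant scorer makes the trimmed fit error out
  (degenerate distribution); alleles with zero assigned ligands are skipped
  in PPV with a message; labels with a single class are skipped in AUC with
  a message; an epitope absent from its antigen is an error.
* All randomness flows from explicit integer seeds through one documented
  derivation; the full training loop is bit-reproducible, and removing the
  MA data reproduces the SA-only trajectory exactly (the published SA
  baseline as a degenerate configuration).
* Configuration files and model serialization use JSON (full 17-digit
  precision, exact round trip); no YAML parser is assumed.

## Limitations

* Per-example SGD semantics are the reference; there is no minibatching or
  adaptive optimizer, by design.
* Hard argmax assignment only — no fractional multi-allele annotation.
* The common-motif partitioner follows the shared-k-mer reading
  (identical ungapped k-mer ⇒ same fold, transitive closure, greedy
  largest-first balancing); the historically exact clustering heuristic of
  the cited algorithm may differ in tie-breaking.
* Class II support is implemented (flanking features, 13–21mer bounds,
  9-position core) but the shipped synthetic benchmarks exercise class I.
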