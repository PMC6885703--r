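#' Cross-validation partitioning by the common-motif rule
#'
#' Two peptides sharing any identical ungapped subsequence of length >=
#' `motif_len` (8 for class I, the shortest binding mode; 9 for class II, the
#' binding-core size) must land in the same partition; the relation is closed
#' transitively, and the resulting clusters are distributed greedily
#' (largest cluster first, into the currently smallest partition, ties broken
#' by partition index) to balance record counts.
#'
#' @param records A `peptide_dataset` (or data.frame with a `peptide` column).
#' @param motif_len Motif length; must not exceed the shortest peptide.
#' @param n_parts Number of partitions (>= 2).
#' @param seed Seed controlling the order among equal-sized clusters.
#' @return The input with its `partition` column filled (integers in
#'   `0:(n_parts-1)`).
#' @export
common_motif_partition <- function(records, motif_len = 8L, n_parts = 5L,
                                   seed = 1L) {
  if (n_parts < 2L) stop("n_parts must be >= 2")
  len <- nchar(records$peptide)
  if (motif_len > min(len))
    stop("motif_len exceeds the shortest peptide length")
  n <- nrow(records)
  cl <- motif_clusters(records$peptide, motif_len)
  sizes <- tabulate(cl, nbins = max(cl))
  ord <- withr::with_seed(as.integer(seed), {
    key <- stats::runif(length(sizes))
    order(-sizes, key)
  })
  totals <- numeric(n_parts)
  assign_part <- integer(length(sizes))
  for (c_id in ord) {
    p <- which.min(totals) # ties: lowest index (which.min contract)
    assign_part[c_id] <- p - 1L
    totals[p] <- totals[p] + sizes[c_id]
  }
  records$partition <- assign_part[cl]
  records
}

# Transitive closure of the shared-k-mer relation; returns cluster id per record.
motif_clusters <- function(peptides, motif_len) {
  n <- length(peptides)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  kmers <- lapply(peptides, function(p) {
    L <- nchar(p)
    unique(substring(p, 1:(L - motif_len + 1), motif_len:L))
  })
  rec <- rep.int(seq_len(n), lengths(kmers))
  km <- unlist(kmers, use.names = FALSE)
  groups <- split(rec, km)
  for (g in groups) {
    if (length(g) > 1L) {
      r0 <- find(g[1])
      for (i in g[-1]) {
        ri <- find(i)
        if (ri != r0) parent[ri] <- r0
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
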