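# Small builders used across the test files.

# sync_table from a list of per-pool count vectors; each element of `pools`
# is a length-6 integer vector (A,T,C,G,N,del) or a sites x 6 matrix
make_sync <- function(chrom, pos, ref, pool_counts) {
  S <- length(pos)
  npool <- length(pool_counts)
  counts <- array(0L, c(S, npool, 6L))
  for (j in seq_len(npool)) {
    m <- pool_counts[[j]]
    if (is.null(dim(m))) m <- matrix(m, S, 6L, byrow = TRUE)
    counts[, j, ] <- m
  }
  sync_table(chrom, pos, ref, counts)
}

# one biallelic site: per-pool (ref count, alt count), ref A / alt T
site_counts <- function(ref_n, alt_n) {
  c(ref_n, alt_n, 0L, 0L, 0L, 0L)
}

# snp_table straight from depth and minor-frequency matrices
make_snps <- function(depth, freq, chrom = "chr1",
                      pos = seq_len(nrow(depth)) * 100L,
                      pools = paste0("pool", seq_len(ncol(depth)))) {
  depth <- as.matrix(depth)
  freq <- as.matrix(freq)
  colnames(depth) <- colnames(freq) <- pools
  x <- list(chrom = rep(chrom, length.out = nrow(depth)), pos = as.integer(pos),
            major = rep("A", nrow(depth)), minor = rep("T", nrow(depth)),
            count = round(depth * freq), depth = depth, freq = freq,
            pools = pools)
  class(x) <- "snp_table"
  x
}

# tiny config for fast simulation tests (its own full-scale design)
tiny_config <- function(...) {
  args <- list(n_anc = 60L, n_deme = 60L, t_burn = 60L, t_split = 150L,
               chrom_len = 5e5, mu = 4e-6, rec = 3e-7, n_chrom = 3L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# brute-force best clipped subinterval score (local-score oracle)
brute_max_subinterval <- function(scores) {
  n <- length(scores)
  best <- 0
  for (i in seq_len(n))
    for (j in i:n)
      best <- max(best, sum(scores[i:j]))
  best
}

# exhaustive hypergeometric upper tail by enumerating all draws (N <= 12)
enum_hyper_tail <- function(N, B, n, b) {
  draws <- utils::combn(N, n)
  # the first B elements of 1..N carry the term
  hits <- colSums(draws <= B)
  mean(hits >= b)
}
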