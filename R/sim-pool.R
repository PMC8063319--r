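#' Truncated-normal integer depths by rejection
#'
#' Draws from Normal(mean, sd), rounds to the nearest integer and rejects
#' values outside `[lo, hi]` (bounds applied after rounding).
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters.
#' @param lo,hi Inclusive integer bounds.
#' @return Integer vector of length `n`.
#' @export
rdepth_truncnorm <- function(n, mean = 23, sd = 5, lo = 15L, hi = 50L) {
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    d <- as.integer(round(stats::rnorm(length(todo), mean, sd)))
    ok <- d >= lo & d <= hi
    out[todo[ok]] <- d[ok]
    todo <- todo[!ok]
  }
  out
}

#' Pool-sequence a truth panel
#'
#' Emulates pooled sequencing of each deme: at every site and pool an integer
#' depth is drawn independently from the truncated normal of `config`, then
#' the derived-read count is Binomial(depth, deme frequency).  Reference and
#' derived bases are assigned per site (reference uniform over A/C/G/T,
#' derived uniform over the remaining three) so the output exercises the full
#' sync dialect.
#'
#' @param truth A `truth_panel` from [simulate_history()].
#' @param config A [sim_config()] (depth model).
#' @param seed Integer seed for depths, read draws and base assignment.
#' @param chrom Chromosome name for the emitted records.
#' @return A [sync_table()] with one pool per deme, plus attribute `depth`
#'   (sites x pools integer matrix) and `alt` (derived base per site).
#' @export
sample_pool <- function(truth, config, seed, chrom = "chr1") {
  stopifnot(inherits(truth, "truth_panel"))
  validate_sim_config(config)
  set.seed(as.integer(seed))
  S <- length(truth$positions)
  npop <- ncol(truth$freqs)
  depth <- matrix(rdepth_truncnorm(S * npop, config$depth_mean,
                                   config$depth_sd, config$depth_min,
                                   config$depth_max), S, npop)
  alt_reads <- matrix(stats::rbinom(S * npop, depth, truth$freqs), S, npop)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alternatives <- t(vapply(bases, function(b) setdiff(bases, b),
                           character(3)))
  alt <- alternatives[cbind(match(ref, bases), sample.int(3L, S, TRUE))]
  counts <- array(0L, c(S, npop, 6L))
  ref_idx <- match(ref, SYNC_BASES)
  alt_idx <- match(alt, SYNC_BASES)
  for (j in seq_len(npop)) {
    counts[cbind(seq_len(S), j, ref_idx)] <- depth[, j] - alt_reads[, j]
    counts[cbind(seq_len(S), j, alt_idx)] <-
      counts[cbind(seq_len(S), j, alt_idx)] + alt_reads[, j]
  }
  out <- sync_table(rep(chrom, S), truth$positions, ref, counts)
  attr(out, "depth") <- depth
  attr(out, "alt") <- unname(alt)
  out
}

#' Global minor-allele frequency from pooled read counts
#'
#' MAF at each site computed from base counts summed across all pools
#' (N and del are not alleles): 1 minus the frequency of the most common
#' base, folded about the major allele.
#'
#' @param sync A [sync_table()].
#' @return Numeric vector of global MAFs (minor-allele read fraction).
#' @export
global_maf <- function(sync) {
  stopifnot(inherits(sync, "sync_table"))
  tot <- pooled_base_counts(sync)
  dep <- rowSums(tot)
  maj <- pmax(tot[, 1], tot[, 2], tot[, 3], tot[, 4])
  ifelse(dep > 0, 1 - maj / dep, NA_real_)
}

# sites x 4 matrix of A/T/C/G read counts summed over pools
pooled_base_counts <- function(sync) {
  S <- length(sync$pos)
  out <- matrix(0L, S, 4L, dimnames = list(NULL, SYNC_BASES[1:4]))
  for (b in 1:4)
    out[, b] <- as.integer(rowSums(sync$counts[, , b, drop = FALSE]))
  out
}

#' Simulate a pooled pseudo-genome
#'
#' Simulates `n_chrom` independent chromosomes under `config`, pool-samples
#' each, concatenates them into one pseudo-genome and applies the global MAF
#' filter (pooled-read MAF `> maf_min`).  Every chromosome's history and
#' pooling use deterministic sub-seeds derived from `seed`, so identical
#' `(config, seed)` pairs give byte-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return List with `sync` (the MAF-filtered [sync_table()]), `truth` (the
#'   matching truth rows: `chrom`, `positions`, `freqs`, `n_hap`), and
#'   `n_sites` (c(segregating = before pooling/filter, maf_pass = emitted)).
#' @export
simulate_pseudo_genome <- function(config, seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  sub <- matrix(sample.int(.Machine$integer.max - 1L, 2L * config$n_chrom),
                ncol = 2L)
  chroms <- vector("list", config$n_chrom)
  truths <- vector("list", config$n_chrom)
  for (k in seq_len(config$n_chrom)) {
    tp <- simulate_history(config, chrom_seed = sub[k, 1L])
    chroms[[k]] <- sample_pool(tp, config, seed = sub[k, 2L],
                               chrom = sprintf("chr%02d", k))
    truths[[k]] <- tp
  }
  counts <- do.call(abind3, lapply(chroms, `[[`, "counts"))
  sync <- sync_table(
    chrom = unlist(lapply(chroms, `[[`, "chrom")),
    pos = unlist(lapply(chroms, `[[`, "pos")),
    ref = unlist(lapply(chroms, `[[`, "ref")),
    counts = counts
  )
  truth <- list(
    chrom = rep(vapply(seq_len(config$n_chrom),
                       function(k) sprintf("chr%02d", k), ""),
                vapply(truths, function(t) length(t$positions), 1L)),
    positions = unlist(lapply(truths, `[[`, "positions")),
    freqs = do.call(rbind, lapply(truths, `[[`, "freqs")),
    n_hap = truths[[1L]]$n_hap
  )
  keep <- global_maf(sync) > config$maf_min
  keep[is.na(keep)] <- FALSE
  list(
    sync = sync[keep],
    truth = list(chrom = truth$chrom[keep],
                 positions = truth$positions[keep],
                 freqs = truth$freqs[keep, , drop = FALSE],
                 n_hap = truth$n_hap),
    n_sites = c(segregating = length(keep), maf_pass = sum(keep))
  )
}

# bind site x pool x 6 arrays along sites
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  out <- array(0L, c(sum(vapply(parts, function(p) dim(p)[1], 1L)),
                     d[2], d[3]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    if (n) out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}
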