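#' Per-SNP FST variance components
#'
#' Computes, for each SNP, the numerator and denominator of an FST estimator
#' from per-pool read depths and allele frequencies, treating read depth as
#' the haploid sample size (standard pool-seq practice).
#'
#' `method = "wc"` is the two-level haploid (allele-count) Weir-Cockerham
#' estimator.  With `r` pools, `nbar = sum(n_i)/r`,
#' `nc = (sum(n_i) - sum(n_i^2)/sum(n_i)) / (r - 1)`,
#' `pbar = sum(n_i p_i)/sum(n_i)` and
#' `s2 = sum(n_i (p_i - pbar)^2) / ((r - 1) nbar)`, the among-population
#' component is
#' `a = (nbar/nc) * (s2 - (pbar (1-pbar) - s2 (r-1)/r) / (nbar - 1))`
#' and the within component
#' `b = (nbar/(nbar-1)) * (pbar (1-pbar) - s2 (r-1)/r)`; the point estimate
#' is `a / (a + b)` (negative per-SNP values are legitimate).
#'
#' `method = "karlsson"` (two pools only) uses
#' `h_i = (n_i/(n_i-1)) p_i (1-p_i)`,
#' `N = (p_1-p_2)^2 - h_1/n_1 - h_2/n_2`, `D = N + h_1 + h_2`, `F = N/D`.
#'
#' Monomorphic identical sites give a zero denominator: the estimate is `NA`
#' but the components are still returned for window ratio-of-sums pooling.
#'
#' @param depth SNPs x pools matrix (or vector for one SNP) of haploid sample
#'   sizes (read depths); every entry must be `>= 2`.
#' @param freq Matching matrix/vector of allele frequencies (same allele
#'   orientation across pools).
#' @param method `"wc"` (any number of pools) or `"karlsson"` (two pools).
#' @return List with numeric vectors `num`, `den`, `est` (one entry per SNP).
#' @export
fst_snp <- function(depth, freq, method = c("wc", "karlsson")) {
  method <- match.arg(method)
  if (is.null(dim(depth))) depth <- matrix(depth, nrow = 1L)
  if (is.null(dim(freq))) freq <- matrix(freq, nrow = 1L)
  stopifnot(all(dim(depth) == dim(freq)), ncol(depth) >= 2L)
  if (any(depth < 2L)) stop("haploid sample sizes (depths) must be >= 2")
  r <- ncol(depth)
  if (method == "wc") {
    n_tot <- rowSums(depth)
    nbar <- n_tot / r
    nc <- (n_tot - rowSums(depth^2) / n_tot) / (r - 1)
    pbar <- rowSums(depth * freq) / n_tot
    s2 <- rowSums(depth * (freq - pbar)^2) / ((r - 1) * nbar)
    inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
    a <- (nbar / nc) * (s2 - inner / (nbar - 1))
    b <- (nbar / (nbar - 1)) * inner
    num <- a
    den <- a + b
  } else {
    if (r != 2L) stop("the Karlsson estimator is defined for exactly 2 pools")
    h <- (depth / (depth - 1)) * freq * (1 - freq)
    num <- (freq[, 1] - freq[, 2])^2 - h[, 1] / depth[, 1] -
      h[, 2] / depth[, 2]
    den <- num + h[, 1] + h[, 2]
  }
  list(num = num, den = den, est = ifelse(den != 0, num / den, NA_real_))
}

window_index <- function(pos, window) {
  as.integer(floor((pos - 1) / window) + 1L)
}

all_pairs <- function(pools) {
  idx <- utils::combn(seq_along(pools), 2L)
  lapply(seq_len(ncol(idx)), function(k) idx[, k])
}

pair_label <- function(pools, pair) paste(pools[pair], collapse = ".")

#' Window FST from a SNP table
#'
#' Non-overlapping windows of `window` bp tile each chromosome (window `k`
#' spans `[(k-1)*window + 1, k*window]`).  The FST of a window is the ratio
#' of sums of the per-SNP components over its SNPs; windows with fewer than
#' `min_snps` SNPs report `NA`.  One column per pool pair is produced, plus
#' (for `method = "wc"`) a column over all pools jointly.
#'
#' @param snps A `snp_table` (sorted by position within chromosome).
#' @param window Window size in bp (default 100 kb).
#' @param method FST estimator passed to [fst_snp()].
#' @param min_snps Minimum SNPs for a defined window estimate.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, one
#'   `fst_<p1>.<p2>` column per pair and (wc only) `fst_all`.
#' @export
fst_windows <- function(snps, window = 1e5, method = c("wc", "karlsson"),
                        min_snps = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(snps, "snp_table"))
  base <- window_frame(snps, window)
  key <- paste(base$map$chrom, base$map$win)
  pairs <- all_pairs(snps$pools)
  for (pair in pairs) {
    comp <- fst_snp(snps$depth[, pair, drop = FALSE],
                    snps$freq[, pair, drop = FALSE], method = method)
    base$frame[[paste0("fst_", pair_label(snps$pools, pair))]] <-
      ratio_of_sums(comp, key, base$levels, base$frame$n_snps, min_snps)
  }
  if (method == "wc" && length(snps$pools) > 2L) {
    comp <- fst_snp(snps$depth, snps$freq, method = "wc")
    base$frame$fst_all <-
      ratio_of_sums(comp, key, base$levels, base$frame$n_snps, min_snps)
  }
  base$frame
}

# shared scaffolding: contiguous windows per chromosome incl. empty ones
window_frame <- function(snps, window) {
  win <- window_index(snps$pos, window)
  chroms <- unique(snps$chrom)
  per_chrom <- lapply(chroms, function(ch) {
    mx <- max(win[snps$chrom == ch])
    data.frame(chrom = ch, window = seq_len(mx))
  })
  frame <- do.call(rbind, per_chrom)
  frame$start <- (frame$window - 1L) * as.integer(window) + 1L
  frame$end <- frame$window * as.integer(window)
  levels <- paste(frame$chrom, frame$window)
  key <- paste(snps$chrom, win)
  frame$n_snps <- as.integer(table(factor(key, levels = levels)))
  frame$window <- NULL
  list(frame = frame, levels = levels,
       map = data.frame(chrom = snps$chrom, win = win))
}

ratio_of_sums <- function(comp, key, levels, n_snps, min_snps) {
  f <- factor(key, levels = levels)
  num <- as.numeric(tapply(comp$num, f, sum, default = 0))
  den <- as.numeric(tapply(comp$den, f, sum, default = 0))
  out <- ifelse(den > 0 | den < 0, num / den, NA_real_)
  out[n_snps < min_snps] <- NA_real_
  out
}
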