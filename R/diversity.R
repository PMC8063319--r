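#' Window nucleotide diversity and absolute divergence
#'
#' Per variant site the depth-corrected heterozygosity is
#' `pi_hat = (n/(n-1)) * 2 p (1-p)` with `n` the pool read depth, and the
#' absolute divergence between pools 1 and 2 is
#' `dxy_hat = p1 (1-p2) + p2 (1-p1)`.  A window's value is the sum over its
#' variant sites divided by the number of covered sites (sites passing the
#' depth filters, monomorphic included).  By default every bp of the window
#' is taken as covered, which is exact for simulated data where depth never
#' leaves the retention bounds; pass `covered` to supply a mask-derived
#' count.  Windows with zero covered sites report `NA`.
#'
#' @param snps A `snp_table`.
#' @param window Window size in bp (default 100 kb).
#' @param covered Either `NULL` (all `window` bp covered), or a data.frame
#'   `chrom`, `start`, `covered_sites` matching the emitted windows.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`,
#'   `covered_sites`, one `pi_<pool>` column per pool and one
#'   `dxy_<p1>.<p2>` column per pair.
#' @export
diversity_windows <- function(snps, window = 1e5, covered = NULL) {
  stopifnot(inherits(snps, "snp_table"))
  base <- window_frame(snps, window)
  frame <- base$frame
  key <- factor(paste(base$map$chrom, base$map$win), levels = base$levels)
  if (is.null(covered)) {
    frame$covered_sites <- as.integer(window)
  } else {
    m <- match(paste(frame$chrom, frame$start), paste(covered$chrom,
                                                      covered$start))
    frame$covered_sites <- covered$covered_sites[m]
  }
  for (j in seq_along(snps$pools)) {
    n <- snps$depth[, j]
    p <- snps$freq[, j]
    site_pi <- (n / (n - 1)) * 2 * p * (1 - p)
    tot <- as.numeric(tapply(site_pi, key, sum, default = 0))
    frame[[paste0("pi_", snps$pools[j])]] <-
      ifelse(frame$covered_sites > 0, tot / frame$covered_sites, NA_real_)
  }
  for (pair in all_pairs(snps$pools)) {
    p1 <- snps$freq[, pair[1]]
    p2 <- snps$freq[, pair[2]]
    site_dxy <- p1 * (1 - p2) + p2 * (1 - p1)
    tot <- as.numeric(tapply(site_dxy, key, sum, default = 0))
    frame[[paste0("dxy_", pair_label(snps$pools, pair))]] <-
      ifelse(frame$covered_sites > 0, tot / frame$covered_sites, NA_real_)
  }
  frame
}
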