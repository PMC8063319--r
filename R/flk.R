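#' Lewontin-Krakauer (LK) test per SNP
#'
#' Standardizes each SNP's multi-population Weir-Cockerham estimate against
#' the genome-wide mean: `T_LK = (r - 1) * theta_l / mean(theta)`, where
#' negative per-SNP estimates are clamped to 0 before scaling and the mean
#' runs over SNPs with a defined estimate.  Significance comes from the
#' upper tail of a chi-square with `r - 1` degrees of freedom; clamped SNPs
#' get `T = 0`, `p = 1`.
#'
#' @param snps A `snp_table` with at least two pools.
#' @return data.frame with `chrom`, `pos`, `T_lk`, `p_lk`.
#' @export
lk_test <- function(snps) {
  stopifnot(inherits(snps, "snp_table"))
  r <- length(snps$pools)
  if (r < 2L) stop("the LK test needs at least two populations")
  comp <- fst_snp(snps$depth, snps$freq, method = "wc")
  theta <- pmax(comp$est, 0)
  mbar <- mean(theta, na.rm = TRUE)
  if (!is.finite(mbar) || mbar <= 0)
    stop("mean per-SNP theta is not positive; LK scaling undefined")
  T_lk <- (r - 1) * theta / mbar
  p <- stats::pchisq(T_lk, df = r - 1, lower.tail = FALSE)
  data.frame(chrom = snps$chrom, pos = snps$pos, T_lk = T_lk,
             p_lk = pmin(pmax(p, .Machine$double.xmin), 1))
}

#' FLK test per SNP
#'
#' The LK test extended with the population kinship matrix `F` of
#' [build_kinship()], which accounts for unequal drift among populations.
#' Per SNP the ancestral frequency is estimated as
#' `p0 = (1' F^-1 p) / (1' F^-1 1)` (clamped to `[0, 1]`); the statistic is
#' the quadratic form `T_FLK = (p - p0 1)' V^-1 (p - p0 1)` with
#' `V = F * p0 (1 - p0)`, referred to a chi-square with
#' `n_tested - 1` degrees of freedom.  SNPs whose estimated ancestral
#' frequency is 0 or 1 carry no information about drift and are dropped from
#' testing (`NA` statistics).
#'
#' @param snps A `snp_table`.
#' @param kinship A `kinship_model` whose pools match `snps`.
#' @param include_outgroup If `FALSE`, the outgroup is excluded from the
#'   tested set (degrees of freedom drop accordingly).
#' @return data.frame with `chrom`, `pos`, `T_flk`, `p_flk`, `p0`.
#' @export
flk_test <- function(snps, kinship, include_outgroup = TRUE) {
  stopifnot(inherits(snps, "snp_table"), inherits(kinship, "kinship_model"))
  if (!identical(sort(kinship$pops), sort(snps$pools)))
    stop("kinship model and SNP table name different populations")
  tested <- if (include_outgroup) kinship$pops else
    setdiff(kinship$pops, kinship$outgroup)
  Fm <- kinship$F[tested, tested, drop = FALSE]
  Finv <- solve(Fm)
  p <- snps$freq[, tested, drop = FALSE]
  w <- colSums(Finv)
  p0 <- as.numeric(p %*% w) / sum(w)
  p0 <- pmin(pmax(p0, 0), 1)
  resid <- p - p0
  quad <- rowSums((resid %*% Finv) * resid)
  v <- p0 * (1 - p0)
  T_flk <- ifelse(v > 0, quad / v, NA_real_)
  pv <- stats::pchisq(T_flk, df = length(tested) - 1, lower.tail = FALSE)
  data.frame(chrom = snps$chrom, pos = snps$pos, T_flk = T_flk,
             p_flk = pmin(pmax(pv, .Machine$double.xmin), 1), p0 = p0)
}
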