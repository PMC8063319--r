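#' Choose the local-score offset xi
#'
#' The per-SNP score of the Lindley process is `-log10(p) - xi`.  A valid
#' `xi` lies between the mean and the maximum of the `-log10(p)`
#' distribution; here it is the empirical 85% quantile (computed genome-wide
#' per statistic), raised to the mean with a warning in the rare case the
#' quantile falls below it.
#'
#' @param pvalues Nonempty p-values in `(0, 1]` (`NA` ignored).
#' @param quantile Quantile level of the `-log10(p)` distribution
#'   (default 0.85).
#' @return The offset `xi` (a single number).
#' @export
choose_xi <- function(pvalues, quantile = 0.85) {
  x <- -log10(pvalues[!is.na(pvalues)])
  if (!length(x)) stop("no p-values available to choose xi")
  if (any(x < 0)) stop("p-values must lie in (0, 1]")
  xi <- stats::quantile(x, quantile, names = FALSE, type = 7)
  m <- mean(x)
  if (xi < m) {
    warning("the ", quantile, " quantile of -log10(p) falls below its mean; ",
            "raising xi to the mean")
    xi <- m
  }
  stopifnot(m <= xi, xi <= max(x))
  xi
}

#' Lindley local-score track
#'
#' The clipped-at-zero cumulative sum of per-SNP scores along a chromosome:
#' `h[i] = max(0, h[i-1] + (-log10(p[i]) - xi))` with `h[0] = 0`.  Excursions
#' of this track above zero mark runs of adjacent SNPs with elevated
#' differentiation.
#'
#' @param pvalues P-values ordered by genomic position within one chromosome.
#' @param xi Score offset from [choose_xi()].
#' @return Numeric vector `h` (same length as `pvalues`, all `>= 0`).
#' @export
lindley_track <- function(pvalues, xi) {
  s <- -log10(pvalues) - xi
  cs <- cumsum(s)
  cs - pmin(cummin(cs), 0)
}

#' Chromosome-wide local-score significance threshold
#'
#' Monte-Carlo calibration under independence: the chromosome's `-log10(p)`
#' values are resampled with replacement `B` times (each resample the length
#' of the chromosome), and the threshold is the empirical `1 - alpha`
#' quantile of the `B` Lindley-track maxima.  Under truly i.i.d. p-values an
#' `alpha` fraction of chromosomes then exceeds their threshold; linkage
#' between SNPs inflates the real exceedance rate above `alpha`.
#'
#' @param pvalues One chromosome's p-values (`NA` dropped).
#' @param xi Score offset (use the genome-wide [choose_xi()] value).
#' @param alpha Chromosome-wide error rate (default 0.05).
#' @param B Number of resamples (`>= 100`).
#' @return The significance threshold (positive number; 0 when every
#'   resampled track stays at zero, in which case no call is made).
#' @export
calibrate_threshold <- function(pvalues, xi, alpha = 0.05, B = 500L) {
  stopifnot(B >= 100L, alpha > 0, alpha < 1)
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) return(0)
  scores <- -log10(p) - xi
  maxima <- .lindley_max_boot(scores, length(scores), as.integer(B))
  stats::quantile(maxima, 1 - alpha, names = FALSE, type = 7)
}

#' Call significant local-score regions
#'
#' Decomposes the Lindley track into excursions (maximal runs with `h > 0`)
#' and keeps those whose peak reaches `threshold`.  A region spans the first
#' SNP of its excursion through the last SNP before the track returns to
#' zero (or the chromosome end); the peak position is the first argmax.
#'
#' @param track Lindley track from [lindley_track()].
#' @param threshold Positive threshold from [calibrate_threshold()]; if not
#'   `> 0`, no regions are called.
#' @param positions bp positions matching `track`.
#' @param chrom Chromosome label for the output.
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `start_idx`,
#'   `end_idx`, `peak`, `peak_bp`, `n_snps` (zero rows when nothing is
#'   significant).
#' @export
call_regions <- function(track, threshold, positions, chrom = "chr1") {
  stopifnot(length(track) == length(positions))
  empty <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), start_idx = integer(0),
                      end_idx = integer(0), peak = numeric(0),
                      peak_bp = integer(0), n_snps = integer(0))
  if (!length(track) || !is.finite(threshold) || threshold <= 0) return(empty)
  pos_run <- track > 0
  if (!any(pos_run)) return(empty)
  r <- rle(pos_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- lapply(which(keep), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    h <- track[i0:i1]
    peak <- max(h)
    if (peak < threshold) return(NULL)
    ipk <- i0 + which.max(h) - 1L
    data.frame(chrom = chrom, start_bp = positions[i0], end_bp = positions[i1],
               start_idx = i0, end_idx = i1, peak = peak,
               peak_bp = positions[ipk], n_snps = i1 - i0 + 1L)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Local-score scan of a whole genome of p-values
#'
#' Convenience wrapper tying the pieces together: chooses `xi` genome-wide,
#' calibrates a Monte-Carlo threshold per chromosome, and calls significant
#' regions on each chromosome's Lindley track.
#'
#' @param pv data.frame with `chrom`, `pos` and a p-value column.
#' @param p_col Name of the p-value column.
#' @param xi_quantile Quantile level for [choose_xi()].
#' @param alpha Chromosome-wide error rate.
#' @param B Resamples per chromosome for [calibrate_threshold()].
#' @return List with `xi`, `thresholds` (per chromosome) and `regions`
#'   (row-bound [call_regions()] output).
#' @export
local_score_scan <- function(pv, p_col, xi_quantile = 0.85, alpha = 0.05,
                             B = 500L) {
  stopifnot(all(c("chrom", "pos", p_col) %in% names(pv)))
  pv <- pv[!is.na(pv[[p_col]]), , drop = FALSE]
  pv <- pv[order(pv$chrom, pv$pos), , drop = FALSE]
  xi <- choose_xi(pv[[p_col]], xi_quantile)
  chroms <- unique(pv$chrom)
  thresholds <- numeric(length(chroms))
  names(thresholds) <- chroms
  regions <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    sel <- pv$chrom == chroms[i]
    p <- pv[[p_col]][sel]
    thresholds[i] <- calibrate_threshold(p, xi, alpha = alpha, B = B)
    regions[[i]] <- call_regions(lindley_track(p, xi), thresholds[i],
                                 pv$pos[sel], chrom = chroms[i])
  }
  list(xi = xi, thresholds = thresholds, regions = do.call(rbind, regions))
}
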