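#' SNP-retention parameters
#'
#' The retention rules applied to pooled sites before estimation: exactly two
#' alleles (bases with nonzero pooled counts; N/del never count as alleles),
#' global minor-allele frequency above `maf_min` (computed from read counts
#' summed over pools), at least `min_minor_copies` pooled copies of the minor
#' allele (guards against sequencing error), and per-pool sequencing depth
#' within `[depth_min, depth_max]` in every pool.  Optional exclusion
#' intervals (e.g. around indels) drop sites outright.
#'
#' @param require_biallelic Keep only sites with exactly two alleles.
#' @param maf_min Global MAF cutoff (strict `>`).
#' @param min_minor_copies Minimum pooled minor-allele read count.
#' @param depth_min,depth_max Inclusive per-pool depth bounds.
#' @param exclude Optional data.frame of intervals (`chrom`, `start`, `end`,
#'   1-based inclusive) whose sites are dropped.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(require_biallelic = TRUE, maf_min = 0.05,
                          min_minor_copies = 2L, depth_min = 15L,
                          depth_max = 50L, exclude = NULL) {
  stopifnot(maf_min >= 0, maf_min < 0.5, depth_min <= depth_max,
            min_minor_copies >= 0)
  if (!is.null(exclude))
    stopifnot(all(c("chrom", "start", "end") %in% names(exclude)))
  p <- list(require_biallelic = isTRUE(require_biallelic),
            maf_min = maf_min, min_minor_copies = as.integer(min_minor_copies),
            depth_min = as.integer(depth_min),
            depth_max = as.integer(depth_max), exclude = exclude)
  class(p) <- "filter_params"
  p
}

#' Filter pooled sites into a biallelic SNP table
#'
#' Applies the retention rules of [filter_params()] to a [sync_table()] and
#' returns the per-pool minor-allele counts, depths and frequencies of the
#' retained SNPs.  Depth is the per-pool sum of the four base counts; the
#' minor allele is the base with the smaller pooled count (ties broken by
#' A:T:C:G order: earlier wins major, later wins minor).  Filtering is
#' idempotent.
#'
#' @param sync A [sync_table()] sorted by (chrom, pos).
#' @param params A [filter_params()].
#' @return An object of class `snp_table`: list with `chrom`, `pos`, `major`,
#'   `minor` (vectors over SNPs) and `count`, `depth`, `freq`
#'   (SNPs x pools matrices of minor-allele counts, depths and frequencies).
#' @export
filter_snps <- function(sync, params = filter_params()) {
  stopifnot(inherits(sync, "sync_table"), inherits(params, "filter_params"))
  if (!sync_is_sorted(sync)) stop("sync records must be sorted by (chrom, pos)")
  S <- length(sync$pos)
  if (S == 0L) {
    out <- list(chrom = character(0), pos = integer(0), major = character(0),
                minor = character(0),
                count = matrix(0L, 0L, length(sync$pools),
                               dimnames = list(NULL, sync$pools)),
                depth = matrix(0L, 0L, length(sync$pools),
                               dimnames = list(NULL, sync$pools)),
                freq = matrix(numeric(0), 0L, length(sync$pools),
                              dimnames = list(NULL, sync$pools)),
                pools = sync$pools)
    class(out) <- "snp_table"
    return(out)
  }
  base_tot <- pooled_base_counts(sync)
  n_alleles <- rowSums(base_tot > 0L)
  keep <- if (params$require_biallelic) n_alleles == 2L else n_alleles >= 2L

  # allele identity: major = larger pooled count, ties broken towards the
  # base earlier in A:T:C:G order (major) / later (minor)
  rk <- max.col(base_tot, ties.method = "first")
  major_idx <- rk
  masked <- base_tot
  masked[cbind(seq_len(S), rk)] <- -1L
  minor_idx <- max.col(masked, ties.method = "last")
  maj_n <- base_tot[cbind(seq_len(S), major_idx)]
  min_n <- base_tot[cbind(seq_len(S), minor_idx)]
  tot_n <- maj_n + min_n
  keep <- keep & tot_n > 0L & (min_n / pmax(tot_n, 1L)) > params$maf_min &
    min_n >= params$min_minor_copies

  npool <- length(sync$pools)
  depth <- matrix(0L, S, npool)
  for (j in seq_len(npool))
    depth[, j] <- as.integer(rowSums(sync$counts[, j, 1:4, drop = FALSE]))
  in_bounds <- depth >= params$depth_min & depth <= params$depth_max
  keep <- keep & (rowSums(in_bounds) == npool)

  if (!is.null(params$exclude) && nrow(params$exclude)) {
    ex <- params$exclude
    for (i in seq_len(nrow(ex))) {
      keep <- keep & !(sync$chrom == ex$chrom[i] & sync$pos >= ex$start[i] &
                         sync$pos <= ex$end[i])
    }
  }

  idx <- which(keep)
  cnt <- matrix(0L, length(idx), length(sync$pools),
                dimnames = list(NULL, sync$pools))
  for (j in seq_along(sync$pools))
    cnt[, j] <- sync$counts[cbind(idx, j, minor_idx[idx])]
  dp <- depth[idx, , drop = FALSE]
  colnames(dp) <- sync$pools
  out <- list(chrom = sync$chrom[idx], pos = sync$pos[idx],
              major = SYNC_BASES[major_idx[idx]],
              minor = SYNC_BASES[minor_idx[idx]],
              count = cnt, depth = dp, freq = cnt / dp,
              pools = sync$pools)
  class(out) <- "snp_table"
  out
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs, %d pools (%s)\n", length(x$pos),
              length(x$pools), paste(x$pools, collapse = ", ")))
  invisible(x)
}

#' Number of SNPs in a SNP table
#' @param x A `snp_table`.
#' @return Integer SNP count.
#' @export
n_snps <- function(x) {
  stopifnot(inherits(x, "snp_table"))
  length(x$pos)
}

#' Convert a SNP table to a data.frame
#' @param x A `snp_table`.
#' @param ... Unused.
#' @return data.frame with per-pool frequency columns `freq_<pool>`.
#' @export
as.data.frame.snp_table <- function(x, ...) {
  df <- data.frame(chrom = x$chrom, pos = x$pos, major = x$major,
                   minor = x$minor)
  fr <- as.data.frame(x$freq)
  names(fr) <- paste0("freq_", x$pools)
  cbind(df, fr)
}

#' Rebuild the sync representation of a SNP table
#'
#' Inverse-direction helper used for idempotence checks: emits a
#' [sync_table()] whose only nonzero base counts are the major and minor
#' alleles of each SNP.
#'
#' @param snps A `snp_table`.
#' @return A [sync_table()].
#' @export
snp_table_as_sync <- function(snps) {
  stopifnot(inherits(snps, "snp_table"))
  S <- length(snps$pos)
  counts <- array(0L, c(S, length(snps$pools), 6L))
  maj_idx <- match(snps$major, SYNC_BASES)
  min_idx <- match(snps$minor, SYNC_BASES)
  for (j in seq_along(snps$pools)) {
    counts[cbind(seq_len(S), j, maj_idx)] <- snps$depth[, j] - snps$count[, j]
    counts[cbind(seq_len(S), j, min_idx)] <-
      counts[cbind(seq_len(S), j, min_idx)] + snps$count[, j]
  }
  sync_table(snps$chrom, snps$pos, snps$major, counts, pools = snps$pools)
}
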