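#' Match two region sets by bp overlap
#'
#' Regions from two statistics on the same chromosome set are grouped into
#' overlap components (two regions share a component if their bp intervals
#' overlap, directly or through a chain).  The discordance is the fraction
#' of components supported by exactly one statistic.
#'
#' @param regions_a,regions_b Region data.frames ([call_regions()] layout),
#'   optionally with a `genome` column separating replicates.
#' @return List with `n_components`, `n_discordant`, `discordance`
#'   (`NA` when both sets are empty).
#' @export
region_discordance <- function(regions_a, regions_b) {
  tag <- function(df, lab) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df$stat <- lab
    if (is.null(df$genome)) df$genome <- 1L
    df[, c("genome", "chrom", "start_bp", "end_bp", "stat")]
  }
  all <- rbind(tag(regions_a, "a"), tag(regions_b, "b"))
  if (is.null(all) || !nrow(all))
    return(list(n_components = 0L, n_discordant = 0L, discordance = NA_real_))
  all <- all[order(all$genome, all$chrom, all$start_bp, all$end_bp), ]
  key <- paste(all$genome, all$chrom)
  n_comp <- 0L
  n_disc <- 0L
  for (k in unique(key)) {
    sub <- all[key == k, ]
    comp_end <- -Inf
    stats_seen <- character(0)
    flush <- function() {
      if (length(stats_seen)) {
        n_comp <<- n_comp + 1L
        if (length(unique(stats_seen)) == 1L) n_disc <<- n_disc + 1L
      }
    }
    for (i in seq_len(nrow(sub))) {
      if (sub$start_bp[i] > comp_end) {
        flush()
        stats_seen <- character(0)
        comp_end <- -Inf
      }
      stats_seen <- c(stats_seen, sub$stat[i])
      comp_end <- max(comp_end, sub$end_bp[i])
    }
    flush()
  }
  list(n_components = n_comp, n_discordant = n_disc,
       discordance = if (n_comp) n_disc / n_comp else NA_real_)
}

#' False-positive-rate experiment on neutral pseudo-genomes
#'
#' Simulates `n_genomes` strictly neutral pseudo-genomes under `config`,
#' runs the FLK and LK tests with an outgroup-rooted kinship matrix, applies
#' the Lindley local score (genome-wide `xi` per statistic, per-chromosome
#' Monte-Carlo thresholds at `alpha`), and summarizes: the mean number of
#' significant regions per genome, the per-chromosome false-positive rate
#' (`regions / (genomes x chromosomes)`), and the fraction of region overlap
#' components significant under exactly one statistic.  Window
#' Weir-Cockerham FST summaries of the same data are reported alongside.
#'
#' @param config A [sim_config()].
#' @param n_genomes Number of pseudo-genome replicates.
#' @param alpha Chromosome-wide error rate (default 0.05).
#' @param xi_quantile Quantile level for [choose_xi()] (default 0.85).
#' @param B Threshold resamples per chromosome.
#' @param seed Master seed; every replicate derives deterministic sub-seeds
#'   from it.
#' @param outgroup Pool used to root the kinship tree (default the last
#'   pool; the demes are exchangeable under neutrality).
#' @param window Window size for the FST summaries.
#' @return An object of class `fpr_report`.
#' @export
fpr_experiment <- function(config, n_genomes, alpha = 0.05,
                           xi_quantile = 0.85, B = 200L, seed = 1L,
                           outgroup = NULL, window = 1e5) {
  validate_sim_config(config)
  stopifnot(n_genomes >= 1L)
  set.seed(as.integer(seed))
  sub <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_genomes),
                ncol = 3L)
  flk_regions <- vector("list", n_genomes)
  lk_regions <- vector("list", n_genomes)
  xi_flk <- xi_lk <- numeric(n_genomes)
  pair_means <- NULL
  n_snps_total <- 0L
  for (g in seq_len(n_genomes)) {
    dat <- simulate_pseudo_genome(config, seed = sub[g, 1L])
    snps <- filter_snps(dat$sync, filter_params(
      maf_min = config$maf_min, depth_min = config$depth_min,
      depth_max = config$depth_max))
    n_snps_total <- n_snps_total + n_snps(snps)
    if (is.null(outgroup)) outgroup <- snps$pools[length(snps$pools)]
    kin <- build_kinship(snps, outgroup = outgroup)
    flk <- flk_test(snps, kin)
    lk <- lk_test(snps)

    set.seed(sub[g, 2L])
    scan_flk <- local_score_scan(flk, "p_flk", xi_quantile, alpha, B)
    set.seed(sub[g, 3L])
    scan_lk <- local_score_scan(lk, "p_lk", xi_quantile, alpha, B)
    xi_flk[g] <- scan_flk$xi
    xi_lk[g] <- scan_lk$xi
    if (nrow(scan_flk$regions)) scan_flk$regions$genome <- g
    if (nrow(scan_lk$regions)) scan_lk$regions$genome <- g
    flk_regions[[g]] <- scan_flk$regions
    lk_regions[[g]] <- scan_lk$regions

    wfst <- fst_windows(snps, window = window, method = "wc")
    cols <- grep("^fst_", names(wfst), value = TRUE)
    cols <- setdiff(cols, "fst_all")
    gm <- vapply(cols, function(cl) mean(wfst[[cl]], na.rm = TRUE), 1)
    pair_means <- rbind(pair_means, gm)
  }
  flk_all <- do.call(rbind, flk_regions)
  lk_all <- do.call(rbind, lk_regions)
  n_chr_total <- n_genomes * config$n_chrom
  disc <- region_discordance(flk_all, lk_all)
  report <- list(
    n_genomes = n_genomes, n_chrom = config$n_chrom,
    n_snps_mean = n_snps_total / n_genomes,
    flk = list(n_regions = nrow0(flk_all),
               mean_regions_per_genome = nrow0(flk_all) / n_genomes,
               fpr = nrow0(flk_all) / n_chr_total,
               xi = xi_flk, regions = flk_all),
    lk = list(n_regions = nrow0(lk_all),
              mean_regions_per_genome = nrow0(lk_all) / n_genomes,
              fpr = nrow0(lk_all) / n_chr_total,
              xi = xi_lk, regions = lk_all),
    discordance = disc,
    window_fst = list(pair_means = colMeans(pair_means),
                      mean_pairwise = mean(colMeans(pair_means)))
  )
  class(report) <- "fpr_report"
  report
}

nrow0 <- function(df) if (is.null(df)) 0L else nrow(df)

#' @export
print.fpr_report <- function(x, ...) {
  cat(sprintf("fpr_report: %d pseudo-genomes x %d chromosomes\n",
              x$n_genomes, x$n_chrom))
  cat(sprintf("  mean SNPs per genome: %.0f\n", x$n_snps_mean))
  cat(sprintf("  FLK: %.2f regions/genome, per-chromosome FPR %.1f%%\n",
              x$flk$mean_regions_per_genome, 100 * x$flk$fpr))
  cat(sprintf("  LK : %.2f regions/genome, per-chromosome FPR %.1f%%\n",
              x$lk$mean_regions_per_genome, 100 * x$lk$fpr))
  cat(sprintf("  discordance (exactly-one-statistic components): %.1f%%\n",
              100 * x$discordance$discordance))
  cat(sprintf("  mean pairwise window FST: %.3f\n",
              x$window_fst$mean_pairwise))
  invisible(x)
}

#' Exact binomial excess test
#'
#' One-sided (greater) exact binomial tail `P(X >= k | n, p)` by direct
#' summation of the probability mass, testing whether `k` observed
#' significant chromosomes (or regions) exceed the false-positive rate `p`
#' estimated from neutral simulations.
#'
#' @param k_observed Observed count (integer, `0 <= k <= n`).
#' @param n_chrom Number of trials (chromosomes).
#' @param p_rate Null rate in `[0, 1]`.
#' @return The one-sided p-value.
#' @export
binomial_excess_test <- function(k_observed, n_chrom, p_rate) {
  stopifnot(p_rate >= 0, p_rate <= 1,
            k_observed == round(k_observed), n_chrom == round(n_chrom),
            k_observed >= 0)
  if (k_observed > n_chrom) stop("k_observed cannot exceed n_chrom")
  if (k_observed == 0) return(1)
  min(sum(stats::dbinom(seq.int(k_observed, n_chrom), n_chrom, p_rate)), 1)
}
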