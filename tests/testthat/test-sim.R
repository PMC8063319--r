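# Monte-Carlo checks of the forward simulator against diffusion expectations.

test_that("with no post-split drift the demes are undifferentiated", {
  cfg <- sim_config(n_anc = 80L, n_deme = 80L, t_burn = 150L, t_split = 0L,
                    chrom_len = 1e6, mu = 4e-6, rec = 3e-7)
  tp <- simulate_history(cfg, chrom_seed = 101)
  expect_gt(length(tp$positions), 500)
  wf <- truth_window_fst(tp, window = 1e5)
  expect_lt(abs(mean(wf$fst_true, na.rm = TRUE)), 0.03)
})

test_that("equilibrium heterozygosity matches the 4 N mu expectation", {
  # 2N = 100 copies, 8 generations of burn-in per coalescent unit
  theta <- 4 * 50 * 1e-6
  cfg <- sim_config(n_anc = 50L, n_deme = 50L, t_burn = 800L, t_split = 0L,
                    n_demes = 1L, chrom_len = 2e6, mu = 1e-6, rec = 1.5e-7)
  tp <- simulate_history(cfg, chrom_seed = 55)
  p <- tp$freqs[, 1]
  het <- 2 * p * (1 - p) * tp$n_hap / (tp$n_hap - 1)
  # block the chromosome to get a linkage-aware standard error
  blocks <- tapply(het, floor(tp$positions / 1e5), sum) / 1e5
  se <- stats::sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(blocks) - theta), 3 * se)
})

test_that("identical (config, seed) pairs give byte-identical sync output", {
  cfg <- tiny_config(n_chrom = 2L)
  f1 <- withr::local_tempfile(fileext = ".sync")
  f2 <- withr::local_tempfile(fileext = ".sync")
  write_sync(simulate_pseudo_genome(cfg, seed = 123)$sync, f1)
  write_sync(simulate_pseudo_genome(cfg, seed = 123)$sync, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("pool sampling is binomial around the true frequencies", {
  cfg <- tiny_config()
  S <- 100000L
  tp <- structure(list(positions = seq_len(S),
                       freqs = matrix(c(rep(0.3, S), rep(0, 2 * S)), S, 3),
                       n_hap = 120L), class = "truth_panel")
  sync <- sample_pool(tp, cfg, seed = 9)
  depth <- attr(sync, "depth")
  # depths honour the truncation bounds
  expect_true(all(depth >= cfg$depth_min & depth <= cfg$depth_max))
  # rounded truncated-normal mean (truncation at 15 shifts it up slightly)
  k <- cfg$depth_min:cfg$depth_max
  pk <- stats::pnorm(k + 0.5, 23, 5) - stats::pnorm(k - 0.5, 23, 5)
  expect_lt(abs(mean(depth) - sum(k * pk) / sum(pk)), 0.05)
  alt_idx <- match(attr(sync, "alt"), c("A", "T", "C", "G", "N", "del"))
  # a frequency of zero yields zero alternate reads
  expect_true(all(sync$counts[cbind(seq_len(S), 2L, alt_idx)] == 0L))
  # the pooled frequency recovers the truth within 3 binomial SEs
  alt1 <- sync$counts[cbind(seq_len(S), 1L, alt_idx)]
  phat <- alt1 / depth[, 1]
  se <- stats::sd(phat) / sqrt(S)
  expect_lt(abs(mean(phat) - 0.3), 3 * se)
})

test_that("pooled frequencies regress on true frequencies with slope one", {
  cfg <- tiny_config(chrom_len = 2e6)
  tp <- simulate_history(cfg, chrom_seed = 77)
  expect_gt(length(tp$positions), 1e4)
  sync <- sample_pool(tp, cfg, seed = 78)
  alt_idx <- match(attr(sync, "alt"), c("A", "T", "C", "G", "N", "del"))
  S <- n_sites(sync)
  phat <- sync$counts[cbind(seq_len(S), 1L, alt_idx)] /
    attr(sync, "depth")[, 1]
  fit <- stats::lm(phat ~ tp$freqs[, 1])
  expect_lt(abs(unname(stats::coef(fit)[2]) - 1), 0.02)
})

test_that("allele-frequency correlation decays with distance", {
  # squared correlation of per-site frequency deviations across demes; the
  # square is essential because the derived-allele orientation of distinct
  # mutations is arbitrary.  With three demes the no-linkage baseline of
  # E[r^2] is 1/2 (two degrees of freedom), approached from above.
  cfg <- desk_config()
  tp <- simulate_history(cfg, chrom_seed = 202)
  g <- rowMeans(tp$freqs)
  keep <- g > 0.1 & g < 0.9
  dev <- tp$freqs[keep, ] - g[keep]
  nrm <- sqrt(rowSums(dev^2))
  ok <- nrm > 0.05
  devn <- dev[ok, ] / nrm[ok]
  n <- nrow(devn)
  mean_r2 <- function(offsets) {
    vals <- unlist(lapply(offsets, function(d) {
      i <- seq_len(n - d)
      rowSums(devn[i, ] * devn[i + d, ])^2
    }))
    mean(vals)
  }
  near <- mean_r2(1:4)        # ~ 0.5-2 kb separation
  mid <- mean_r2(16:64)       # ~ 10-30 kb
  far <- mean_r2(1024L + (0:3) * 512L)  # > 400 kb
  expect_gt(near, mid)
  expect_gt(mid, far)
  expect_gt(near - 0.5, 0.01)
  expect_lt(abs(far - 0.5), 0.005)
})

test_that("rescaled runs agree with the unscaled miniature design", {
  base <- sim_config(n_anc = 200L, n_deme = 200L, t_burn = 200L,
                     t_split = 500L, chrom_len = 1e6, mu = 1e-6,
                     rec = 1.5e-7, n_chrom = 4L)
  arms <- list(base, scale_config(base, 5), scale_config(base, 10))
  het <- fst <- matrix(NA_real_, 3, 4)
  for (a in 1:3) {
    for (k in 1:4) {
      tp <- simulate_history(arms[[a]], chrom_seed = 1000L * a + k)
      p <- tp$freqs
      het[a, k] <- sum(2 * p[, 1] * (1 - p[, 1])) / arms[[a]]$chrom_len
      comp <- fst_snp(matrix(tp$n_hap, nrow(p), 3), p, method = "wc")
      fst[a, k] <- sum(comp$num) / sum(comp$den)
    }
  }
  for (a in 2:3) {
    se_h <- sqrt(stats::sd(het[1, ])^2 + stats::sd(het[a, ])^2) / sqrt(4)
    expect_lt(abs(mean(het[a, ]) - mean(het[1, ])), 3 * se_h + 1e-6)
    se_f <- sqrt(stats::sd(fst[1, ])^2 + stats::sd(fst[a, ])^2) / sqrt(4)
    expect_lt(abs(mean(fst[a, ]) - mean(fst[1, ])), 3 * se_f + 0.01)
  }
})

test_that("pseudo-genomes apply the pooled MAF filter and keep the truth", {
  cfg <- tiny_config()
  pg <- simulate_pseudo_genome(cfg, seed = 31)
  expect_true(all(global_maf(pg$sync) > cfg$maf_min))
  expect_lte(pg$n_sites["maf_pass"], pg$n_sites["segregating"])
  expect_equal(length(unique(pg$sync$chrom)), cfg$n_chrom)
  # truth rows track the emitted sites one to one
  expect_equal(pg$truth$positions, pg$sync$pos)
  expect_equal(pg$truth$chrom, pg$sync$chrom)
})
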