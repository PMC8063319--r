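const_kinship <- function(c0, pools = c("pool1", "pool2", "pool3"),
                          outgroup = "pool3") {
  F <- diag(rep(c0, 3))
  dimnames(F) <- list(pools, pools)
  m <- list(pops = pools, outgroup = outgroup, D = NULL,
            branch = stats::setNames(rep(c0, 3), pools), F = F)
  class(m) <- "kinship_model"
  m
}

test_that("LK standardizes against the genome-wide mean", {
  # identical theta at every SNP -> T = n_pop - 1 everywhere
  snps <- make_snps(depth = matrix(20, 4, 3),
                    freq = rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(0, 0, 1)))
  lk <- lk_test(snps)
  expect_equal(lk$T_lk, rep(2, 4))
  expect_equal(lk$p_lk, rep(stats::pchisq(2, 2, lower.tail = FALSE), 4))

  # a SNP with theta = 2 * mean -> T = 2 (n_pop - 1), p = exp(-2) for 3 pops
  expect_equal(stats::pchisq(4, 2, lower.tail = FALSE), exp(-2))

  # negative theta clamps to zero with p = 1
  snps2 <- make_snps(depth = matrix(20, 2, 3),
                     freq = rbind(c(1, 0, 0), c(0.5, 0.5, 0.5)))
  lk2 <- lk_test(snps2)
  expect_equal(lk2$T_lk[2], 0)
  expect_equal(lk2$p_lk[2], 1)
})

test_that("FLK reproduces hand matrix arithmetic", {
  kin <- const_kinship(0.1)
  # equal frequencies: the null point, T = 0, p = 1
  snps0 <- make_snps(depth = matrix(20, 1, 3),
                     freq = rbind(c(0.4, 0.4, 0.4)))
  r0 <- flk_test(snps0, kin)
  expect_equal(r0$T_flk, 0)
  expect_equal(r0$p_flk, 1)
  expect_equal(r0$p0, 0.4)

  # F = c I and equal depths: T = sum((p - pbar)^2) / (c pbar (1 - pbar))
  p <- c(0.5, 0.5, 0.8)
  snps1 <- make_snps(depth = matrix(20, 1, 3), freq = rbind(p))
  r1 <- flk_test(snps1, kin)
  pbar <- mean(p)
  expect_equal(r1$p0, pbar)
  expect_equal(r1$T_flk, sum((p - pbar)^2) / (0.1 * pbar * (1 - pbar)))

  # SNPs at an estimated ancestral frequency of 0 or 1 are dropped
  snps2 <- make_snps(depth = matrix(20, 1, 3), freq = rbind(c(0, 0, 0)))
  r2 <- flk_test(snps2, kin)
  expect_true(is.na(r2$T_flk))

  # excluding the outgroup reduces the tested set (df = 1)
  r3 <- flk_test(snps1, kin, include_outgroup = FALSE)
  expect_equal(r3$p0, 0.5)
  expect_equal(r3$T_flk, 0)
})

test_that("T_FLK follows chi-square(2) under ideal star-topology drift", {
  # true Wright-Fisher drift as the oracle: three demes of 2N = 4000 drift
  # 40 generations from an interior ancestral frequency, giving
  # F = 1 - (1 - 1/2N)^t on a star tree; frequencies observed exactly
  set.seed(5)
  m <- 10000L
  two_n <- 4000L
  t_gen <- 40L
  p0 <- runif(m, 0.2, 0.8)
  drift <- function(p) {
    for (g in seq_len(t_gen)) p <- rbinom(m, two_n, p) / two_n
    p
  }
  freq <- cbind(drift(p0), drift(p0), drift(p0))
  c0 <- 1 - (1 - 1 / two_n)^t_gen
  snps <- make_snps(depth = matrix(two_n, m, 3), freq = freq)
  res <- flk_test(snps, const_kinship(c0))
  T <- res$T_flk[!is.na(res$T_flk)]
  ks <- suppressWarnings(stats::ks.test(T, stats::pchisq, df = 2))
  expect_gt(ks$p.value, 0.01)
  # and the p-values are uniform
  ks2 <- suppressWarnings(stats::ks.test(res$p_flk[!is.na(res$T_flk)],
                                         "punif"))
  expect_gt(ks2$p.value, 0.01)
})

test_that("FLK with equal branch lengths ranks SNPs like LK", {
  set.seed(6)
  cfg <- tiny_config()
  tp <- simulate_history(cfg, chrom_seed = 61)
  sync <- sample_pool(tp, cfg, seed = 62)
  snps <- filter_snps(sync, filter_params())
  lk <- lk_test(snps)
  flk <- flk_test(snps, const_kinship(0.2))
  ok <- !is.na(flk$T_flk) & !is.na(lk$T_lk)
  rho <- cor(flk$T_flk[ok], lk$T_lk[ok], method = "spearman")
  expect_gt(rho, 0.99)
})
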