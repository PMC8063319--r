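test_that("per-SNP estimators reproduce hand-derived cases", {
  # fixed difference, n1 = n2 = 20
  wc <- fst_snp(c(20, 20), c(1, 0), method = "wc")
  expect_equal(wc$num, 0.5)
  expect_equal(wc$den, 0.5)
  expect_equal(wc$est, 1)
  ka <- fst_snp(c(20, 20), c(1, 0), method = "karlsson")
  expect_equal(ka$num, 1)
  expect_equal(ka$den, 1)
  expect_equal(ka$est, 1)

  # identical intermediate frequencies: negative estimate -1/(nbar - 1)
  wc2 <- fst_snp(c(20, 20), c(0.5, 0.5), method = "wc")
  expect_equal(wc2$est, -1 / 19)

  # monomorphic identical site: components zero, estimate undefined
  wc3 <- fst_snp(c(20, 20), c(0, 0), method = "wc")
  expect_equal(wc3$num, 0)
  expect_equal(wc3$den, 0)
  expect_true(is.na(wc3$est))
  ka3 <- fst_snp(c(20, 20), c(0, 0), method = "karlsson")
  expect_equal(ka3$den, 0)
  expect_true(is.na(ka3$est))
})

test_that("the WC formulas match a brute-force component evaluation", {
  set.seed(7)
  for (i in 1:20) {
    r <- sample(2:5, 1)
    n <- sample(15:50, r, replace = TRUE)
    p <- round(runif(r), 3)
    got <- fst_snp(n, p, method = "wc")
    # independent evaluation, scalar arithmetic step by step
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
    expect_equal(got$num, a)
    expect_equal(got$den, a + b)
  }
  expect_error(fst_snp(c(20, 20, 20), c(0, 0.5, 1), method = "karlsson"),
               "2 pools")
  expect_error(fst_snp(c(1, 20), c(0, 1)), ">= 2")
})

test_that("window FST is a ratio of sums over the window's SNPs", {
  # one SNP: window estimate equals the SNP estimate
  snps <- make_snps(depth = rbind(c(20, 20)), freq = rbind(c(1, 0)),
                    pos = 5L)
  w <- fst_windows(snps, window = 1e5, min_snps = 1L)
  expect_equal(w$fst_pool1.pool2, 1)
  expect_equal(c(w$start, w$end), c(1L, 100000L))

  # components (0.5, 0) and (0, 0.5) pool to 0.5 / 1.0
  snps2 <- make_snps(depth = rbind(c(20, 20), c(20, 20)),
                     freq = rbind(c(1, 0), c(0.5, 0.5)),
                     pos = c(5L, 6L))
  w2 <- fst_windows(snps2, window = 1e5, min_snps = 1L)
  a2 <- fst_snp(c(20, 20), c(0.5, 0.5))
  expect_equal(w2$fst_pool1.pool2,
               (0.5 + a2$num) / (0.5 + a2$den))

  # windows tile the chromosome: window k covers [(k-1)w + 1, kw]
  snps3 <- make_snps(depth = rbind(c(20, 20), c(20, 20)),
                     freq = rbind(c(1, 0), c(1, 0)),
                     pos = c(100000L, 100001L))
  w3 <- fst_windows(snps3, window = 1e5, min_snps = 1L)
  expect_equal(w3$n_snps, c(1L, 1L))
  expect_equal(w3$start, c(1L, 100001L))

  # below min_snps the estimate is missing but the window is reported
  w4 <- fst_windows(snps3, window = 1e5, min_snps = 10L)
  expect_equal(w4$n_snps, c(1L, 1L))
  expect_true(all(is.na(w4$fst_pool1.pool2)))
})

test_that("genome summary ranks the top fraction with deterministic ties", {
  win <- data.frame(chrom = "chr1", start = c(1, 2, 3) * 1e5 - 1e5 + 1,
                    end = c(1, 2, 3) * 1e5, n_snps = 10L,
                    fst = c(0.1, 0.3, 0.5))
  gs <- genome_summary(win, "fst", top_fraction = 0.001)
  expect_equal(gs$mean_fst, 0.3)
  expect_equal(gs$k, 1L)
  expect_equal(gs$top$fst, 0.5)

  # k = round(valid * fraction): 19512 windows at 0.1% -> 20
  expect_equal(max(1L, as.integer(round(19512 * 0.001))), 20L)
  big <- data.frame(chrom = "chr1", start = seq_len(19512), end = seq_len(19512),
                    fst = runif(19512))
  gs2 <- genome_summary(big, "fst", top_fraction = 0.001)
  expect_equal(gs2$k, 20L)
  expect_equal(nrow(gs2$top), 20L)
  expect_equal(gs2$top$fst, sort(big$fst, decreasing = TRUE)[1:20])
})

test_that("WC and Karlsson window estimates agree in rank on drifted data", {
  set.seed(11)
  cfg <- tiny_config()
  tp <- simulate_history(cfg, chrom_seed = 21)
  sync <- sample_pool(tp, cfg, seed = 22)
  snps <- filter_snps(sync[global_maf(sync) > 0.05], filter_params())
  two <- make_snps(snps$depth[, 1:2], snps$freq[, 1:2], pos = snps$pos)
  w_wc <- fst_windows(two, window = 5e4, method = "wc", min_snps = 5L)
  w_ka <- fst_windows(two, window = 5e4, method = "karlsson", min_snps = 5L)
  ok <- !is.na(w_wc$fst_pool1.pool2) & !is.na(w_ka$fst_pool1.pool2)
  expect_gt(sum(ok), 5)
  rho <- cor(w_wc$fst_pool1.pool2[ok], w_ka$fst_pool1.pool2[ok],
             method = "spearman")
  expect_gt(rho, 0.95)
})
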