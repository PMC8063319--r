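test_that("enrichment p-values equal exhaustive enumeration", {
  # N = 10, B = 4 term genes, target of 3 all carrying the term
  universe <- paste0("g", 1:10)
  terms <- data.frame(gene = universe[1:4], term = "T1")
  p <- hypergeom_enrich(universe[1:3], universe, terms)$p
  expect_equal(p, 4 / 120)
  expect_equal(p, enum_hyper_tail(10, 4, 3, 3))

  # random small universes against the enumeration oracle
  set.seed(14)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    B <- sample(1:N, 1)
    n <- sample(1:(N - 1), 1)
    genes <- paste0("g", seq_len(N))
    terms <- data.frame(gene = genes[seq_len(B)], term = "T1")
    target <- sample(genes, n)
    b <- sum(target %in% genes[seq_len(B)])
    got <- hypergeom_enrich(target, genes, terms)
    expect_equal(got$p, enum_hyper_tail(N, B, n, b))
    expect_equal(got$b, b)
  }
})

test_that("terms absent from the target are never significant", {
  genes <- paste0("g", 1:20)
  terms <- data.frame(gene = genes[11:20], term = "T_none")
  row <- hypergeom_enrich(genes[1:5], genes, terms)
  expect_equal(row$p, 1)
  expect_false(row$significant)
})

test_that("include and exclude modes coincide for a disjoint background", {
  target <- paste0("t", 1:4)
  background <- paste0("b", 1:8)
  terms <- data.frame(gene = c(target[1:2], background[1:3]), term = "T1")
  exc <- hypergeom_enrich(target, background, terms, mode = "exclude")
  expect_warning(
    inc <- hypergeom_enrich(target, background, terms, mode = "include"),
    "added")
  expect_equal(inc$p, exc$p)
  expect_equal(inc$N, exc$N)
})

test_that("adding a term-carrying target gene never increases the p-value", {
  set.seed(15)
  genes <- paste0("g", 1:30)
  terms <- data.frame(gene = genes[1:10], term = "T1")
  target <- c(genes[1:3], genes[25:28])
  p_before <- hypergeom_enrich(target, genes, terms)$p
  p_after <- hypergeom_enrich(c(target, genes[4]), genes, terms)$p
  expect_lte(p_after, p_before)
})

test_that("nested FST bins give nested targets and non-increasing b", {
  fix <- toy_enrichment_fixture(withr::local_tempdir(), seed = 4)
  ann <- load_annotations(fix$gff, fix$termmap)
  t_low <- genes_in_windows(fix$windows, ann$genes, "fst_sim", 0.05)
  t_high <- genes_in_windows(fix$windows, ann$genes, "fst_sim", 0.5)
  expect_true(all(t_high %in% t_low))
  e_low <- hypergeom_enrich(t_low, ann$genes$id, ann$terms)
  e_high <- hypergeom_enrich(t_high, ann$genes$id, ann$terms)
  shared <- intersect(e_low$term, e_high$term)
  expect_true(all(e_high$b[match(shared, e_high$term)] <=
                    e_low$b[match(shared, e_low$term)]))
})

test_that("the planted term in the toy fixture is detected end to end", {
  fix <- toy_enrichment_fixture(withr::local_tempdir(), seed = 16)
  ann <- load_annotations(fix$gff, fix$termmap)
  expect_equal(nrow(ann$genes), 40L)
  target <- genes_in_windows(fix$windows, ann$genes, "fst_sim", 0.5)
  expect_gt(length(target), 0L)
  res <- hypergeom_enrich(target, ann$genes$id, ann$terms)
  top <- res[1, ]
  expect_equal(top$term, "PLANTED")
  expect_true(top$significant)
  expect_true(all(res$p[-1] > 0.001))
})

test_that("annotation loading preserves coordinates and flags unknowns", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "three.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=gA",
               "chr1\tsrc\tgene\t2000\t2500\t.\t-\t.\tID=gB",
               "chr2\tsrc\tgene\t1\t50\t.\t+\t.\tID=gC"), gff)
  tm <- file.path(dir, "terms.tsv")
  writeLines(c("gene\tterm", "gA\tT1", "gB\tT1", "missing\tT2"), tm)
  expect_warning(ann <- load_annotations(gff, tm), "1 term-map row")
  expect_equal(ann$genes$id, c("gA", "gB", "gC"))
  expect_equal(ann$genes$start, c(100L, 2000L, 1L))
  expect_equal(ann$genes$end, c(900L, 2500L, 50L))
  expect_equal(nrow(ann$terms), 2L)

  # gene overlap is inclusive on both ends
  win <- data.frame(chrom = "chr1", start = 901L, end = 1000L, fst = 0.9)
  expect_equal(genes_in_windows(win, ann$genes, "fst", 0.5), character(0))
  win2 <- data.frame(chrom = "chr1", start = 900L, end = 1000L, fst = 0.9)
  expect_equal(genes_in_windows(win2, ann$genes, "fst", 0.5), "gA")
  # a gene straddling two qualifying windows is counted once
  win3 <- data.frame(chrom = "chr1", start = c(1L, 501L), end = c(500L, 1000L),
                     fst = 0.9)
  expect_equal(genes_in_windows(win3, ann$genes, "fst", 0.5), "gA")
})
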