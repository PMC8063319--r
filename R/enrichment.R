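#' Load gene annotations and a gene-to-term map
#'
#' Reads gene records from a GFF3 file (features of type `gene`; 1-based
#' inclusive coordinates preserved) and a flat two-column tab-separated
#' gene-to-term map (columns `gene`, `term`, optional `description`).  Term
#' rows naming genes absent from the GFF are skipped with a warning giving
#' the count.
#'
#' @param gff_path Path to a GFF3 file.
#' @param termmap_path Path to the gene-to-term TSV (header required).
#' @return List with `genes` (data.frame `id`, `chrom`, `start`, `end`,
#'   `strand`) and `terms` (data.frame `gene`, `term`, and `description` if
#'   present).
#' @export
load_annotations <- function(gff_path, termmap_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("every gene needs an ID attribute")
  genes <- data.frame(
    id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  terms <- utils::read.delim(termmap_path, header = TRUE,
                             stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(terms)))
    stop("term map needs columns 'gene' and 'term'")
  unknown <- !(terms$gene %in% genes$id)
  if (any(unknown)) {
    warning(sum(unknown), " term-map row(s) name unknown genes; skipped")
    terms <- terms[!unknown, , drop = FALSE]
  }
  list(genes = genes, terms = terms)
}

#' Target genes overlapping high-FST windows
#'
#' A gene is a target when any bp of its span overlaps any window whose FST
#' exceeds `min_fst` (1-based inclusive coordinates on both sides).  Each
#' gene is counted once regardless of how many windows it touches.
#'
#' @param windows Window data.frame from [fst_windows()].
#' @param genes Gene data.frame from [load_annotations()].
#' @param fst_col FST column defining the windows' rank.
#' @param min_fst Strict lower FST bound for a qualifying window.
#' @return Character vector of unique target gene ids.
#' @export
genes_in_windows <- function(windows, genes, fst_col, min_fst) {
  stopifnot(fst_col %in% names(windows))
  qual <- windows[!is.na(windows[[fst_col]]) & windows[[fst_col]] > min_fst,
                  , drop = FALSE]
  if (!nrow(qual) || !nrow(genes)) return(character(0))
  wgr <- GenomicRanges::GRanges(qual$chrom,
                                IRanges::IRanges(qual$start, qual$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  hit <- GenomicRanges::findOverlaps(ggr, wgr)
  unique(genes$id[unique(S4Vectors::queryHits(hit))])
}

#' Exact hypergeometric term enrichment, target vs background
#'
#' For every term, tests whether the target gene set contains more genes
#' annotated with the term than expected from `n` draws out of the gene
#' universe.  The universe always contains the target; `mode` states whether
#' the supplied background already includes the target genes
#' (`"include"`: universe = background) or was built without them
#' (`"exclude"`: universe = background plus the target).  With a background
#' disjoint from the target the two modes coincide.  The upper-tail p-value
#' is `P(X >= b)` for `X ~ Hypergeometric(N, B, n)`; Benjamini-Hochberg
#' q-values are reported, and the significance flag uses the raw
#' `p <= p_cut` gate (default 0.001).
#'
#' @param target Character vector of target gene ids.
#' @param background Character vector of background gene ids.
#' @param terms Gene-to-term data.frame (`gene`, `term`, optional
#'   `description`).
#' @param mode `"include"` or `"exclude"` (see above).
#' @param p_cut Raw p-value significance gate.
#' @return data.frame with one row per term present in the universe: `term`,
#'   `description` (if available), `b`, `n`, `B`, `N`, `ratio`
#'   (`(b/n)/(B/N)`), `p`, `q`, `significant`; sorted by `p`.
#' @export
hypergeom_enrich <- function(target, background, terms,
                             mode = c("include", "exclude"),
                             p_cut = 0.001) {
  mode <- match.arg(mode)
  target <- unique(target)
  background <- unique(background)
  if (!length(background)) stop("background must be nonempty")
  universe <- if (mode == "include") {
    miss <- setdiff(target, background)
    if (length(miss))
      warning(length(miss), " target gene(s) absent from the background ",
              "were added to the universe")
    union(background, target)
  } else {
    union(setdiff(background, target), target)
  }
  terms <- terms[terms$gene %in% universe, , drop = FALSE]
  if (!nrow(terms))
    return(data.frame(term = character(0), b = integer(0), n = integer(0),
                      B = integer(0), N = integer(0), ratio = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  N <- length(universe)
  n <- length(target)
  by_term <- split(terms$gene, terms$term)
  term_ids <- names(by_term)
  B <- vapply(by_term, function(g) length(unique(g)), 1L)
  b <- vapply(by_term, function(g) length(intersect(unique(g), target)), 1L)
  p <- stats::phyper(b - 1L, B, N - B, n, lower.tail = FALSE)
  out <- data.frame(term = term_ids, b = b, n = n, B = B, N = N,
                    ratio = (b / n) / (B / N),
                    p = pmin(p, 1), q = stats::p.adjust(pmin(p, 1), "BH"),
                    significant = pmin(p, 1) <= p_cut,
                    row.names = NULL)
  if ("description" %in% names(terms)) {
    d <- terms$description[match(out$term, terms$term)]
    out <- cbind(out[, "term", drop = FALSE], description = d,
                 out[, setdiff(names(out), "term")])
  }
  out[order(out$p, out$term), , drop = FALSE]
}

#' Toy enrichment fixture with a planted signal
#'
#' Builds a miniature genome for testing the enrichment path end to end: a
#' GFF3 of evenly spaced genes on two chromosomes, a term map in which one
#' term ("PLANTED") is concentrated in the genes of a chosen high-FST
#' region, and a window table whose FST exceeds the bin threshold exactly
#' over that region.
#'
#' @param dir Directory in which `genes.gff3` and `gene2term.tsv` are
#'   written.
#' @param n_genes Genes per chromosome.
#' @param seed Seed for the background term assignment.
#' @return List with `gff`, `termmap` (paths), `windows` (data.frame with
#'   `fst_sim` column), and `planted_term`.
#' @export
toy_enrichment_fixture <- function(dir = tempdir(), n_genes = 20L, seed = 1L) {
  set.seed(seed)
  gene_len <- 5000L
  gap <- 45000L
  rows <- list()
  genes <- list()
  for (ch in c("chr1", "chr2")) {
    start <- (seq_len(n_genes) - 1L) * (gene_len + gap) + 1000L
    id <- sprintf("%s_g%02d", ch, seq_len(n_genes))
    genes[[ch]] <- data.frame(id = id, chrom = ch, start = start,
                              end = start + gene_len - 1L)
    rows[[ch]] <- sprintf(
      "%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s", ch, start,
      start + gene_len - 1L, id)
  }
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3", unlist(rows)), gff)
  gdf <- do.call(rbind, genes)
  # windows of 100 kb; chr1 windows 1-3 are the high-FST region
  win <- expand.grid(start = seq(1L, max(gdf$end), by = 100000L),
                     chrom = c("chr1", "chr2"))[, c(2, 1)]
  win$end <- win$start + 99999L
  win$fst_sim <- 0.1
  win$fst_sim[win$chrom == "chr1" & win$start <= 200001L] <- 0.6
  hot <- genes_in_windows(win, gdf, "fst_sim", 0.5)
  terms <- data.frame(gene = gdf$id,
                      term = sample(paste0("T", 1:4), nrow(gdf),
                                    replace = TRUE))
  planted <- data.frame(gene = hot, term = "PLANTED")
  tm <- rbind(terms, planted)
  tm$description <- ifelse(tm$term == "PLANTED", "planted signal",
                           "background term")
  termmap <- file.path(dir, "gene2term.tsv")
  utils::write.table(tm, termmap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(gff = gff, termmap = termmap, windows = win, genes = gdf,
       planted_term = "PLANTED")
}
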