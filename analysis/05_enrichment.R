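#!/usr/bin/env Rscript

# Gene-set enrichment of genes overlapping high-FST windows, demonstrated on
# the synthetic toy annotation (a planted term concentrated in the high-FST
# region).  With real data, point gff/termmap at the genome annotation and
# the windows table at a real scan.

suppressPackageStartupMessages(library(poolscan))

out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fix <- toy_enrichment_fixture(out_dir, seed = 5L)
ann <- load_annotations(fix$gff, fix$termmap)
message(sprintf("toy annotation: %d genes, %d term assignments",
                nrow(ann$genes), nrow(ann$terms)))

target <- genes_in_windows(fix$windows, ann$genes, "fst_sim", min_fst = 0.5)
message(sprintf("%d genes overlap windows with FST > 0.5", length(target)))

res <- hypergeom_enrich(target, ann$genes$id, ann$terms, mode = "include",
                        p_cut = 0.001)
print(head(res, 5))
write.table(res, file.path(out_dir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", out_dir, "/enrichment.tsv")
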