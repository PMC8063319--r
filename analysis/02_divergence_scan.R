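#!/usr/bin/env Rscript

# Window-based divergence scan of the simulated pseudo-genome: SNP filtering,
# 100-kb Weir-Cockerham and Karlsson FST, pi and dxy per window, per-bin
# diversity summaries and the top-0.1% window table.

suppressPackageStartupMessages(library(poolscan))

out_dir <- "results/scan"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sync <- read_sync("results/sim/neutral.sync")
snps <- filter_snps(sync, filter_params())
message(sprintf("%d sites -> %d SNPs after retention rules", n_sites(sync),
                n_snps(snps)))

wc <- fst_windows(snps, window = 1e5, method = "wc")
ka <- fst_windows(snps, window = 1e5, method = "karlsson")
div <- diversity_windows(snps, window = 1e5)
windows <- merge(merge(wc, ka, by = c("chrom", "start", "end", "n_snps"),
                       suffixes = c("_wc", "_ka")),
                 div[, setdiff(names(div), "n_snps")],
                 by = c("chrom", "start", "end"))
windows <- windows[order(windows$chrom, windows$start), ]
write.table(windows, file.path(out_dir, "windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gs <- genome_summary(windows, "fst_pool1.pool2_wc", top_fraction = 0.001)
message(sprintf("pool1-pool2 genome-wide mean window FST = %.3f over %d windows",
                gs$mean_fst, gs$n_valid))
write.table(gs$top, file.path(out_dir, "top_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

bins <- bin_summary(windows, "fst_pool1.pool2_wc",
                    c("pi_pool1", "pi_pool2", "dxy_pool1.pool2"))
print(bins)
write.table(bins, file.path(out_dir, "bin_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", out_dir, "/{windows,top_windows,bin_summary}.tsv")
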