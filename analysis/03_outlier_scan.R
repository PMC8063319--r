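#!/usr/bin/env Rscript

# FLK and LK single-SNP tests with an outgroup-rooted kinship matrix,
# followed by the Lindley local score with chromosome-wide Monte-Carlo
# thresholds (alpha = 0.05, xi = the 85% quantile of -log10 p).

suppressPackageStartupMessages(library(poolscan))

out_dir <- "results/scan"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sync <- read_sync("results/sim/neutral.sync")
snps <- filter_snps(sync, filter_params())
kin <- build_kinship(snps, outgroup = "pool3")
print(kin)

flk <- flk_test(snps, kin)
lk <- lk_test(snps)
per_snp <- cbind(flk[, c("chrom", "pos", "T_flk", "p_flk", "p0")],
                 lk[, c("T_lk", "p_lk")])
write.table(per_snp, file.path(out_dir, "flk_lk_per_snp.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

set.seed(2L)
scan_flk <- local_score_scan(flk, "p_flk", xi_quantile = 0.85, alpha = 0.05,
                             B = 200L)
set.seed(3L)
scan_lk <- local_score_scan(lk, "p_lk", xi_quantile = 0.85, alpha = 0.05,
                            B = 200L)
message(sprintf("xi: FLK %.2f, LK %.2f", scan_flk$xi, scan_lk$xi))
message(sprintf("significant regions: FLK %d, LK %d on a strictly neutral genome",
                nrow(scan_flk$regions), nrow(scan_lk$regions)))

regions <- rbind(cbind(statistic = "flk", scan_flk$regions),
                 cbind(statistic = "lk", scan_lk$regions))
write.table(regions, file.path(out_dir, "local_score_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out_dir, "/{flk_lk_per_snp,local_score_regions}.tsv")
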