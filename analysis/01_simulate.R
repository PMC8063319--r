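#!/usr/bin/env Rscript

# Simulate one desk-scale neutral pseudo-genome (three isolated demes,
# pool-sequenced at ~23x) and write it to disk in sync format together with
# the per-deme truth frequencies.  Downstream scripts start from these files.

suppressPackageStartupMessages(library(poolscan))

seed <- 1L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- desk_config()  # lambda = 10 rescaling of the full design, 2 Mb chroms
print(cfg)

pg <- simulate_pseudo_genome(cfg, seed = seed)
message(sprintf("segregating sites: %d; after pooled MAF > %.2f: %d",
                pg$n_sites["segregating"], cfg$maf_min,
                pg$n_sites["maf_pass"]))

write_sync(pg$sync, file.path(out_dir, "neutral.sync"))
truth <- data.frame(chrom = pg$truth$chrom, pos = pg$truth$positions,
                    pg$truth$freqs)
write.table(truth, file.path(out_dir, "neutral.truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(unclass(cfg), file.path(out_dir, "neutral.config.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", out_dir, "/neutral.{sync,truth.tsv,config.json}")
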