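#!/usr/bin/env Rscript
# Stage 2: filter the duplicate catalog and produce the count accounting.
#
# Applies the Ks retention window (0.05 <= Ks <= 5), assigns pair-level PPI
# status (reference by network degree, other species by family projection),
# and writes the species-by-mode-by-PPI count table.

suppressPackageStartupMessages(library(dupdiverge))
suppressPackageStartupMessages(library(optparse))
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results"))))

dataset <- read_dataset(file.path(opts$outdir, "data"))
res <- assemble_records(dataset)

win <- apply_ks_window(dataset$catalog)
cat(sprintf("Ks window: kept %d pairs, discarded %d low / %d high\n",
            nrow(win), attr(win, "discarded_low"), attr(win, "discarded_high")))

utils::write.table(res$counts_summary,
                   file.path(opts$outdir, "counts_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(res$counts_summary)

# younger-duplicate subsets per mode, for reference
for (sub in c("ks<5", "ks<1")) {
  parts <- partition_pairs(res$records, by = "mode", ks_subset = sub)
  cat(sprintf("%s: tandem %d, block %d\n", sub,
              nrow(parts$tandem), nrow(parts$block)))
}
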