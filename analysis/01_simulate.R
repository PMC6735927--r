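#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-species study dataset.
#
# One reference species (ath) carries the PPI network; two further species
# (sly, zma) receive PPI status only through gene-family projection. Ground
# truth (latent curves, per-pair divergence values) is written alongside the
# data so later stages can be audited.

suppressPackageStartupMessages(library(dupdiverge))
suppressPackageStartupMessages(library(optparse))
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "results"))))

cfg <- generator_config(seed = opts$seed)
dataset <- generate_dataset(cfg)
print(dataset)

data_dir <- file.path(opts$outdir, "data")
manifest <- write_dataset(dataset, data_dir)
manifest$md5 <- unname(tools::md5sum(file.path(data_dir, manifest$file)))
utils::write.table(manifest, file.path(opts$outdir, "manifest_simulate.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(manifest), "files to", data_dir, "\n")
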