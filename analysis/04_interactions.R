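#!/usr/bin/env Rscript
# Stage 4: interaction network, ID statistic, cutoff sweep, projection.
#
# Builds the deduplicated reference-species PPI network, computes ID with
# the 4/1 eligibility cutoffs, sweeps the high-degree cutoff 1..14, projects
# PPI status onto the other species via gene families, and bands eligible
# pairs by partner retention.

suppressPackageStartupMessages(library(dupdiverge))
suppressPackageStartupMessages(library(optparse))
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results"))))

dataset <- read_dataset(file.path(opts$outdir, "data"))
catalog <- apply_ks_window(dataset$catalog)
ref <- dataset$ground_truth$reference_species

network <- merge_networks(dataset$ppi, normalize_ids = FALSE)
cat(sprintf("network: %d proteins, %d interactions\n",
            attr(network, "n_nodes"), attr(network, "n_edges")))

ref_cat <- catalog[catalog$species == ref, ]
ids <- id_table(ref_cat, network)
utils::write.table(ids, file.path(opts$outdir, "id.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d reference pairs eligible at cutoffs 4/1\n",
            sum(ids$eligible), nrow(ids)))

sweep <- sweep_id_cutoffs(ref_cat, network)
utils::write.table(sweep, file.path(opts$outdir, "id_cutoff_sweep.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

proj <- project_ppi_status(dataset$families, network, ref)
utils::write.table(proj, file.path(opts$outdir, "ppi_status.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

elig <- ids[ids$eligible & ids$mode %in% c("tandem", "block"), ]
elig$partition <- elig$mode
banding <- shared_partner_banding(elig)
print(banding$bands)
if (!is.null(banding$tests)) print(banding$tests)
utils::write.table(banding$bands, file.path(opts$outdir, "id_banding.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
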