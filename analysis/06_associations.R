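#!/usr/bin/env Rscript
# Stage 6: correlation panels, representation tests, GO enrichment.
#
# Pearson/Spearman panels among Ks, SD, ED (and ID for the reference
# species) per mode and PPI partition and Ks subset; Fisher representation
# test of PPIs across modes; hypergeometric GO-slim enrichment of block and
# tandem duplicate genes against all duplicate genes.

suppressPackageStartupMessages(library(dupdiverge))
suppressPackageStartupMessages(library(optparse))
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results"))))

dataset <- read_dataset(file.path(opts$outdir, "data"))
res <- assemble_records(dataset)
ref <- dataset$ground_truth$reference_species

panels <- list()
for (sp in unique(res$records$species)) {
  recs <- res$records[res$records$species == sp, ]
  vars <- if (sp == ref) c("ks", "sd", "ed", "id") else c("ks", "sd", "ed")
  for (pc in c("mode", "ppi_status"))
    panels[[length(panels) + 1L]] <-
      cbind(species = sp, partition_by = pc,
            correlation_panel(recs, vars, partition_col = pc))
}
correlations <- do.call(rbind, panels)
utils::write.table(correlations, file.path(opts$outdir, "correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("correlation panel: %d cells (%d computed)\n",
            nrow(correlations), sum(correlations$computed)))

# are PPIs over-represented among block duplicates?
rep_rows <- list()
for (sp in unique(res$records$species)) {
  recs <- res$records[res$records$species == sp, ]
  counts <- rbind(
    tandem = c(with = sum(recs$mode == "tandem" & recs$ppi_status == "with"),
               without = sum(recs$mode == "tandem" & recs$ppi_status == "without")),
    block = c(with = sum(recs$mode == "block" & recs$ppi_status == "with"),
              without = sum(recs$mode == "block" & recs$ppi_status == "without")))
  rep_rows[[sp]] <- cbind(species = sp, representation_test(counts))
}
representation <- do.call(rbind, rep_rows)
utils::write.table(representation, file.path(opts$outdir, "representation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(representation)

# GO-slim enrichment, reference species genes, background = all duplicates
recs <- res$records[res$records$species == ref, ]
background <- unique(c(recs$gene_a, recs$gene_b))
enr <- list()
for (m in c("tandem", "block")) {
  genes <- unique(c(recs$gene_a[recs$mode == m], recs$gene_b[recs$mode == m]))
  e <- go_enrichment(genes, background, dataset$go)
  enr[[m]] <- cbind(gene_set = m, e)
}
enrichment <- do.call(rbind, enr)
utils::write.table(enrichment, file.path(opts$outdir, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- enrichment[enrichment$q_value < 0.05, ]
cat(sprintf("%d significant (q < 0.05) term/set combinations\n", nrow(sig)))
print(sig[, c("gene_set", "term_id", "k", "K", "direction", "q_value")])
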