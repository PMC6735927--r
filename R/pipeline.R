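# End-to-end assembly: from a dataset's raw tables to the per-pair record
# table that the saturation fits, correlation panels and enrichment consume.

#' Assemble per-pair divergence records from a dataset
#'
#' Runs the standard chain on a (synthetic or real) dataset: Ks-window
#' filter on the catalog; low-expression filter, detection profiles and ED
#' per species; PPI network build, gene- and pair-level PPI status
#' (reference species by network degree, other species by family
#' projection); ID for reference-species pairs. Unclassified pairs are
#' discarded from the analysis set.
#'
#' @param dataset list with elements `catalog`, `counts` (named list of
#'   matrices), `ppi` (edge data frame), `families` — e.g. a
#'   [generate_dataset()] result or [read_dataset()] output.
#' @param ks_min,ks_max Ks retention window (defaults 0.05 and 5).
#' @param detection_threshold detection threshold for expression profiles.
#' @param low_expr_multiplier low-expression filter multiple (default 2).
#' @param min_deg_high,min_deg_low ID eligibility cutoffs (defaults 4, 1).
#' @param drop_unclassified discard pairs labeled unclassified (default
#'   TRUE, the standard analysis choice).
#' @return list with `records` (species, gene_a, gene_b, mode, ppi_status,
#'   ks, sd, ed, id — `id` only for eligible reference pairs), `network`
#'   (the merged igraph), `id_full` (all ID records incl. ineligible),
#'   `ed_exclusions`, and `counts_summary` (the species-by-mode-by-PPI
#'   accounting table over the full windowed catalog).
#' @export
assemble_records <- function(dataset,
                             ks_min = 0.05, ks_max = 5.0,
                             detection_threshold = 0,
                             low_expr_multiplier = 2,
                             min_deg_high = 4L, min_deg_low = 1L,
                             drop_unclassified = TRUE) {
  catalog <- apply_ks_window(dataset$catalog, ks_min, ks_max)

  network <- merge_networks(dataset$ppi, normalize_ids = FALSE)
  ref <- if (!is.null(dataset$ground_truth$reference_species))
    dataset$ground_truth$reference_species else dataset$catalog$species[1]

  # gene-level PPI status: reference by degree, other species by projection
  deg <- if (igraph::vcount(network) > 0) igraph::degree(network) else numeric()
  ref_genes <- unique(dataset$families$gene_id[dataset$families$species == ref])
  gene_status <- data.frame(
    gene_id = ref_genes,
    ppi_status = ifelse(ref_genes %in% names(deg)[deg >= 1], "with", "without"),
    stringsAsFactors = FALSE)
  if (any(dataset$families$species != ref)) {
    proj <- project_ppi_status(dataset$families, network, ref)
    gene_status <- rbind(gene_status, proj)
  }
  catalog$ppi_status <- pair_ppi_status(catalog, gene_status)

  # expression divergence per species
  ed_parts <- list(); excl_parts <- list()
  for (sp in unique(catalog$species)) {
    cm <- dataset$counts[[sp]]
    if (is.null(cm)) stop("no count matrix for species ", sp)
    keep <- low_expression_filter(cm, multiplier = low_expr_multiplier)
    prof <- detection_profiles(cm[keep, , drop = FALSE],
                               threshold = detection_threshold)
    res <- ed_table(catalog[catalog$species == sp, , drop = FALSE], prof)
    ed_parts[[sp]] <- res$ed
    excl_parts[[sp]] <- res$exclusions
  }
  ed_all <- do.call(rbind, ed_parts)
  ed_key <- paste(ed_all$gene_a, ed_all$gene_b)

  # interaction divergence, reference species only
  ref_cat <- catalog[catalog$species == ref, , drop = FALSE]
  id_full <- id_table(ref_cat, network, min_deg_high, min_deg_low)
  id_key <- paste(id_full$gene_a, id_full$gene_b)

  records <- catalog
  records$sd <- records$kn
  m <- match(paste(records$gene_a, records$gene_b), ed_key)
  records$ed <- ed_all$ed[m]
  m2 <- match(paste(records$gene_a, records$gene_b), id_key)
  records$id <- ifelse(!is.na(m2) & id_full$eligible[m2],
                       id_full$id_value[m2], NA_real_)
  counts_summary <- summarize_counts(catalog)
  if (drop_unclassified)
    records <- records[records$mode != "unclassified", , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       network = network,
       id_full = id_full,
       ed_exclusions = do.call(rbind, excl_parts),
       counts_summary = counts_summary)
}
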