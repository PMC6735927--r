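# Protein-protein interaction networks and the interaction-divergence (ID)
# statistic.
#
# ID = 1 - 2 * I12 / (I1 + I2): one minus the Dice-style retention rate of
# interaction partners shared between two duplicates, where I1 and I2 are the
# partner counts of each copy and I12 the shared count.

#' Merge edge lists into a deduplicated undirected PPI network
#'
#' Takes one or more two-column edge tables (e.g. several source compendia),
#' normalizes identifiers (trimmed, upper-cased, version suffixes such as
#' `.1` stripped), drops self-interactions and collapses unordered duplicate
#' edges.
#'
#' @param edge_lists a data frame or list of data frames, each with two
#'   character columns (additional columns ignored).
#' @param normalize_ids normalize identifiers before merging (default TRUE).
#' @return an [igraph][igraph::graph_from_data_frame] undirected simple
#'   graph; attributes `n_nodes`, `n_edges` report the merged size.
#' @export
merge_networks <- function(edge_lists, normalize_ids = TRUE) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  rows <- lapply(seq_along(edge_lists), function(k) {
    el <- edge_lists[[k]]
    if (ncol(el) < 2) stop("edge list ", k, " has fewer than two columns")
    bad <- which(is.na(el[[1]]) | is.na(el[[2]]) | el[[1]] == "" | el[[2]] == "")
    if (length(bad))
      stop("edge list ", k, ": malformed row(s) at line(s) ",
           paste(utils::head(bad, 10), collapse = ", "))
    data.frame(a = as.character(el[[1]]), b = as.character(el[[2]]),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (normalize_ids && nrow(edges)) {
    norm <- function(x) sub("\\.[0-9]+$", "", toupper(trimws(x)))
    edges$a <- norm(edges$a)
    edges$b <- norm(edges$b)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  attr(g, "n_nodes") <- igraph::vcount(g)
  attr(g, "n_edges") <- igraph::ecount(g)
  g
}

partner_set <- function(network, gene, exclude = character()) {
  if (!(gene %in% igraph::V(network)$name)) return(NULL)
  nb <- igraph::neighbors(network, gene)$name
  setdiff(nb, exclude)
}

#' Interaction divergence of one duplicate pair
#'
#' Partner sets are taken from the merged network; by default each duplicate
#' is excluded from the other's partner set, so a heterodimerizing pair does
#' not automatically gain a shared partner from its own mutual interaction.
#' The pair is `eligible` for ID analysis when the better-connected copy has
#' at least `min_deg_high` partners and the other at least `min_deg_low`
#' (reducing noise from the high false-negative rate of experimental PPI
#' data); `id_value` is computed regardless and eligibility only flagged.
#'
#' @param gene_a,gene_b protein identifiers.
#' @param network an [merge_networks()] graph.
#' @param min_deg_high,min_deg_low eligibility cutoffs (defaults 4 and 1).
#' @param exclude_paralog drop each copy from the other's partner set before
#'   counting (default TRUE).
#' @return one-row data frame `i1`, `i2`, `i12`, `id_value`, `eligible`;
#'   `id_value` is `NA` when `i1 + i2 = 0` or a gene is absent from the
#'   network (then `eligible = FALSE`).
#' @export
compute_id <- function(gene_a, gene_b, network,
                       min_deg_high = 4L, min_deg_low = 1L,
                       exclude_paralog = TRUE) {
  excl <- if (exclude_paralog) c(gene_a, gene_b) else character()
  pa <- partner_set(network, gene_a, exclude = setdiff(excl, gene_a))
  pb <- partner_set(network, gene_b, exclude = setdiff(excl, gene_b))
  if (is.null(pa) || is.null(pb))
    return(data.frame(gene_a = gene_a, gene_b = gene_b,
                      i1 = NA_integer_, i2 = NA_integer_, i12 = NA_integer_,
                      id_value = NA_real_, eligible = FALSE,
                      stringsAsFactors = FALSE))
  i1 <- length(pa); i2 <- length(pb); i12 <- length(intersect(pa, pb))
  idv <- if (i1 + i2 > 0) 1 - 2 * i12 / (i1 + i2) else NA_real_
  data.frame(gene_a = gene_a, gene_b = gene_b, i1 = i1, i2 = i2, i12 = i12,
             id_value = idv,
             eligible = max(i1, i2) >= min_deg_high && min(i1, i2) >= min_deg_low,
             stringsAsFactors = FALSE)
}

#' Interaction divergence for a catalog of pairs
#'
#' @param pairs data frame with `gene_a`, `gene_b` (other columns carried
#'   through).
#' @inheritParams compute_id
#' @return `pairs` with `i1`, `i2`, `i12`, `id_value`, `eligible` appended.
#' @export
id_table <- function(pairs, network, min_deg_high = 4L, min_deg_low = 1L,
                     exclude_paralog = TRUE) {
  recs <- lapply(seq_len(nrow(pairs)), function(i)
    compute_id(pairs$gene_a[i], pairs$gene_b[i], network,
               min_deg_high, min_deg_low, exclude_paralog))
  recs <- do.call(rbind, recs)
  cbind(pairs, recs[, c("i1", "i2", "i12", "id_value", "eligible")])
}

#' Sweep the high-degree eligibility cutoff
#'
#' Recomputes pair eligibility for every cutoff value, reproducing the
#' robustness analysis in which the minimum partner count required of the
#' better-connected duplicate ranges from 1 to 14. The eligible set is
#' monotone decreasing in the cutoff.
#'
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param network a merged PPI graph.
#' @param cutoffs integer vector of `min_deg_high` values (default 1:14).
#' @param min_deg_low fixed low-degree cutoff (default 1).
#' @return data frame `cutoff`, `n_eligible`.
#' @export
sweep_id_cutoffs <- function(pairs, network, cutoffs = 1:14, min_deg_low = 1L) {
  base <- id_table(pairs, network, min_deg_high = 1L, min_deg_low = min_deg_low)
  hi <- pmax(base$i1, base$i2)
  lo <- pmin(base$i1, base$i2)
  data.frame(cutoff = cutoffs,
             n_eligible = vapply(cutoffs, function(k)
               sum(!is.na(hi) & hi >= k & lo >= min_deg_low), integer(1)))
}

#' Project reference-species PPI status onto other species via gene families
#'
#' A target-species gene is labeled `"with"` PPI iff any reference-species
#' gene in its family has at least one interaction in the reference network;
#' genes absent from the family table are `"without"` with a coverage
#' warning. A pair is `"with"` iff at least one member is.
#'
#' @param families data frame `family_id`, `species`, `gene_id`.
#' @param reference_network merged PPI graph for the reference species.
#' @param reference_species species identifier whose genes carry the network.
#' @param genes optional character vector of target genes to label (defaults
#'   to all non-reference genes in the family table).
#' @return data frame `gene_id`, `ppi_status`.
#' @export
project_ppi_status <- function(families, reference_network, reference_species,
                               genes = NULL) {
  stopifnot(all(c("family_id", "species", "gene_id") %in% names(families)))
  ref <- families[families$species == reference_species, , drop = FALSE]
  deg <- if (igraph::vcount(reference_network) > 0)
    igraph::degree(reference_network) else numeric()
  ref$has_ppi <- ref$gene_id %in% names(deg)[deg >= 1]
  fam_with <- unique(ref$family_id[ref$has_ppi])
  if (is.null(genes))
    genes <- unique(families$gene_id[families$species != reference_species])
  fam_of <- families$family_id[match(genes, families$gene_id)]
  uncovered <- is.na(fam_of)
  if (any(uncovered))
    warning(sum(uncovered), " gene(s) absent from the family table; ",
            "labeled without PPI")
  data.frame(gene_id = genes,
             ppi_status = ifelse(!uncovered & fam_of %in% fam_with,
                                 "with", "without"),
             stringsAsFactors = FALSE)
}

#' Pair-level PPI status
#'
#' A pair is `"with"` PPI iff at least one member is.
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param gene_status data frame `gene_id`, `ppi_status` (e.g. from
#'   [project_ppi_status()], or reference-species degrees).
#' @return character vector of `"with"`/`"without"` per pair.
#' @export
pair_ppi_status <- function(pairs, gene_status) {
  sa <- gene_status$ppi_status[match(pairs$gene_a, gene_status$gene_id)]
  sb <- gene_status$ppi_status[match(pairs$gene_b, gene_status$gene_id)]
  ifelse(!is.na(sa) & sa == "with" | !is.na(sb) & sb == "with",
         "with", "without")
}

#' Partner-retention banding of eligible pairs
#'
#' For each partition, the fraction of eligible pairs with more than half of
#' their interaction partners conserved (retention rate `2*i12/(i1+i2) >
#' 0.5`, strict) and the fraction sharing no partner at all (`i12 = 0`),
#' compared across partitions by two-sided Fisher's exact tests.
#'
#' @param id_records data frame with `i1`, `i2`, `i12`, `eligible` and a
#'   `partition` column (e.g. duplication mode).
#' @return list with `bands` (per-partition fractions and counts) and
#'   `tests` (Fisher p-values comparing the first two partitions for each
#'   band), or fractions flagged `NA` for empty partitions.
#' @export
shared_partner_banding <- function(id_records) {
  d <- id_records[id_records$eligible, , drop = FALSE]
  d$retention <- 2 * d$i12 / (d$i1 + d$i2)
  parts <- unique(d$partition)
  bands <- do.call(rbind, lapply(parts, function(p) {
    dp <- d[d$partition == p, ]
    n <- nrow(dp)
    data.frame(partition = p, n = n,
               n_half_conserved = sum(dp$retention > 0.5),
               n_zero_shared = sum(dp$i12 == 0),
               frac_half_conserved = if (n > 0) mean(dp$retention > 0.5) else NA_real_,
               frac_zero_shared = if (n > 0) mean(dp$i12 == 0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(parts) >= 2 && all(bands$n[1:2] > 0)) {
    ft <- function(hits) stats::fisher.test(matrix(
      c(hits, bands$n[1:2] - hits), nrow = 2))$p.value
    tests <- data.frame(
      band = c("half_conserved", "zero_shared"),
      p_value = c(ft(bands$n_half_conserved[1:2]), ft(bands$n_zero_shared[1:2])),
      stringsAsFactors = FALSE)
  }
  list(bands = bands, tests = tests)
}
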