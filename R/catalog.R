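# Duplicate-pair catalogs: loading, tandem classification, Ks filtering,
# partitioning and Table-style count summaries.

#' Read a duplicate-pair catalog
#'
#' @param path tab-separated file with columns `species`, `gene_a`, `gene_b`,
#'   `mode` (tandem/block/unclassified), `ks`, `kn`.
#' @return data frame of duplicate pairs.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "gene_a", "gene_b", "mode", "ks", "kn")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  bad <- df$mode[!df$mode %in% c("tandem", "block", "unclassified")]
  if (length(bad))
    stop("unknown duplication mode label(s): ", paste(unique(bad), collapse = ", "))
  if (any(df$gene_a == df$gene_b)) stop("catalog contains self-pairs")
  if (any(df$ks < 0) || any(df$kn < 0)) stop("ks and kn must be nonnegative")
  df
}

#' Classify duplicate pairs as tandem, block, or unclassified
#'
#' A pair is tandem when both genes lie on the same chromosome with at most
#' `max_gap` intervening genes on the gene-order axis (`|rank_a - rank_b| - 1
#' <= max_gap`). Block membership is consumed from the input (`is_block`
#' column), never computed: collinearity detection is upstream of this
#' package. A pair flagged both tandem and block, or neither, is labeled
#' `"unclassified"`; downstream analyses drop that label.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b` and logical
#'   `is_block`.
#' @param positions data frame with columns `gene_id`, `chromosome`, `rank`
#'   (0-based gene-order index, unique per chromosome).
#' @param max_gap maximum number of intervening genes for the tandem call
#'   (inclusive boundary; the default matches the usual tandem-gap setting
#'   of collinearity pipelines).
#' @return `pairs` with added columns `is_tandem` and `mode`. Pairs with a
#'   missing position raise a warning and get `mode = "unclassified"` with
#'   `is_tandem = NA` rather than being dropped silently.
#' @export
classify_tandem <- function(pairs, positions, max_gap = 30L) {
  stopifnot(all(c("gene_a", "gene_b", "is_block") %in% names(pairs)),
            all(c("gene_id", "chromosome", "rank") %in% names(positions)))
  if (anyDuplicated(positions[, c("chromosome", "rank")]))
    stop("positions: rank must be unique per chromosome")
  ia <- match(pairs$gene_a, positions$gene_id)
  ib <- match(pairs$gene_b, positions$gene_id)
  no_pos <- is.na(ia) | is.na(ib)
  if (any(no_pos))
    warning(sum(no_pos), " pair(s) have a gene without a position; ",
            "reported as unclassified")
  same_chr <- positions$chromosome[ia] == positions$chromosome[ib]
  intervening <- abs(positions$rank[ia] - positions$rank[ib]) - 1L
  pairs$is_tandem <- ifelse(no_pos, NA, same_chr & intervening <= max_gap)
  pairs$mode <- ifelse(is.na(pairs$is_tandem), "unclassified",
                ifelse(pairs$is_tandem & !pairs$is_block, "tandem",
                ifelse(pairs$is_block & !pairs$is_tandem, "block",
                       "unclassified")))
  pairs
}

#' Apply the Ks retention window
#'
#' Discards pairs whose synonymous substitution rate falls strictly below
#' `ks_min` (genetic redundancy of very young copies) or strictly above
#' `ks_max` (synonymous-site saturation of old copies); boundary values are
#' retained.
#'
#' @param pairs data frame with a `ks` column.
#' @param ks_min,ks_max window bounds (inclusive).
#' @return retained pairs, with attributes `discarded_low` and
#'   `discarded_high` holding the discard counts.
#' @export
apply_ks_window <- function(pairs, ks_min = 0.05, ks_max = 5.0) {
  stopifnot("ks" %in% names(pairs), !anyNA(pairs$ks))
  low <- pairs$ks < ks_min
  high <- pairs$ks > ks_max
  out <- pairs[!low & !high, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded_low") <- sum(low)
  attr(out, "discarded_high") <- sum(high)
  out
}

#' Partition duplicate pairs for comparative analysis
#'
#' Splits retained pairs by duplication mode, PPI status, or their cross,
#' optionally restricted to a younger-duplicate Ks subset (strict `<`
#' threshold). Unclassified pairs are excluded from any mode-based scheme.
#'
#' @param pairs data frame with `mode`, `ks` and (where needed) `ppi_status`
#'   (`"with"`/`"without"`).
#' @param by one of `"mode"`, `"ppi_status"`, `"mode_x_ppi"`.
#' @param ks_subset one of `"ks<5"`, `"ks<1"`.
#' @return named list of disjoint data frames; empty partitions are kept and
#'   flagged via the `"empty_partitions"` attribute.
#' @export
partition_pairs <- function(pairs, by = c("mode", "ppi_status", "mode_x_ppi"),
                            ks_subset = c("ks<5", "ks<1")) {
  by <- match.arg(by)
  ks_subset <- match.arg(ks_subset)
  thr <- if (ks_subset == "ks<5") 5 else 1
  pairs <- pairs[pairs$ks < thr, , drop = FALSE]
  if (by != "ppi_status")
    pairs <- pairs[pairs$mode %in% c("tandem", "block"), , drop = FALSE]
  key <- switch(by,
    mode = pairs$mode,
    ppi_status = pairs$ppi_status,
    mode_x_ppi = paste(pairs$mode, pairs$ppi_status, sep = "_"))
  levels <- switch(by,
    mode = c("tandem", "block"),
    ppi_status = c("with", "without"),
    mode_x_ppi = c("tandem_with", "tandem_without", "block_with", "block_without"))
  out <- lapply(levels, function(l) {
    d <- pairs[key == l, , drop = FALSE]; rownames(d) <- NULL; d
  })
  names(out) <- levels
  attr(out, "empty_partitions") <- levels[vapply(out, nrow, integer(1)) == 0L]
  out
}

#' Summarize duplicate counts by species, mode and PPI status
#'
#' Produces the classic accounting table: for each species, pair counts by
#' duplication mode crossed with with/without PPI, plus totals; each species
#' row sums to its total pair count.
#'
#' @param pairs data frame with `species`, `mode`, `ppi_status`.
#' @return data frame with one row per species and per-mode
#'   total/with/without columns.
#' @export
summarize_counts <- function(pairs) {
  stopifnot(all(c("species", "mode", "ppi_status") %in% names(pairs)))
  species <- sort(unique(pairs$species))
  modes <- c("tandem", "block", "unclassified")
  rows <- lapply(species, function(sp) {
    d <- pairs[pairs$species == sp, ]
    cells <- unlist(lapply(modes, function(m) {
      dm <- d[d$mode == m, ]
      c(total = nrow(dm),
        with_ppi = sum(dm$ppi_status == "with"),
        without_ppi = sum(dm$ppi_status == "without"))
    }))
    names(cells) <- paste(rep(modes, each = 3),
                          c("total", "with_ppi", "without_ppi"), sep = "_")
    data.frame(species = sp, t(cells), total = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(0))
  rownames(out) <- NULL
  out
}
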