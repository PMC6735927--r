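# Correlation panels, representation tests and flat GO-slim enrichment.

star_bin <- function(p) {
  ifelse(p < 1e-10, "***", ifelse(p < 1e-5, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Pairwise correlation panel across partitions and Ks subsets
#'
#' For every variable pair, partition and Ks subset, computes Pearson's r and
#' Spearman's rank rho (average ranks under ties) with their p-values, binned
#' into significance stars (`***` p < 1e-10, `**` p < 1e-5, `*` p < 0.05,
#' `ns` otherwise). Cells with fewer than `min_n` complete observations are
#' flagged not computed.
#'
#' @param records data frame containing `ks` plus the variables.
#' @param variables character vector of variable column names (e.g.
#'   `c("ks", "sd", "ed")`); all unordered pairs are tested.
#' @param partition_col column of `records` naming the partition of each row
#'   (NULL = one partition `"all"`).
#' @param ks_subsets character vector among `c("ks<5", "ks<1")` (strict
#'   thresholds).
#' @param min_n minimum complete observations per cell (default 3).
#' @return long data frame: `var_x`, `var_y`, `partition`, `ks_subset`,
#'   `method`, `coefficient`, `p_value`, `star_bin`, `n`, `computed`.
#' @export
correlation_panel <- function(records, variables,
                              partition_col = NULL,
                              ks_subsets = c("ks<5", "ks<1"),
                              min_n = 3L) {
  stopifnot(all(variables %in% names(records)), "ks" %in% names(records))
  parts <- if (is.null(partition_col)) list(all = rep(TRUE, nrow(records)))
    else {
      lv <- unique(records[[partition_col]])
      stats::setNames(lapply(lv, function(l) records[[partition_col]] == l), lv)
    }
  combs <- utils::combn(variables, 2)
  out <- list()
  for (ksub in ks_subsets) {
    thr <- if (ksub == "ks<5") 5 else 1
    in_ks <- records$ks < thr
    for (pn in names(parts)) for (k in seq_len(ncol(combs))) {
      vx <- combs[1, k]; vy <- combs[2, k]
      sel <- parts[[pn]] & in_ks & !is.na(records[[vx]]) & !is.na(records[[vy]])
      n <- sum(sel)
      for (method in c("pearson", "spearman")) {
        if (n >= min_n) {
          ct <- suppressWarnings(stats::cor.test(
            records[[vx]][sel], records[[vy]][sel], method = method,
            exact = FALSE))
          row <- data.frame(var_x = vx, var_y = vy, partition = pn,
                            ks_subset = ksub, method = method,
                            coefficient = unname(ct$estimate),
                            p_value = ct$p.value,
                            star_bin = star_bin(ct$p.value),
                            n = n, computed = TRUE, stringsAsFactors = FALSE)
        } else {
          row <- data.frame(var_x = vx, var_y = vy, partition = pn,
                            ks_subset = ksub, method = method,
                            coefficient = NA_real_, p_value = NA_real_,
                            star_bin = NA_character_, n = n, computed = FALSE,
                            stringsAsFactors = FALSE)
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}

#' Per-category representation test of a binary trait
#'
#' For each category, builds the 2x2 table (category vs. rest) x (trait vs.
#' no trait), runs a two-sided Fisher's exact test, assigns direction from
#' the odds ratio and BH-corrects across categories.
#'
#' @param counts matrix or data frame with categories as rows and two columns
#'   `with` and `without` (trait counts per category).
#' @return data frame `category`, `with`, `without`, `direction`
#'   (`"over"`/`"under"` representation of the trait), `p_value`, `q_value`.
#' @export
representation_test <- function(counts) {
  counts <- as.matrix(counts[, c("with", "without")])
  if (nrow(counts) < 2L) stop("need at least two categories")
  tot <- colSums(counts)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    tab <- rbind(counts[i, ], tot - counts[i, ])
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(category = rownames(counts)[i],
               with = counts[i, "with"], without = counts[i, "without"],
               direction = if (ft$estimate >= 1) "over" else "under",
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_correct(out$p_value)
  rownames(out) <- NULL
  out
}

#' Flat GO-slim enrichment by hypergeometric tests
#'
#' For each term with at least one annotated background gene, computes the
#' upper hypergeometric tail (over-representation of the term in the gene
#' set) and the lower tail (under-representation); both tests are reported,
#' the smaller tail defines the term's direction, and BH correction is
#' applied across all reported tests. Annotations are used flat (GO-slim):
#' no DAG propagation.
#'
#' @param gene_set character vector, a subset of `background`.
#' @param background character vector of all genes in the analysis set.
#' @param annotations data frame `gene_id`, `term_id`.
#' @return data frame `term_id`, `k` (term genes in set), `n` (set size),
#'   `K` (term genes in background), `N` (background size), `direction`,
#'   `p_over`, `p_under`, `p_value` (smaller tail), `q_value`.
#' @export
go_enrichment <- function(gene_set, background, annotations) {
  if (length(background) == 0L) stop("empty background")
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  terms <- sort(unique(ann$term_id))
  N <- length(background); n <- length(gene_set)
  res <- lapply(terms, function(t) {
    tg <- unique(ann$gene_id[ann$term_id == t])
    K <- length(tg)
    k <- sum(gene_set %in% tg)
    p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
    data.frame(term_id = t, k = k, n = n, K = K, N = N,
               direction = if (p_over <= p_under) "over" else "under",
               p_over = p_over, p_under = p_under,
               p_value = min(p_over, p_under), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term_id = character(0)))
  out$q_value <- bh_correct(out$p_value)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up correction
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`: step-up
#' `q_i = min_{j >= i} m * p_(j) / j`, clipped at 1, mapped back to input
#' order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_correct <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}
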