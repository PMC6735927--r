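# Expression divergence (ED) of duplicate pairs from condition detection
# profiles.
#
# ED = (C1 + C2) / C, where C1 and C2 count conditions in which only one of
# the two copies is detected and C counts conditions in which at least one is
# (the union). ED = 0 means the copies are always detected together; ED = 1
# means they are never detected together.

#' Counts-per-million transform
#'
#' Scales each condition column to a library size of one million:
#' `cpm[i, j] = counts[i, j] / colsum[j] * 1e6`.
#'
#' @param counts nonnegative gene-by-condition count matrix.
#' @return numeric matrix of the same shape.
#' @export
cpm_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  cs <- colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("all-zero condition column(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, cs, "/") * 1e6
}

#' Low-expression filter
#'
#' A gene is retained iff its summed count over all conditions is at least
#' twice the number of conditions (genes summing strictly lower are removed).
#'
#' @param counts integer gene-by-condition matrix with gene rownames.
#' @param multiplier the per-condition count multiple required (default 2).
#' @return character vector of retained gene ids.
#' @export
low_expression_filter <- function(counts, multiplier = 2) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) stop("count matrix has zero conditions")
  keep <- rowSums(counts) >= multiplier * ncol(counts)
  rownames(counts)[keep]
}

#' Build per-gene detection profiles
#'
#' A gene is "detected" in a condition when its matrix value exceeds
#' `threshold`. With raw counts the default threshold 0 reads as "at least
#' one read"; a positive threshold on a CPM-transformed matrix is the
#' configurable alternative.
#'
#' @param mat gene-by-condition matrix (raw or CPM-transformed), rows already
#'   restricted to the post-filter gene set.
#' @param threshold detection threshold (strictly-greater comparison).
#' @return logical gene-by-condition matrix of class `"detection_profiles"`.
#' @export
detection_profiles <- function(mat, threshold = 0) {
  mat <- as.matrix(mat)
  out <- mat > threshold
  class(out) <- c("detection_profiles", class(out))
  out
}

#' Expression divergence of one duplicate pair
#'
#' @param gene_a,gene_b gene identifiers.
#' @param profiles a [detection_profiles()] matrix.
#' @return A one-row data frame with `c1` (conditions where only `gene_a` is
#'   detected), `c2` (only `gene_b`), `c` (at least one), and
#'   `ed = (c1 + c2) / c`; or an object of class `"ed_exclusion"` (a list
#'   with element `reason`) when the pair cannot be scored (a gene absent
#'   from the matrix, or `c = 0`).
#' @export
compute_ed <- function(gene_a, gene_b, profiles) {
  excl <- function(reason) structure(list(reason = reason), class = "ed_exclusion")
  if (!(gene_a %in% rownames(profiles)) || !(gene_b %in% rownames(profiles)))
    return(excl("gene not represented in expression matrix"))
  a <- profiles[gene_a, ]
  b <- profiles[gene_b, ]
  c1 <- sum(a & !b)
  c2 <- sum(b & !a)
  cc <- sum(a | b)
  if (cc == 0L) return(excl("not detected in any condition"))
  data.frame(gene_a = gene_a, gene_b = gene_b,
             c1 = c1, c2 = c2, c = cc, ed = (c1 + c2) / cc,
             stringsAsFactors = FALSE)
}

#' Expression divergence for a catalog of pairs
#'
#' Vectorized driver over [compute_ed()] semantics: for each pair, C1/C2/C
#' are the only-one-copy and union detection counts and ED = (C1 + C2)/C.
#' Pairs with a copy missing from the (post-filter) matrix or never detected
#' are routed to an exclusion table with a reason code, mirroring the
#' both-genes-represented accounting of real compendia.
#'
#' @param pairs data frame with `gene_a`, `gene_b` columns (other columns are
#'   carried through).
#' @param profiles a [detection_profiles()] matrix.
#' @return list with `ed` (scored pairs with `c1`, `c2`, `c`, `ed` columns
#'   appended) and `exclusions` (pairs plus `reason`).
#' @export
ed_table <- function(pairs, profiles) {
  rn <- rownames(profiles)
  ia <- match(pairs$gene_a, rn)
  ib <- match(pairs$gene_b, rn)
  missing <- is.na(ia) | is.na(ib)
  c1 <- c2 <- cc <- rep(NA_integer_, nrow(pairs))
  ok <- which(!missing)
  if (length(ok)) {
    A <- profiles[ia[ok], , drop = FALSE]
    B <- profiles[ib[ok], , drop = FALSE]
    c1[ok] <- rowSums(A & !B)
    c2[ok] <- rowSums(B & !A)
    cc[ok] <- rowSums(A | B)
  }
  undetected <- !missing & cc == 0L
  scored <- !missing & !undetected
  ed <- pairs[scored, , drop = FALSE]
  ed$c1 <- c1[scored]; ed$c2 <- c2[scored]; ed$c <- cc[scored]
  ed$ed <- (ed$c1 + ed$c2) / ed$c
  excl <- pairs[!scored, , drop = FALSE]
  excl$reason <- ifelse(missing[!scored],
                        "gene not represented in expression matrix",
                        "not detected in any condition")
  rownames(ed) <- rownames(excl) <- NULL
  list(ed = ed, exclusions = excl)
}
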