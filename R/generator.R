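# Synthetic multi-species duplicate-gene datasets with known ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# probe: bimodal Ks for block (WGD) duplicates vs. quasi-continuous Ks for
# tandem ones; sequence (Kn), expression (ED) and interaction (ID) divergence
# rising with Ks along saturating curves with partition-specific asymptotes;
# PPI degrees with a mode-independent mean; GO terms biased by partition.

#' Build and validate a synthetic-dataset generator configuration
#'
#' The defaults describe a three-species study (one reference species carrying
#' the PPI network, two species receiving PPI status only by family
#' projection), with block-duplicate Ks drawn from a two-peak Gaussian mixture
#' (emulating the age peaks left by discrete WGD events) and tandem Ks from a
#' truncated exponential (continuous, ongoing duplication). Divergence means
#' follow origin-constrained saturation curves `a * ks / (b + ks)` whose
#' asymptotes differ by duplication mode and PPI status: block < tandem and
#' with-PPI < without-PPI, the orderings the pipeline is designed to detect.
#'
#' @param species character vector of species identifiers; the first is the
#'   reference species, the only one that receives PPI edges.
#' @param n_block_pairs,n_tandem_pairs,n_unclassified_pairs pairs per species
#'   (scalars, recycled across species). Unclassified pairs are drawn from the
#'   tandem process and relabeled; they exist so downstream stages can be shown
#'   to drop them.
#' @param block_ks_peaks list of numeric vectors `c(mean, sd, weight)` defining
#'   the truncated Gaussian mixture for block-pair Ks.
#' @param tandem_ks_rate rate of the truncated exponential for tandem Ks.
#' @param ks_range length-2 numeric, truncation window for all Ks draws.
#' @param sd_curve_params,ed_curve_params,id_curve_params named lists with
#'   elements `tandem_without`, `tandem_with`, `block_without`, `block_with`,
#'   each `c(a, b)`: asymptote and half-saturation of the latent divergence
#'   curve for that mode-by-PPI partition. ED and ID asymptotes must lie in
#'   [0, 1]; the SD asymptote only needs to be nonnegative.
#' @param noise_sd named numeric `c(sd, ed, id)`: Gaussian noise added to the
#'   latent curve value before discretization, then clamped to the measure's
#'   bounds.
#' @param n_conditions number of expression conditions (>= 10; fewer cannot
#'   realize a useful ED resolution).
#' @param detection_prob probability mass of conditions in a pair's detected
#'   union: the union size is `round(detection_prob * n_conditions)`.
#' @param count_model numeric `c(mean, dispersion)` for negative-binomial
#'   counts in detected cells (dispersion 0 gives Poisson counts).
#' @param ppi_degree_mean mean of the zero-truncated Poisson ancestral partner
#'   count; identical for both modes so degree does not confound mode effects.
#' @param ppi_fraction fraction of reference-species pairs engaging in PPIs.
#' @param go_base_rate baseline probability a gene carries a given GO term.
#' @param go_terms data frame with columns `term`, `partition` (one of
#'   `"block"`, `"tandem"`, `"none"`) and `fold`: term `term` is assigned to
#'   genes of that duplication mode at `fold` times the base rate.
#' @param seed single integer; all random substreams are derived from it by
#'   fixed offsets.
#'
#' @return A validated list of class `"generator_config"`.
#' @seealso [generate_dataset()], [write_dataset()]
#' @export
generator_config <- function(species = c("ath", "sly", "zma"),
                             n_block_pairs = 300L,
                             n_tandem_pairs = 300L,
                             n_unclassified_pairs = 60L,
                             block_ks_peaks = list(c(mean = 0.9, sd = 0.2, weight = 0.55),
                                                   c(mean = 2.4, sd = 0.45, weight = 0.45)),
                             tandem_ks_rate = 0.8,
                             ks_range = c(0.05, 5),
                             sd_curve_params = list(
                               tandem_without = c(a = 1.00, b = 1.2),
                               tandem_with    = c(a = 0.75, b = 1.2),
                               block_without  = c(a = 0.55, b = 1.2),
                               block_with     = c(a = 0.40, b = 1.2)),
                             ed_curve_params = list(
                               tandem_without = c(a = 0.55, b = 0.6),
                               tandem_with    = c(a = 0.40, b = 0.6),
                               block_without  = c(a = 0.32, b = 0.6),
                               block_with     = c(a = 0.22, b = 0.6)),
                             id_curve_params = list(
                               tandem_without = c(a = 0.85, b = 0.8),
                               tandem_with    = c(a = 0.85, b = 0.8),
                               block_without  = c(a = 0.55, b = 0.8),
                               block_with     = c(a = 0.55, b = 0.8)),
                             noise_sd = c(sd = 0.05, ed = 0.05, id = 0.05),
                             n_conditions = 50L,
                             detection_prob = 0.8,
                             count_model = c(mean = 100, dispersion = 0.3),
                             ppi_degree_mean = 6.2,
                             ppi_fraction = 0.6,
                             go_base_rate = 0.05,
                             go_terms = default_go_terms(),
                             seed = 1L) {
  cfg <- list(
    species = as.character(species),
    n_block_pairs = as.integer(n_block_pairs),
    n_tandem_pairs = as.integer(n_tandem_pairs),
    n_unclassified_pairs = as.integer(n_unclassified_pairs),
    block_ks_peaks = block_ks_peaks,
    tandem_ks_rate = tandem_ks_rate,
    ks_range = as.numeric(ks_range),
    sd_curve_params = sd_curve_params,
    ed_curve_params = ed_curve_params,
    id_curve_params = id_curve_params,
    noise_sd = noise_sd,
    n_conditions = as.integer(n_conditions),
    detection_prob = detection_prob,
    count_model = count_model,
    ppi_degree_mean = ppi_degree_mean,
    ppi_fraction = ppi_fraction,
    go_base_rate = go_base_rate,
    go_terms = go_terms,
    seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(length(cfg$species) >= 1L, !anyDuplicated(cfg$species))
  if (cfg$n_block_pairs < 1L || cfg$n_tandem_pairs < 1L)
    stop("need at least one block and one tandem pair per species")
  if (cfg$n_unclassified_pairs < 0L)
    stop("n_unclassified_pairs must be nonnegative")
  if (cfg$n_conditions < 10L)
    stop("n_conditions must be at least 10 to realize the requested ED resolution")
  if (!(cfg$detection_prob > 0 && cfg$detection_prob <= 1))
    stop("detection_prob must be in (0, 1]")
  if (cfg$ppi_fraction < 0 || cfg$ppi_fraction > 1)
    stop("ppi_fraction must be in [0, 1]")
  if (cfg$ks_range[1] >= cfg$ks_range[2] || cfg$ks_range[1] < 0)
    stop("ks_range must satisfy 0 <= min < max")
  if (cfg$tandem_ks_rate <= 0) stop("tandem_ks_rate must be positive")
  w <- vapply(cfg$block_ks_peaks, function(p) p[["weight"]], numeric(1))
  if (any(w < 0) || sum(w) <= 0) stop("block_ks_peaks weights must be nonnegative, not all zero")
  if (any(cfg$noise_sd < 0)) stop("noise_sd entries must be nonnegative")
  for (nm in c("sd", "ed", "id")) {
    pars <- cfg[[paste0(nm, "_curve_params")]]
    need <- c("tandem_without", "tandem_with", "block_without", "block_with")
    if (!all(need %in% names(pars)))
      stop(sprintf("%s_curve_params must name all four mode-by-PPI partitions", nm))
    for (p in pars) {
      if (p[["a"]] < 0) stop("curve asymptote a must be >= 0")
      if (p[["b"]] <= 0) stop("curve half-saturation b must be > 0")
      if (nm %in% c("ed", "id") && p[["a"]] > 1)
        stop(sprintf("%s asymptote must lie in [0, 1] (bounded measure)", toupper(nm)))
    }
  }
  if (cfg$count_model[["mean"]] <= 0 || cfg$count_model[["dispersion"]] < 0)
    stop("count_model mean must be positive and dispersion nonnegative")
  if (cfg$ppi_degree_mean <= 0) stop("ppi_degree_mean must be positive")
  invisible(cfg)
}

#' Default GO-slim term table for the generator
#'
#' Twelve flat terms: three biased into block duplicates, three into tandem
#' duplicates (fivefold over the base rate), six unbiased.
#' @return data frame with columns `term`, `partition`, `fold`.
#' @export
default_go_terms <- function() {
  data.frame(
    term = sprintf("GO:%07d", seq_len(12L)),
    partition = c(rep("block", 3), rep("tandem", 3), rep("none", 6)),
    fold = c(rep(5, 6), rep(1, 6)),
    stringsAsFactors = FALSE)
}

## -- truncated samplers (inverse-CDF, vectorized, rejection-free) ------------

rtrunc_exp <- function(n, rate, lo, hi) {
  u <- stats::runif(n)
  plo <- stats::pexp(lo, rate)
  phi <- stats::pexp(hi, rate)
  stats::qexp(plo + u * (phi - plo), rate)
}

rtrunc_norm_mix <- function(n, peaks, lo, hi) {
  w <- vapply(peaks, function(p) p[["weight"]], numeric(1))
  comp <- sample.int(length(peaks), n, replace = TRUE, prob = w)
  m <- vapply(peaks, function(p) p[["mean"]], numeric(1))[comp]
  s <- vapply(peaks, function(p) p[["sd"]], numeric(1))[comp]
  plo <- stats::pnorm(lo, m, s)
  phi <- stats::pnorm(hi, m, s)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), m, s)
}

rpois_trunc1 <- function(n, mu) {
  # zero-truncated Poisson via inverse CDF
  p0 <- stats::ppois(0, mu)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), mu)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

saturation_mean <- function(ks, pars) pars[["a"]] * ks / (pars[["b"]] + ks)

#' Generate a synthetic duplicate-gene dataset
#'
#' Runs the full generative model described in [generator_config()]. Latent
#' per-pair divergence values are drawn from the partition's saturation curve
#' plus clamped Gaussian noise; observable data are then constructed so the
#' downstream statistics recover the latent values up to discretization:
#'
#' * **ED**: each pair's detected union has `C = round(detection_prob *
#'   n_conditions)` conditions of which `round(ED * C)` are unique to one
#'   copy, split as evenly as possible (odd remainder to the lexicographically
#'   first gene); counts in detected cells are negative binomial with a floor
#'   guaranteeing survival of the low-expression filter.
#' * **ID** (reference species, with-PPI pairs only): ancestral partner count
#'   `N` is zero-truncated Poisson; both genes keep `s = round((1 - ID) * N)`
#'   shared partners plus `N - s` unique ones each, so both degrees equal `N`
#'   and the realized ID is `1 - s/N`.
#' * **Kn** is the latent sequence-divergence (SD) value itself.
#'
#' Non-reference pairs inherit family membership (and hence projected PPI
#' status) from a reference-species family by cyclic assignment.
#'
#' @param config a [generator_config()].
#' @return An object of class `"synthetic_dataset"`: a list with elements
#'   `catalog` (data frame: species, gene_a, gene_b, mode, ks, kn), `counts`
#'   (named list of integer gene-by-condition matrices, one per species),
#'   `ppi` (two-column edge data frame for the reference species), `families`
#'   (family_id, species, gene_id), `go` (gene_id, term_id) and
#'   `ground_truth` (curve parameters plus a per-pair table of latent and
#'   realized divergence values).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n_sp <- length(config$species)
  n_pairs <- config$n_block_pairs + config$n_tandem_pairs + config$n_unclassified_pairs
  ref <- config$species[1]

  ## substream 1: Ks, PPI status, latent divergence values -------------------
  set.seed(config$seed + 11L)
  truth <- vector("list", n_sp)
  for (si in seq_len(n_sp)) {
    sp <- config$species[si]
    mode <- rep(c("block", "tandem", "unclassified"),
                c(config$n_block_pairs, config$n_tandem_pairs, config$n_unclassified_pairs))
    ks <- numeric(n_pairs)
    is_blk <- mode == "block"
    ks[is_blk] <- rtrunc_norm_mix(sum(is_blk), config$block_ks_peaks,
                                  config$ks_range[1], config$ks_range[2])
    ks[!is_blk] <- rtrunc_exp(sum(!is_blk), config$tandem_ks_rate,
                              config$ks_range[1], config$ks_range[2])
    pid <- sprintf("%s_p%04d", sp, seq_len(n_pairs))
    truth[[si]] <- data.frame(
      species = sp, pair_id = pid,
      gene_a = paste0(pid, "a"), gene_b = paste0(pid, "b"),
      mode = mode, ks = ks, stringsAsFactors = FALSE)
  }
  # reference PPI status; targets inherit via cyclic family link
  truth[[1]]$ppi_status <- ifelse(stats::runif(n_pairs) < config$ppi_fraction,
                                  "with", "without")
  truth[[1]]$family_id <- sprintf("FAM%05d", seq_len(n_pairs))
  if (n_sp > 1) for (si in 2:n_sp) {
    link <- ((seq_len(n_pairs) - 1L) %% n_pairs) + 1L
    truth[[si]]$ppi_status <- truth[[1]]$ppi_status[link]
    truth[[si]]$family_id <- truth[[1]]$family_id[link]
  }
  truth <- do.call(rbind, truth)

  # latent divergence values: unclassified pairs ride the tandem curves
  curve_mode <- ifelse(truth$mode == "block", "block", "tandem")
  part <- paste(curve_mode, truth$ppi_status, sep = "_")
  latent_one <- function(pars_list, noise, lo, hi) {
    mu <- vapply(seq_len(nrow(truth)), function(i)
      saturation_mean(truth$ks[i], pars_list[[part[i]]]), numeric(1))
    clamp(mu + stats::rnorm(nrow(truth), 0, noise), lo, hi)
  }
  truth$latent_sd <- latent_one(config$sd_curve_params, config$noise_sd[["sd"]], 0, Inf)
  truth$latent_ed <- latent_one(config$ed_curve_params, config$noise_sd[["ed"]], 0, 1)
  truth$latent_id <- latent_one(config$id_curve_params, config$noise_sd[["id"]], 0, 1)
  truth$kn <- truth$latent_sd

  ## substream 2: detection-profile structure --------------------------------
  set.seed(config$seed + 12L)
  C <- max(1L, as.integer(round(config$detection_prob * config$n_conditions)))
  U <- as.integer(round(truth$latent_ed * C))
  truth$realized_ed <- U / C
  det_a <- det_b <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    conds <- sample.int(config$n_conditions, C)
    shared <- conds[seq_len(C - U[i])]
    uniq <- setdiff(conds, shared)
    ua <- as.integer(ceiling(U[i] / 2))      # odd remainder to the first gene
    det_a[[i]] <- c(shared, uniq[seq_len(ua)])
    det_b[[i]] <- c(shared, if (U[i] > ua) uniq[(ua + 1L):U[i]])
  }

  ## substream 3: counts -----------------------------------------------------
  set.seed(config$seed + 13L)
  mu <- config$count_model[["mean"]]
  phi <- config$count_model[["dispersion"]]
  draw_counts <- function(n) {
    if (phi > 0) stats::rnbinom(n, mu = mu, size = 1 / phi) else stats::rpois(n, mu)
  }
  counts <- list()
  for (sp in config$species) {
    idx <- which(truth$species == sp)
    genes <- c(rbind(truth$gene_a[idx], truth$gene_b[idx]))
    m <- matrix(0L, nrow = length(genes), ncol = config$n_conditions,
                dimnames = list(genes, sprintf("cond%03d", seq_len(config$n_conditions))))
    for (k in seq_along(idx)) {
      i <- idx[k]
      for (g in list(c(truth$gene_a[i], "a"), c(truth$gene_b[i], "b"))) {
        det <- if (g[2] == "a") det_a[[i]] else det_b[[i]]
        if (length(det) == 0L) next
        floor_ct <- max(1L, ceiling(2 * config$n_conditions / length(det)))
        m[g[1], det] <- floor_ct + draw_counts(length(det))
      }
    }
    counts[[sp]] <- m
  }

  ## substream 4: PPI partner sets (reference species only) ------------------
  set.seed(config$seed + 14L)
  ref_idx <- which(truth$species == ref)
  with_idx <- ref_idx[truth$ppi_status[ref_idx] == "with"]
  truth$ppi_degree <- NA_integer_
  truth$realized_id <- NA_real_
  edges <- list()
  if (length(with_idx) > 0) {
    N <- rpois_trunc1(length(with_idx), config$ppi_degree_mean)
    s <- as.integer(round((1 - truth$latent_id[with_idx]) * N))
    truth$ppi_degree[with_idx] <- N
    truth$realized_id[with_idx] <- 1 - s / N
    for (k in seq_along(with_idx)) {
      i <- with_idx[k]
      pid <- truth$pair_id[i]
      sh <- if (s[k] > 0) sprintf("%s_shared%02d", pid, seq_len(s[k])) else character()
      ua <- if (N[k] - s[k] > 0) sprintf("%s_ua%02d", pid, seq_len(N[k] - s[k])) else character()
      ub <- if (N[k] - s[k] > 0) sprintf("%s_ub%02d", pid, seq_len(N[k] - s[k])) else character()
      edges[[length(edges) + 1L]] <- data.frame(
        protein_a = c(rep(truth$gene_a[i], N[k]), rep(truth$gene_b[i], N[k])),
        protein_b = c(sh, ua, sh, ub), stringsAsFactors = FALSE)
    }
  }
  ppi <- if (length(edges)) do.call(rbind, edges) else
    data.frame(protein_a = character(), protein_b = character(), stringsAsFactors = FALSE)

  ## substream 5: GO annotation (reference species genes) --------------------
  set.seed(config$seed + 15L)
  ref_genes <- data.frame(
    gene_id = c(truth$gene_a[ref_idx], truth$gene_b[ref_idx]),
    mode = rep(truth$mode[ref_idx], 2L), stringsAsFactors = FALSE)
  go_rows <- list()
  for (t in seq_len(nrow(config$go_terms))) {
    trm <- config$go_terms$term[t]
    p <- config$go_base_rate *
      ifelse(ref_genes$mode == config$go_terms$partition[t], config$go_terms$fold[t], 1)
    hit <- stats::runif(nrow(ref_genes)) < pmin(p, 1)
    if (any(hit))
      go_rows[[length(go_rows) + 1L]] <- data.frame(
        gene_id = ref_genes$gene_id[hit], term_id = trm, stringsAsFactors = FALSE)
  }
  go <- if (length(go_rows)) do.call(rbind, go_rows) else
    data.frame(gene_id = character(), term_id = character(), stringsAsFactors = FALSE)

  families <- data.frame(
    family_id = truth$family_id,
    species = truth$species,
    gene_id = truth$gene_a, stringsAsFactors = FALSE)
  families <- rbind(families,
                    transform(families, gene_id = truth$gene_b))
  families <- families[order(families$family_id, families$species, families$gene_id), ]
  rownames(families) <- NULL

  catalog <- truth[, c("species", "gene_a", "gene_b", "mode", "ks", "kn")]
  rownames(catalog) <- NULL

  structure(list(
    catalog = catalog,
    counts = counts,
    ppi = ppi,
    families = families,
    go = go,
    ground_truth = list(
      seed = config$seed,
      species = config$species,
      reference_species = ref,
      n_conditions = config$n_conditions,
      union_size = C,
      curve_params = list(sd = config$sd_curve_params,
                          ed = config$ed_curve_params,
                          id = config$id_curve_params),
      note = paste("All distributional choices are the generator's own;",
                   "unclassified pairs are relabeled draws from the tandem process.",
                   "Realized ED = round(latent_ed * C) / C;",
                   "realized ID = 1 - round((1 - latent_id) * N) / N with both degrees N."),
      pairs = truth)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$catalog), "pairs across",
      length(unique(x$catalog$species)), "species;",
      nrow(x$ppi), "PPI edges;", nrow(x$go), "GO annotations\n")
  print(table(x$catalog$species, x$catalog$mode))
  invisible(x)
}

#' Write a synthetic dataset to its external file interfaces
#'
#' Emits `catalog.tsv`, one `counts.<species>.tsv` per species, `ppi.tsv`,
#' `families.tsv`, `go.tsv` and a `ground_truth.json` sidecar holding every
#' latent parameter and per-pair latent value.
#'
#' @param dataset a [generate_dataset()] result.
#' @param directory output directory (created if absent).
#' @return Invisibly, a manifest data frame (`file`, `kind`, `rows`).
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(directory, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    data.frame(file = file, kind = "interface", rows = nrow(df),
               stringsAsFactors = FALSE)
  }
  man <- list(wr(dataset$catalog, "catalog.tsv"))
  for (sp in names(dataset$counts)) {
    m <- dataset$counts[[sp]]
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    man[[length(man) + 1L]] <- wr(df, sprintf("counts.%s.tsv", sp))
  }
  man[[length(man) + 1L]] <- wr(dataset$ppi, "ppi.tsv")
  man[[length(man) + 1L]] <- wr(dataset$families, "families.tsv")
  man[[length(man) + 1L]] <- wr(dataset$go, "go.tsv")
  jsonlite::write_json(dataset$ground_truth,
                       file.path(directory, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  man[[length(man) + 1L]] <- data.frame(file = "ground_truth.json",
                                        kind = "sidecar",
                                        rows = nrow(dataset$ground_truth$pairs),
                                        stringsAsFactors = FALSE)
  invisible(do.call(rbind, man))
}

#' Read a written synthetic dataset back from disk
#'
#' Inverse of [write_dataset()]; the ground-truth sidecar is reloaded too.
#' @param directory directory written by [write_dataset()].
#' @return a list with the same `catalog`, `counts`, `ppi`, `families`, `go`
#'   elements as the in-memory dataset.
#' @export
read_dataset <- function(directory) {
  rd <- function(file) utils::read.delim(file.path(directory, file),
                                         stringsAsFactors = FALSE, check.names = FALSE)
  catalog <- rd("catalog.tsv")
  cf <- list.files(directory, pattern = "^counts\\..*\\.tsv$")
  counts <- list()
  for (f in cf) {
    df <- rd(f)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df$gene_id
    counts[[sub("^counts\\.(.*)\\.tsv$", "\\1", f)]] <- m
  }
  gt_path <- file.path(directory, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(catalog = catalog, counts = counts, ppi = rd("ppi.tsv"),
       families = rd("families.tsv"), go = rd("go.tsv"), ground_truth = gt)
}
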