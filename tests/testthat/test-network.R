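test_that("merging deduplicates unordered edges and drops self-loops", {
  l1 <- data.frame(a = "a", b = "b")
  l2 <- data.frame(a = c("b", "a"), b = c("a", "a"))
  g <- merge_networks(list(l1, l2), normalize_ids = FALSE)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)
  empty <- merge_networks(data.frame(a = character(), b = character()))
  expect_equal(igraph::ecount(empty), 0)
})

test_that("disjoint sources merge additively; malformed rows are reported", {
  lists <- list(data.frame(a = c("a", "b"), b = c("b", "c")),
                data.frame(a = "x", b = "y"),
                data.frame(a = "p", b = "q"))
  g <- merge_networks(lists, normalize_ids = FALSE)
  expect_equal(igraph::ecount(g), 4)
  expect_error(merge_networks(data.frame(a = c("a", ""), b = c("b", "c"))),
               "line")
})

test_that("identifier normalization merges case/version variants and is reported by degree", {
  g <- merge_networks(data.frame(a = c("At1g01010.1", "AT1G01010"),
                                 b = c("AT2G02020", "at2g02020.2")))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
})

test_that("ID follows the shared-partner formula with eligibility flags", {
  g <- network_from_partner_sets("A", "B", c("w", "x", "y", "z"), c("y", "z"))
  rec <- compute_id("A", "B", g)
  expect_equal(rec$i1, 4L); expect_equal(rec$i2, 2L); expect_equal(rec$i12, 2L)
  expect_equal(rec$id_value, 1 - 2 * 2 / (4 + 2))
  expect_true(rec$eligible)
  same <- network_from_partner_sets("A", "B", c("x", "y"), c("x", "y"))
  expect_equal(compute_id("A", "B", same)$id_value, 0)
  disjoint <- network_from_partner_sets("A", "B", c("x", "y"), c("u", "v"))
  expect_equal(compute_id("A", "B", disjoint)$id_value, 1)
  expect_false(compute_id("A", "B", disjoint)$eligible)  # max degree 2 < 4
  off <- compute_id("A", "Z", g)
  expect_true(is.na(off$id_value)); expect_false(off$eligible)
})

test_that("mutually interacting paralogs do not count as shared partners by default", {
  edges <- data.frame(a = c("A", "A", "B"), b = c("B", "x", "x"))
  g <- merge_networks(edges, normalize_ids = FALSE)
  rec <- compute_id("A", "B", g)
  expect_equal(rec$i12, 1L)          # only x; the A-B edge is excluded
  expect_equal(rec$i1, 1L)
  inc <- compute_id("A", "B", g, exclude_paralog = FALSE)
  expect_equal(inc$i1, 2L)           # B counts as A's partner
  expect_equal(inc$i12, 1L)          # shared set still only x
})

test_that("ID equals 1 - Dice on random partner sets; symmetric and bounded", {
  set.seed(7)
  universe <- sprintf("p%03d", 1:60)
  for (rep in 1:200) {
    pa <- sample(universe, sample(1:12, 1))
    pb <- sample(universe, sample(1:12, 1))
    g <- network_from_partner_sets("A", "B", pa, pb)
    rec <- compute_id("A", "B", g)
    expect_equal(rec$id_value, 1 - dice_oracle(pa, pb), tolerance = 1e-12)
    expect_equal(compute_id("B", "A", g)$id_value, rec$id_value)
    expect_gte(rec$id_value, 0); expect_lte(rec$id_value, 1)
    expect_lte(rec$i12, min(rec$i1, rec$i2))
  }
})

test_that("the eligibility sweep is monotone and matches a brute-force recount", {
  d <- generate_dataset(tiny_config(seed = 23))
  g <- merge_networks(d$ppi, normalize_ids = FALSE)
  sweep <- sweep_id_cutoffs(d$catalog, g, cutoffs = 1:14)
  expect_true(all(diff(sweep$n_eligible) <= 0))
  # brute force at k = 4 over all pairs
  brute <- sum(vapply(seq_len(nrow(d$catalog)), function(i) {
    r <- compute_id(d$catalog$gene_a[i], d$catalog$gene_b[i], g)
    isTRUE(r$eligible)
  }, logical(1)))
  expect_equal(sweep$n_eligible[sweep$cutoff == 4], brute)
  # a cutoff beyond the maximum degree leaves nothing eligible
  over <- sweep_id_cutoffs(d$catalog, g,
                           cutoffs = max(igraph::degree(g)) + 1L)
  expect_equal(over$n_eligible, 0L)
})

test_that("family projection transfers reference PPI status", {
  families <- data.frame(
    family_id = c("F1", "F1", "F1", "F2", "F2"),
    species = c("ath", "sly", "zma", "ath", "sly"),
    gene_id = c("a1", "s1", "z1", "a2", "s2"), stringsAsFactors = FALSE)
  g <- merge_networks(data.frame(a = "a1", b = c("p1", "p2", "p3")),
                      normalize_ids = FALSE)
  proj <- project_ppi_status(families, g, "ath")
  expect_equal(proj$ppi_status[proj$gene_id == "s1"], "with")
  expect_equal(proj$ppi_status[proj$gene_id == "z1"], "with")
  expect_equal(proj$ppi_status[proj$gene_id == "s2"], "without")
  expect_warning(
    orphan <- project_ppi_status(families, g, "ath", genes = c("s1", "sX")),
    "family table")
  expect_equal(orphan$ppi_status[orphan$gene_id == "sX"], "without")
  # empty reference network labels nothing with PPI
  g0 <- merge_networks(data.frame(a = character(), b = character()))
  proj0 <- project_ppi_status(families, g0, "ath")
  expect_true(all(proj0$ppi_status == "without"))
})

test_that("pair-level status is with-PPI iff at least one member is", {
  status <- data.frame(gene_id = c("a", "b", "c"),
                       ppi_status = c("with", "without", "without"))
  pairs <- data.frame(gene_a = c("a", "b", "x"), gene_b = c("b", "c", "y"))
  expect_equal(pair_ppi_status(pairs, status), c("with", "without", "without"))
})

test_that("partner-retention banding uses strict one-half and zero-shared bands", {
  recs <- data.frame(
    partition = c("block", "block", "tandem", "tandem"),
    i1 = c(4L, 4L, 4L, 5L), i2 = c(4L, 4L, 4L, 5L),
    i12 = c(4L, 2L, 0L, 0L),   # retentions 1, 0.5, 0, 0
    eligible = TRUE, stringsAsFactors = FALSE)
  out <- shared_partner_banding(recs)
  blk <- out$bands[out$bands$partition == "block", ]
  expect_equal(blk$frac_half_conserved, 0.5)  # retention exactly 0.5 excluded
  tnd <- out$bands[out$bands$partition == "tandem", ]
  expect_equal(tnd$frac_zero_shared, 1.0)
  expect_true(all(out$tests$p_value >= 0 & out$tests$p_value <= 1))
})

test_that("banding separates partitions with different latent ID", {
  set.seed(31)
  mk <- function(id_latent, n) {
    N <- pmax(4L, rpois(n, 8))
    s <- round((1 - id_latent) * N)
    data.frame(i1 = N, i2 = N, i12 = s, eligible = TRUE)
  }
  recs <- rbind(cbind(partition = "low_id", mk(0.2, 100)),
                cbind(partition = "high_id", mk(0.8, 100)))
  out <- shared_partner_banding(recs)
  expect_gt(out$bands$frac_half_conserved[out$bands$partition == "low_id"],
            out$bands$frac_half_conserved[out$bands$partition == "high_id"])
})

test_that("generator PPI degrees have mode-independent means", {
  d <- generate_dataset(generator_config(species = "ath",
                                         n_block_pairs = 250,
                                         n_tandem_pairs = 250,
                                         n_unclassified_pairs = 0,
                                         seed = 37))
  gt <- d$ground_truth$pairs
  deg <- gt$ppi_degree[!is.na(gt$ppi_degree)]
  mode <- gt$mode[!is.na(gt$ppi_degree)]
  p <- t.test(deg[mode == "block"], deg[mode == "tandem"])$p.value
  expect_gt(p, 1e-3)
})
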