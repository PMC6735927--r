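test_that("correlation panel handles linear and monotone relationships", {
  x <- seq(0.1, 2, length.out = 30)
  rec <- data.frame(ks = x, sd = 2 * x, ed = x^3)
  out <- correlation_panel(rec, c("ks", "sd", "ed"), ks_subsets = "ks<5")
  lin <- out[out$var_x == "ks" & out$var_y == "sd", ]
  expect_equal(lin$coefficient[lin$method == "pearson"], 1, tolerance = 1e-12)
  expect_equal(lin$coefficient[lin$method == "spearman"], 1, tolerance = 1e-12)
  cub <- out[out$var_x == "ks" & out$var_y == "ed", ]
  expect_equal(cub$coefficient[cub$method == "spearman"], 1, tolerance = 1e-12)
  expect_lt(cub$coefficient[cub$method == "pearson"], 1)
})

test_that("Spearman equals Pearson on rank-transformed data (no ties)", {
  set.seed(12)
  for (rep in 1:20) {
    x <- sample(seq(0.1, 4.9, by = 0.01), 40)
    y <- rnorm(40)
    rec <- data.frame(ks = x, sd = y)
    out <- correlation_panel(rec, c("ks", "sd"), ks_subsets = "ks<5")
    rho <- out$coefficient[out$method == "spearman"]
    expect_equal(rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("star bins follow the printed significance thresholds", {
  rec <- data.frame(p = c(1e-11, 1e-10, 1e-6, 1e-5, 0.04, 0.05, 0.5))
  bins <- dupdiverge:::star_bin(rec$p)
  expect_equal(bins, c("***", "**", "**", "*", "*", "ns", "ns"))
})

test_that("undersized cells are flagged not computed; partitions split correctly", {
  rec <- data.frame(ks = c(0.5, 0.7, 2, 3), sd = c(1, 2, 3, 4),
                    mode = c("t", "t", "b", "b"))
  out <- correlation_panel(rec, c("ks", "sd"), partition_col = "mode")
  young_t <- out[out$partition == "t" & out$ks_subset == "ks<1", ]
  expect_true(all(!young_t$computed))  # only 2 points under ks < 1
  expect_true(all(is.na(young_t$coefficient)))
  full <- out[out$ks_subset == "ks<5" & out$partition == "b", ]
  expect_true(all(!full$computed))     # 2 points in partition b
})

test_that("representation test matches the exact enumeration oracle", {
  counts <- rbind(cat1 = c(with = 10, without = 0),
                  cat2 = c(with = 0, without = 10))
  out <- representation_test(counts)
  p_exact <- 2 / choose(20, 10)  # only the two extreme tables are as extreme
  expect_equal(out$p_value, rep(p_exact, 2), tolerance = 1e-12)
  expect_equal(out$direction, c("over", "under"))
  # swapping rows flips direction, same p
  swapped <- representation_test(counts[2:1, ])
  expect_equal(swapped$p_value, out$p_value[2:1])
  expect_equal(swapped$direction, c("under", "over"))
  flat <- representation_test(rbind(a = c(with = 5, without = 5),
                                    b = c(with = 5, without = 5)))
  expect_equal(flat$p_value, c(1, 1))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  background <- sprintf("g%02d", 1:10)
  ann <- data.frame(gene_id = background[1:5], term_id = "T")
  out <- go_enrichment(background[1:4], background, ann)
  # P(X >= 4) with K = 5, N = 10, n = 4: only k = 4 possible
  expect_equal(out$p_over, choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-12)
  expect_equal(out$direction, "over")
  # a term annotating every background gene is uninformative
  ann_all <- data.frame(gene_id = background, term_id = "ALL")
  out_all <- go_enrichment(background[1:4], background, ann_all)
  expect_equal(out_all$p_over, 1, tolerance = 1e-12)
  expect_equal(out_all$p_under, 1, tolerance = 1e-12)
  expect_error(go_enrichment("g01", character(), ann), "background")
  expect_error(go_enrichment("zz", background, ann), "subset")
})

test_that("hypergeometric tails agree with brute-force enumeration on small tables", {
  for (N in c(8, 12, 20)) for (K in c(2, N %/% 2)) for (n in c(3, N %/% 2)) {
    background <- sprintf("g%03d", 1:N)
    ann <- data.frame(gene_id = background[seq_len(K)], term_id = "T")
    gene_set <- background[seq_len(n)]
    out <- go_enrichment(gene_set, background, ann)
    k <- out$k
    enum_over <- sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
    enum_under <- sum(vapply(0:k, function(i)
      choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
    expect_equal(out$p_over, enum_over, tolerance = 1e-12)
    expect_equal(out$p_under, enum_under, tolerance = 1e-12)
  }
})

test_that("BH correction reproduces the step-up hand example and is order-invariant", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  set.seed(13)
  p <- runif(20)
  idx <- sample.int(20)
  expect_equal(bh_correct(p)[idx], bh_correct(p[idx]))
  expect_true(all(bh_correct(p) >= p))
})

test_that("generator GO bias is recovered by enrichment on block duplicates", {
  d <- generate_dataset(generator_config(species = "ath",
                                         n_block_pairs = 250,
                                         n_tandem_pairs = 250,
                                         n_unclassified_pairs = 0,
                                         seed = 53))
  gt <- d$ground_truth$pairs
  block_genes <- c(gt$gene_a[gt$mode == "block"], gt$gene_b[gt$mode == "block"])
  background <- c(gt$gene_a, gt$gene_b)
  out <- go_enrichment(block_genes, background, d$go)
  biased <- default_go_terms()
  block_terms <- biased$term[biased$partition == "block"]
  hits <- out[out$term_id %in% block_terms, ]
  expect_true(all(hits$direction == "over"))
  expect_true(all(hits$q_value < 0.05))
  neutral <- out[out$term_id %in% biased$term[biased$partition == "none"], ]
  expect_true(mean(neutral$q_value < 0.05) <= 0.5)
})
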