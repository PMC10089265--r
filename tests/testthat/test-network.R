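test_that("prevalence filter applies the strictly-more-than rule", {
  m <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10),
                                        c("f7", "f9", "f0")))
  m[8:10, "f7"] <- 0   # present in 7/10
  m[10, "f9"] <- 0     # present in 9/10
  m[, "f0"] <- 0; m[1, "f0"] <- 1
  ft <- feature_table(m, "otu", "reads")
  kept <- prevalence_filter(ft, 0.8)
  expect_identical(colnames(kept), "f9")
  all_kept <- prevalence_filter(ft, 1e-9)
  expect_setequal(colnames(all_kept), c("f7", "f9", "f0"))
  m2 <- m; m2[, ] <- 0
  expect_error(prevalence_filter(feature_table(m2, "otu", "reads"), 0.8),
               class = "invanet_empty_result")
})

test_that("Spearman matrix matches rank arithmetic and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  feats <- cbind(a = x, b = y, c = 2 * x, d = -x)
  cm <- correlation_matrix(feats)
  # hand rank computation: sum d^2 = 4 -> rho = 1 - 24/120
  expect_equal(cm$rho["a", "b"], 0.8, tolerance = 1e-12)
  expect_equal(cm$rho["a", "c"], 1)
  expect_equal(cm$rho["a", "d"], -1)
  expect_equal(cm$p["a", "c"], 0)
  o <- spearman_oracle(x, y)
  expect_equal(cm$rho["a", "b"], o$rho, tolerance = 1e-12)
  expect_equal(cm$p["a", "b"], o$p, tolerance = 1e-12)

  set.seed(31)
  f2 <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, letters[1:4]))
  cm2 <- correlation_matrix(f2)
  for (i in 1:3) for (j in (i + 1):4) {
    o <- spearman_oracle(f2[, i], f2[, j])
    expect_equal(cm2$rho[i, j], o$rho, tolerance = 1e-12)
    expect_equal(cm2$p[i, j], o$p, tolerance = 1e-10)
  }

  f3 <- cbind(f2, const = 1)
  expect_warning(cm3 <- correlation_matrix(f3), "zero-variance")
  expect_false("const" %in% colnames(cm3$rho))
  expect_error(correlation_matrix(f2[1:4, ]),
               class = "invanet_invalid_argument")
})

test_that("edge selection equals an independent all-pairs filter", {
  res <- generate_dataset(synth_config(n_sites = 11, n_otus = 60, seed = 17))
  d <- res$dataset
  samp <- rownames(d$otus)
  grp <- d$metadata$group[match(samp, d$metadata$sample_id)]
  rows <- samp[grp == "AP"]
  q <- quantify(d$ct, d$panel, d$abs_16s)
  otus_g <- feature_table(unclass(d$otus)[rows, ], "otu", "reads")
  genes_g <- feature_table(q$absolute[rows, 1:25], "gene", "copies_per_gram")
  cfg <- network_config(preset = "fmen")
  net <- build_network(otus_g, genes_g, cfg)

  # oracle: prevalence by hand, cor.test per pair, BH from scratch
  ov <- unclass(otus_g)[, ]
  ov <- ov / rowSums(ov)  # relative abundance over the full community
  ov <- ov[, colSums(ov > 0) > 0.8 * nrow(ov), drop = FALSE]
  gv <- unclass(genes_g)[, ]
  gv <- gv[, colSums(gv > 0) > 0.8 * nrow(gv), drop = FALSE]
  feats <- cbind(ov, gv)
  pairs <- t(combn(ncol(feats), 2))
  rho <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    o <- spearman_oracle(feats[, pairs[k, 1]], feats[, pairs[k, 2]])
    rho[k] <- o$rho; p[k] <- o$p
  }
  q_adj <- bh_oracle(p)
  sel <- q_adj < cfg$alpha & abs(rho) > cfg$r_min
  want <- sort(paste(pmin(colnames(feats)[pairs[sel, 1]],
                          colnames(feats)[pairs[sel, 2]]),
                     pmax(colnames(feats)[pairs[sel, 1]],
                          colnames(feats)[pairs[sel, 2]])))
  got <- sort(paste(pmin(net$edges$from, net$edges$to),
                    pmax(net$edges$from, net$edges$to)))
  expect_identical(got, want)
  expect_true(all(net$edges$sign == ifelse(net$edges$rho >= 0,
                                           "positive", "negative")))
})

test_that("BH adjustment matches a from-scratch implementation", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("null data yields almost no edges under BH control", {
  n_edges <- vapply(1:200, function(s) {
    set.seed(s)
    m <- matrix(rexp(20 * 30), 20, 30,
                dimnames = list(paste0("s", 1:20), paste0("f", 1:30)))
    ft <- feature_table(m, "gene", "copies_per_gram")
    net <- build_network(genes = ft,
                         config = network_config(preset = "fmen"))
    nrow(net$edges)
  }, numeric(1))
  # among 435 independent pairs the edge count must stay far below the
  # alpha fraction of true nulls
  expect_lt(mean(n_edges), 0.05 * choose(30, 2))
  expect_lt(mean(n_edges), 1)
})

test_that("topology matches closed forms on canonical graphs", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  t_tri <- topology(net_from_adj(tri))
  expect_equal(t_tri$average_degree, 2)
  expect_equal(t_tri$transitivity, 1)
  expect_equal(t_tri$diameter, 1)
  expect_equal(t_tri$average_distance, 1)
  expect_equal(t_tri$average_clustering, 1)

  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1; path4 <- path4 + t(path4)
  t_p4 <- topology(net_from_adj(path4))
  expect_equal(t_p4$average_degree, 1.5)
  expect_equal(t_p4$transitivity, 0)
  expect_equal(t_p4$diameter, 3)
  o <- topology_oracle(path4)
  expect_equal(t_p4$average_distance, o$average_distance)
})

test_that("topology agrees with the brute-force oracle on random graphs", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, runif(1, 0.2, 0.7))
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    t_pkg <- topology(net_from_adj(adj))
    o <- topology_oracle(adj)
    expect_equal(t_pkg$n_edges, o$n_edges)
    expect_equal(t_pkg$average_degree, o$average_degree)
    expect_equal(t_pkg$average_clustering, o$average_clustering,
                 tolerance = 1e-12)
    expect_equal(t_pkg$transitivity, o$transitivity, tolerance = 1e-12)
    expect_equal(t_pkg$average_distance, o$average_distance,
                 tolerance = 1e-12)
    expect_equal(t_pkg$diameter, o$diameter)
    expect_equal(t_pkg$component_count, o$component_count)
    # degree sum identity
    deg <- table(c(net_from_adj(adj)$edges$from, net_from_adj(adj)$edges$to))
    expect_equal(sum(deg), 2 * t_pkg$n_edges)
  }
})

test_that("keystones are the top-degree OTU nodes with documented tie-breaks", {
  # star: hub OTU connected to 5 genes
  adj <- matrix(0, 6, 6); adj[1, 2:6] <- 1; adj <- adj + t(adj)
  rownames(adj) <- colnames(adj) <- c("OTU_hub", paste0("g", 1:5))
  net <- net_from_adj(adj, kind = c("otu", rep("gene", 5)))
  ks <- suppressWarnings(keystone_taxa(net, k = 5))
  expect_identical(ks$keystone[1], "OTU_hub")
  expect_equal(ks$degree[1], 5L)

  # degree tie broken by mean abundance, then id
  nodes <- data.frame(id = c("OTU_a", "OTU_b", "OTU_c", "g1"),
                      kind = c("otu", "otu", "otu", "gene"),
                      mean_abundance = c(0.01, 0.02, 0.02, 0.5))
  edges <- data.frame(from = c("OTU_a", "OTU_b", "OTU_c"),
                      to = c("g1", "g1", "g1"),
                      rho = 0.9, p_raw = 1e-5, q = 1e-4, sign = "positive")
  net2 <- eco_network(nodes, edges)
  ks2 <- keystone_taxa(net2, k = 2)
  expect_identical(ks2$keystone, c("OTU_b", "OTU_c"))  # 0.02 ties: id order

  expect_warning(ks3 <- keystone_taxa(net2, k = 5), "only 3 OTU nodes")
  expect_equal(nrow(ks3), 3)

  net_genes <- net_from_adj(adj[2:6, 2:6] + 0, kind = rep("gene", 5))
  expect_error(keystone_taxa(net_genes), class = "invanet_invalid_argument")
})

test_that("network invariants hold on the network container", {
  nodes <- data.frame(id = c("a", "b"), kind = "otu", mean_abundance = 0.1)
  bad_sign <- data.frame(from = "a", to = "b", rho = -0.7, p_raw = 1e-3,
                         q = 1e-2, sign = "positive")
  expect_error(eco_network(nodes, bad_sign), class = "invanet_invalid_table")
  loop <- data.frame(from = "a", to = "a", rho = 0.7, p_raw = 1e-3,
                     q = 1e-2, sign = "positive")
  expect_error(eco_network(nodes, loop), class = "invanet_invalid_table")
})
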