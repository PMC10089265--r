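make_counts <- function(m, samples = NULL, otus = NULL) {
  samples <- samples %||% paste0("s", seq_len(nrow(m)))
  otus <- otus %||% paste0("OTU_", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  feature_table(m, kind = "otu", units = "reads")
}

test_that("rarefaction conserves depth, drops shallow samples, needs a seed", {
  ft <- make_counts(rbind(c(5, 3), c(60, 40), c(2, 1)))
  expect_warning(out <- rarefy(ft, depth = 8, seed = 1), "dropped 1")
  expect_equal(unname(rowSums(out)), c(8, 8))
  expect_false("s3" %in% rownames(out))
  # depth equal to a sample's total leaves it unchanged
  expect_equal(unclass(out)["s1", ], c(OTU_1 = 5, OTU_2 = 3))
  expect_error(rarefy(ft, depth = 8), class = "invanet_invalid_argument")

  big <- make_counts(matrix(rpois(200, 20), 4, 50))
  r1 <- rarefy(big, depth = 500, seed = 1)
  r2 <- rarefy(big, depth = 500, seed = 2)
  expect_equal(unname(rowSums(r1)), rep(500, 4))
  expect_equal(unname(rowSums(r2)), rep(500, 4))
  expect_false(identical(unclass(r1)[, ], unclass(r2)[, ]))  # different draws
  expect_identical(unclass(rarefy(big, depth = 500, seed = 1))[, ],
                   unclass(r1)[, ])                          # same seed, same draw
})

test_that("alpha diversity matches closed forms on tiny communities", {
  ft <- make_counts(rbind(c(10, 0, 0), c(5, 5, 0), c(1, 1, 2)))
  a <- alpha_diversity(ft)
  expect_equal(a$richness, c(1, 2, 3))
  expect_equal(a$shannon[1], 0)
  expect_equal(a$simpson[1], 0)
  expect_equal(a$shannon[2], log(2))
  expect_equal(a$simpson[2], 0.5)
  # bias-corrected Chao1: S + F1(F1-1)/(2(F2+1)) = 3 + 2*1/4
  expect_equal(a$chao1[3], 3.5)
  inv <- alpha_diversity(ft, simpson = "inverse")
  expect_equal(inv$simpson[2], 2)
})

test_that("all-zero samples are flagged, not silently zero", {
  ft <- make_counts(rbind(c(3, 2), c(0, 0)))
  expect_warning(a <- alpha_diversity(ft), "all-zero")
  expect_true(is.na(a$shannon[2]))
  expect_true(is.na(a$richness[2]))
})

test_that("chao1 and ace dominate observed richness on random tables", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rpois(8 * 40, lambda = sample(1:4, 1)), 8, 40)
    m[1, ] <- m[1, ] + 1  # avoid empty samples
    a <- alpha_diversity(make_counts(m))
    ok <- !is.na(a$richness)
    expect_true(all(a$chao1[ok] >= a$richness[ok] - 1e-9))
    expect_true(all(a$ace[ok] >= a$richness[ok] - 1e-9))
  }
})

test_that("Bray-Curtis matches its closed form and bounds", {
  ft <- make_counts(rbind(c(1, 2), c(3, 0), c(1, 2), c(0, 5)))
  d <- bray_curtis(ft)
  expect_equal(d["s1", "s2"], 4 / 6, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s2", "s4"], 1)  # disjoint supports
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  zero <- make_counts(rbind(c(1, 2), c(0, 0)))
  expect_error(bray_curtis(zero), class = "invanet_invalid_table")
})

test_that("PCoA embeds distances faithfully", {
  # all pairwise distances 1: an equilateral triangle, two equal eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa(d3)
  emb <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(emb[upper.tri(emb)]), rep(1, 3), tolerance = 1e-9)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # Euclidean inputs are reproduced exactly
  set.seed(11)
  x <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("s", 1:6), NULL))
  de <- as.matrix(dist(x))
  orde <- pcoa(de)
  expect_equal(as.matrix(dist(orde$coordinates)), de, tolerance = 1e-9)

  # a duplicated sample lands on coincident coordinates
  dd <- as.matrix(dist(x[c(1, 1, 2, 3), ]))
  dimnames(dd) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ordd <- pcoa(dd)
  expect_equal(ordd$coordinates[1, ], ordd$coordinates[2, ], tolerance = 1e-9)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)),
               class = "invanet_invalid_argument")
})

test_that("ANOSIM attains its closed-form extremes", {
  # two tight clusters far apart: R = 1
  x <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 50, 0.01), 5))
  rownames(x) <- paste0("s", 1:10)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 5)
  expect_equal(anosim(d, g, n_permutations = 99, seed = 1)$statistic, 1)
  # all distances equal: R = 0
  d0 <- matrix(1, 6, 6) - diag(6)
  expect_equal(anosim(d0, rep(c("a", "b"), 3), n_permutations = 99,
                      seed = 1)$statistic, 0)
  expect_error(anosim(d0, c("a", rep("b", 5))),
               class = "invanet_invalid_argument")
})

test_that("ANOSIM agrees with an exhaustive relabeling oracle at n = 4", {
  set.seed(23)
  x <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  d <- as.matrix(dist(x))
  g <- c("a", "a", "b", "b")
  # oracle: R over all 6 balanced label assignments, exact p
  rank_d <- rank(d[lower.tri(d)])
  pi_ <- row(d)[lower.tri(d)]; pj <- col(d)[lower.tri(d)]
  r_of <- function(lab) {
    between <- lab[pi_] != lab[pj]
    m <- length(rank_d)
    (mean(rank_d[between]) - mean(rank_d[!between])) / (m / 2)
  }
  combos <- combn(4, 2)
  r_all <- apply(combos, 2, function(idx) {
    lab <- rep("b", 4); lab[idx] <- "a"; r_of(lab)
  })
  r_obs <- r_of(g)
  p_exact <- mean(r_all >= r_obs)
  res <- anosim(d, g, n_permutations = 1999, seed = 4)
  expect_equal(res$statistic, r_obs, tolerance = 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.05)
})

test_that("ANOSIM R statistic matches vegan on a generated dataset", {
  res <- generate_dataset(synth_config(n_sites = 6, n_otus = 60,
                                       group_effect = 1.5, seed = 13))
  d <- res$dataset
  rare <- rarefy(d$otus, seed = 2)
  dm <- bray_curtis(rare)
  grp <- d$metadata$group[match(rownames(rare), d$metadata$sample_id)]
  ours <- anosim(dm, grp, n_permutations = 499, seed = 3)
  ref <- vegan::anosim(as.dist(dm), grouping = factor(grp), permutations = 499)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_gte(ours$p_value, 1 / 500)
})

test_that("Kruskal-Wallis screen reproduces hand-computed H and honours ranks", {
  ft <- make_counts(rbind(c(1, 9), c(2, 8), c(3, 7), c(4, 6), c(5, 5),
                          c(6, 4)))
  # relative abundance of OTU_1 is 0.1..0.6: groups {.1,.2,.3} vs {.4,.5,.6}
  g <- rep(c("A", "B"), each = 3)
  out <- kruskal_wallis_screen(ft, g)
  h1 <- out$H[out$taxon == "OTU_1"]
  expect_equal(h1, 3.857143, tolerance = 1e-6)

  # identical distributions: H = 0, p = 1
  ft2 <- make_counts(matrix(c(2, 2, 2, 2, 6, 6, 6, 6), 4, 2))
  out2 <- kruskal_wallis_screen(ft2, c("A", "A", "B", "B"))
  expect_equal(out2$H, c(0, 0))
  expect_equal(out2$p_value, c(1, 1))

  # collapsing to an absent rank fails loudly
  tax <- data.frame(otu_id = c("OTU_1", "OTU_2"), phylum = c("P1", "P2"))
  expect_error(kruskal_wallis_screen(ft, g, taxonomy = tax, rank = "family"),
               class = "invanet_invalid_argument")

  # top_n keeps the most abundant taxa
  out3 <- kruskal_wallis_screen(ft, g, top_n = 1)
  expect_equal(nrow(out3), 1)
})

test_that("planted phylum shifts are detected at the phylum rank", {
  hits <- vapply(1:10, function(s) {
    res <- generate_dataset(synth_config(n_sites = 11, n_otus = 150, seed = s))
    d <- res$dataset
    grp <- d$metadata$group[match(rownames(d$otus), d$metadata$sample_id)]
    out <- kruskal_wallis_screen(d$otus, grp, taxonomy = d$taxonomy,
                                 rank = "phylum", top_n = 10)
    row <- out[out$taxon == "Bacteroidetes", ]
    nrow(row) == 1 && row$p_value < 0.05 && row$median_AP > row$median_N
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
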