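# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Benjamini-Hochberg from the definition: q_(i) = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Spearman rho from mid-ranks and the Pearson formula, p from the
# t approximation.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), n - 2))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Full topology oracle from first principles (no igraph).
topology_oracle <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  n_edges <- sum(adj) / 2
  # triangles and local clustering
  tri_at <- numeric(n)
  local_cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k >= 2) {
      links <- sum(adj[nb, nb]) / 2
      tri_at[v] <- links
      local_cc[v] <- links / (k * (k - 1) / 2)
    }
  }
  triangles <- sum(tri_at) / 3
  triads <- sum(deg * (deg - 1) / 2)
  d <- floyd_warshall(adj)
  # connected components from reachability
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1L
      comp[is.finite(d[v, ])] <- cid
    }
  }
  giant <- which(comp == which.max(tabulate(comp)))
  dg <- d[giant, giant, drop = FALSE]
  finite_off <- dg[upper.tri(dg)]
  list(
    n_nodes = n,
    n_edges = n_edges,
    average_degree = 2 * n_edges / n,
    average_clustering = mean(local_cc),
    transitivity = if (triads > 0) 3 * triangles / triads else 0,
    average_distance = if (length(finite_off)) mean(finite_off) else NA_real_,
    diameter = if (length(finite_off)) max(finite_off) else NA_real_,
    component_count = max(comp)
  )
}

# Build an eco_network directly from an adjacency matrix (for topology and
# keystone unit tests).
net_from_adj <- function(adj, kind = NULL, abundance = NULL) {
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  kind <- kind %||% rep("otu", n)
  abundance <- abundance %||% rep(1 / n, n)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    rho = rep(0.9, nrow(idx)), p_raw = rep(1e-4, nrow(idx)),
    q = rep(1e-3, nrow(idx)), sign = rep("positive", nrow(idx)),
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(id = ids, kind = kind, mean_abundance = abundance,
                      stringsAsFactors = FALSE)
  eco_network(nodes, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal valid dataset written to TSV files; returns the path list.
write_tiny_dataset <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- matrix(c(5, 3, 1, 2, 4, 6), nrow = 3,
                   dimnames = list(c("s1", "s2", "s3"), c("OTU_1", "OTU_2")))
  ft <- feature_table(counts, kind = "otu", units = "reads")
  panel <- qmec_panel()
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    site_id = c("a", "a", "b"),
    group = c("AP", "N", "AP"),
    lon = c(116.5, 116.5, 117.0), lat = c(39.0, 39.0, 39.5),
    pH = 8, TC = 15, TN = 1.2, TP = 0.8, AN = 8, NN = 10, AP_P = 12
  )
  tax <- data.frame(otu_id = c("OTU_1", "OTU_2"),
                    phylum = c("Proteobacteria", "Bacteroidetes"),
                    class = "unclassified", order = "unclassified",
                    family = "unclassified", genus = "unclassified",
                    species = "unclassified")
  ct <- matrix(c(25, 26, 27, 20, 20, 20), nrow = 3,
               dimnames = list(c("s1", "s2", "s3"), c("nifH", "16S_rRNA")))
  paths <- list(otus = file.path(dir, "otus.tsv"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                ct = file.path(dir, "ct.tsv"),
                panel = file.path(dir, "panel.tsv"))
  write_feature_table(ft, paths$otus)
  write_taxonomy(tax, paths$taxonomy)
  write_metadata(meta, paths$metadata)
  write_ct_table(ct, paths$ct)
  write_panel(panel, paths$panel)
  paths
}
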