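#' Construct an ecological co-occurrence network
#'
#' Container for a correlation network over OTUs and/or functional genes.
#' Nodes carry their kind and mean relative abundance; edges carry the
#' Spearman correlation, raw and FDR-adjusted p-values, and the correlation
#' sign.
#'
#' @param nodes data.frame: `id`, `kind` (`"otu"`/`"gene"`),
#'   `mean_abundance`.
#' @param edges data.frame: `from`, `to`, `rho`, `p_raw`, `q`, `sign`.
#' @return an `eco_network`.
#' @export
eco_network <- function(nodes, edges) {
  stopifnot(all(c("id", "kind", "mean_abundance") %in% names(nodes)))
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), p_raw = numeric(), q = numeric(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to", "rho", "p_raw", "q", "sign") %in% names(edges)))
  if (anyDuplicated(nodes$id)) {
    invanet_error("invanet_duplicate_id", "duplicate node ids")
  }
  if (!all(nodes$kind %in% c("otu", "gene"))) {
    invanet_error("invanet_invalid_table", "node kind must be 'otu' or 'gene'")
  }
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) {
      invanet_error("invanet_invalid_table", "self-loops are not allowed")
    }
    unknown <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(unknown)) {
      invanet_error("invanet_invalid_table", sprintf(
        "edge endpoints missing from node table: %s",
        paste(unknown, collapse = ", ")
      ))
    }
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) {
      invanet_error("invanet_invalid_table", "duplicate (undirected) edges")
    }
    if (!all(edges$sign == ifelse(edges$rho >= 0, "positive", "negative"))) {
      invanet_error("invanet_invalid_table", "edge sign must match sign(rho)")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "eco_network")
}

#' @export
print.eco_network <- function(x, ...) {
  cat(sprintf("<eco_network> %d nodes (%d otu, %d gene), %d edges (%d+, %d-)\n",
              nrow(x$nodes), sum(x$nodes$kind == "otu"),
              sum(x$nodes$kind == "gene"), nrow(x$edges),
              sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Network construction configuration
#'
#' Thresholds for [build_network()]. The two presets mirror the study's
#' conventions: `"fmen"` (functional molecular ecological network, OTUs +
#' genes; correlation threshold 0.6) and `"genenet"` (gene-gene network,
#' threshold 0.8).
#'
#' @param prevalence_min features must be present in strictly more than this
#'   fraction of samples.
#' @param r_min edges require `|rho|` strictly greater than this.
#' @param p_adjust `"bh_fdr"` (one BH family per network build) or
#'   `"none"`.
#' @param alpha edges require (adjusted) p strictly below this.
#' @param pair_types which feature pairs are tested: any of `"otu-otu"`,
#'   `"otu-gene"`, `"gene-gene"`.
#' @param preset `"fmen"` or `"genenet"`; sets `r_min` accordingly.
#' @return a `network_config` list.
#' @export
network_config <- function(prevalence_min = 0.8, r_min = NULL,
                           p_adjust = c("bh_fdr", "none"), alpha = 0.05,
                           pair_types = c("otu-otu", "otu-gene", "gene-gene"),
                           preset = c("fmen", "genenet")) {
  preset <- match.arg(preset)
  p_adjust <- match.arg(p_adjust)
  r_min <- r_min %||% if (preset == "fmen") 0.6 else 0.8
  if (prevalence_min <= 0 || prevalence_min > 1) {
    invanet_error("invanet_invalid_config", "prevalence_min must lie in (0, 1]")
  }
  if (r_min <= 0 || r_min >= 1) {
    invanet_error("invanet_invalid_config", "r_min must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) {
    invanet_error("invanet_invalid_config", "alpha must lie in (0, 1)")
  }
  bad <- setdiff(pair_types, c("otu-otu", "otu-gene", "gene-gene"))
  if (length(bad)) {
    invanet_error("invanet_invalid_config",
                  sprintf("unknown pair types: %s", paste(bad, collapse = ", ")))
  }
  structure(list(prevalence_min = prevalence_min, r_min = r_min,
                 p_adjust = p_adjust, alpha = alpha,
                 pair_types = pair_types, preset = preset),
            class = "network_config")
}

#' Prevalence filter
#'
#' Keeps features with a nonzero value in strictly more than
#' `prevalence_min` of the samples ("present in more than 80% of all
#' samples" at the default).
#'
#' @param table a [feature_table()].
#' @param prevalence_min fraction in `[0, 1)`.
#' @return the filtered [feature_table()].
#' @export
prevalence_filter <- function(table, prevalence_min = 0.8) {
  x <- ft_values(table)
  prev <- colSums(x > 0)
  keep <- prev > prevalence_min * nrow(x)
  if (!any(keep)) {
    invanet_error("invanet_empty_result",
                  "no features pass the prevalence filter; lower prevalence_min")
  }
  feature_table(x[, keep, drop = FALSE], kind = ft_kind(table),
                units = ft_units(table))
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rho (mid-ranks for ties) with two-sided p-values from
#' the t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on `n - 2`
#' degrees of freedom; perfect correlations get p = 0. Zero-variance
#' features have undefined rank correlation and are excluded with a warning.
#'
#' @param features samples x features numeric matrix (>= 5 samples).
#' @return list: `rho` and `p` matrices over the retained features.
#' @export
correlation_matrix <- function(features) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 5) {
    invanet_error("invanet_invalid_argument", "need at least 5 samples for correlation")
  }
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning(sprintf("correlation_matrix: excluded %d zero-variance feature(s): %s",
                    sum(const), paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  rho <- stats::cor(x, method = "spearman")
  r <- pmin(pmax(rho, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(rho) <- 1
  diag(p) <- 0
  list(rho = rho, p = p)
}

#' Build a co-occurrence network
#'
#' Applies the prevalence filter to each input table, normalises OTU counts
#' to relative abundance (gene tables are used on their given scale),
#' computes the Spearman correlation matrix over the combined features,
#' Benjamini-Hochberg-adjusts the p-values of all tested pairs as one
#' family, and keeps an edge when the adjusted p is strictly below `alpha`
#' and `|rho|` strictly above `r_min`. Only nodes incident to at least one
#' edge are retained in the network.
#'
#' @param otus optional OTU [feature_table()] (counts or relative).
#' @param genes optional gene [feature_table()] (absolute copies).
#' @param config a [network_config()].
#' @return an [eco_network()].
#' @export
build_network <- function(otus = NULL, genes = NULL,
                          config = network_config()) {
  if (is.null(otus) && is.null(genes)) {
    invanet_error("invanet_invalid_argument", "supply at least one feature table")
  }
  if (!is.null(otus) && !is.null(genes) &&
      !identical(rownames(otus), rownames(genes))) {
    invanet_error("invanet_sample_mismatch",
                  "OTU and gene tables must share an identical sample set (same order)")
  }
  blocks <- list()
  if (!is.null(otus)) {
    ov <- ft_values(otus)
    # relative abundance w.r.t. the whole community, before filtering
    if (ft_units(otus) != "relative") ov <- ov / rowSums(ov)
    o <- prevalence_filter(feature_table(ov, "otu", "relative"),
                           config$prevalence_min)
    blocks$otu <- ft_values(o)
  }
  if (!is.null(genes)) {
    g <- prevalence_filter(genes, config$prevalence_min)
    blocks$gene <- ft_values(g)
  }
  kind <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  feat <- do.call(cbind, unname(blocks))
  dup <- colnames(feat)[duplicated(colnames(feat))]
  if (length(dup)) {
    invanet_error("invanet_duplicate_id", sprintf(
      "feature ids shared between tables: %s", paste(dup, collapse = ", ")
    ))
  }
  cm <- correlation_matrix(feat)
  keep_feat <- colnames(cm$rho)
  kind <- kind[match(keep_feat, colnames(feat))]
  mean_ab <- colMeans(feat[, keep_feat, drop = FALSE])

  m <- length(keep_feat)
  idx <- which(upper.tri(cm$rho), arr.ind = TRUE)
  k1 <- kind[idx[, 1]]
  k2 <- kind[idx[, 2]]
  type <- ifelse(k1 == k2, paste(k1, k2, sep = "-"), "otu-gene")
  tested <- type %in% config$pair_types
  idx <- idx[tested, , drop = FALSE]
  p_raw <- cm$p[idx]
  rho <- cm$rho[idx]
  q <- if (config$p_adjust == "bh_fdr") stats::p.adjust(p_raw, "BH") else p_raw
  sel <- q < config$alpha & abs(rho) > config$r_min
  edges <- data.frame(
    from = keep_feat[idx[sel, 1]],
    to = keep_feat[idx[sel, 2]],
    rho = rho[sel], p_raw = p_raw[sel], q = q[sel],
    sign = ifelse(rho[sel] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  used <- unique(c(edges$from, edges$to))
  nodes <- data.frame(id = keep_feat, kind = kind, mean_abundance = mean_ab,
                      row.names = NULL, stringsAsFactors = FALSE)
  nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  rownames(nodes) <- NULL
  eco_network(nodes, edges)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Topological summary of a network
#'
#' Reports the attributes conventionally tabulated for ecological networks:
#' node/edge counts, signed edge counts, average degree (2E/N), average
#' local clustering coefficient (nodes of degree < 2 contribute 0), global
#' transitivity (3 x triangles / connected triples), greedy-agglomeration
#' modularity Q, and the average shortest-path distance and diameter of the
#' largest connected component. Edgeless networks have undefined distances
#' (reported `NA`).
#'
#' @param net an [eco_network()].
#' @return a `topology_summary` list.
#' @export
topology <- function(net) {
  if (nrow(net$nodes) == 0) {
    invanet_error("invanet_invalid_argument", "empty network")
  }
  g <- as_igraph(net)
  n_nodes <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[!is.finite(local_cc)] <- 0
  trans <- igraph::transitivity(g, type = "global")
  if (!is.finite(trans)) trans <- 0
  comp <- igraph::components(g)
  if (n_edges > 0) {
    giant <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize))
    )
    avg_dist <- igraph::mean_distance(giant)
    diam <- igraph::diameter(giant)
    # greedy agglomerative modularity; deterministic for a given graph
    q_mod <- igraph::modularity(igraph::cluster_fast_greedy(g))
  } else {
    avg_dist <- NA_real_
    diam <- NA_real_
    q_mod <- NA_real_
  }
  structure(list(
    n_nodes = n_nodes,
    n_edges = n_edges,
    n_positive = sum(net$edges$sign == "positive"),
    n_negative = sum(net$edges$sign == "negative"),
    average_degree = 2 * n_edges / n_nodes,
    average_clustering = mean(local_cc),
    transitivity = trans,
    modularity = q_mod,
    average_distance = avg_dist,
    diameter = diam,
    component_count = comp$no
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("<topology_summary> %d nodes, %d edges (%d+/%d-), ",
                     "avg degree %.2f, transitivity %.3f, Q %.3f\n"),
              x$n_nodes, x$n_edges, x$n_positive, x$n_negative,
              x$average_degree, x$transitivity,
              ifelse(is.na(x$modularity), NaN, x$modularity)))
  invisible(x)
}

#' Keystone taxa by degree centrality
#'
#' The top `k` OTU nodes of a network ranked by degree. Ties are broken by
#' higher mean relative abundance, then lexicographic node id. If fewer
#' than `k` OTU nodes exist, all are returned with a warning.
#'
#' @param net an [eco_network()] containing OTU nodes.
#' @param k number of keystones (default 5).
#' @param taxonomy optional taxonomy data.frame; when given, the lineage
#'   columns are joined onto the result.
#' @return data.frame: keystone id, degree, mean relative abundance, and
#'   lineage if supplied, ordered by rank.
#' @export
keystone_taxa <- function(net, k = 5, taxonomy = NULL) {
  otu_nodes <- net$nodes[net$nodes$kind == "otu", , drop = FALSE]
  if (nrow(otu_nodes) == 0) {
    invanet_error("invanet_invalid_argument", "network has no OTU nodes")
  }
  deg <- table(c(net$edges$from, net$edges$to))
  otu_nodes$degree <- as.integer(deg[otu_nodes$id])
  otu_nodes$degree[is.na(otu_nodes$degree)] <- 0L
  ord <- order(-otu_nodes$degree, -otu_nodes$mean_abundance, otu_nodes$id)
  otu_nodes <- otu_nodes[ord, , drop = FALSE]
  if (nrow(otu_nodes) < k) {
    warning(sprintf("only %d OTU nodes available (k = %d); returning all",
                    nrow(otu_nodes), k))
    k <- nrow(otu_nodes)
  }
  out <- otu_nodes[seq_len(k), c("id", "degree", "mean_abundance")]
  names(out)[1] <- "keystone"
  if (!is.null(taxonomy)) {
    ranks <- setdiff(names(taxonomy), "otu_id")
    out <- cbind(out, taxonomy[match(out$keystone, taxonomy$otu_id), ranks,
                               drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
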