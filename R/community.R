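#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth.
#' Samples whose total falls below the depth are dropped with a warning.
#'
#' @param table a counts [feature_table()] (integer-valued).
#' @param depth target depth; defaults to the minimum sample total.
#' @param seed RNG seed (mandatory, so rarefaction is reproducible).
#' @return a rarefied [feature_table()].
#' @export
rarefy <- function(table, depth = NULL, seed) {
  x <- ft_values(table)
  if (any(x != round(x))) {
    invanet_error("invanet_invalid_table", "rarefaction requires integer counts")
  }
  if (missing(seed) || is.null(seed)) {
    invanet_error("invanet_invalid_argument", "rarefy requires an explicit seed")
  }
  totals <- rowSums(x)
  depth <- depth %||% min(totals)
  if (depth < 1) {
    invanet_error("invanet_invalid_argument", "depth must be >= 1")
  }
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf("rarefy: dropped %d sample(s) with fewer than %d reads: %s",
                    sum(!keep), depth,
                    paste(rownames(x)[!keep], collapse = ", ")))
  }
  x <- x[keep, , drop = FALSE]
  # integer counts are validated above; rrarefy's "smallest count" heuristic
  # misfires on small fixtures
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(x, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  feature_table(out, kind = ft_kind(table), units = "reads")
}

#' Alpha-diversity estimators
#'
#' Per sample: observed richness, bias-corrected Chao1
#' \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))}, the ACE estimator (rare-species
#' cutoff 10), Shannon entropy (natural log) and Simpson diversity. The
#' Simpson index is Gini-Simpson \eqn{1 - \sum p_i^2} by default; set
#' `simpson = "inverse"` for \eqn{1 / \sum p_i^2}.
#'
#' All-zero samples have undefined diversity and come back as `NA` with a
#' warning, never as silent zeros. Chao1/ACE need integer counts; when no
#' rare species (abundance <= 10) exist the ACE machinery has nothing to
#' extrapolate from and ACE equals observed richness.
#'
#' @param table a counts [feature_table()].
#' @param simpson `"gini"` (default) or `"inverse"`.
#' @return data.frame: sample_id, richness, chao1, ace, shannon, simpson.
#' @export
alpha_diversity <- function(table, simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  x <- ft_values(table)
  if (any(x != round(x))) {
    invanet_error("invanet_invalid_table", "alpha diversity estimators require integer counts")
  }
  empty <- rowSums(x) == 0
  if (any(empty)) {
    warning(sprintf("alpha_diversity: undefined for all-zero sample(s): %s",
                    paste(rownames(x)[empty], collapse = ", ")))
  }
  est <- suppressWarnings(vegan::estimateR(x))
  sh <- vegan::diversity(x, index = "shannon")
  si <- if (simpson == "gini") {
    vegan::diversity(x, index = "simpson")
  } else {
    vegan::diversity(x, index = "invsimpson")
  }
  richness <- est["S.obs", ]
  chao1 <- est["S.chao1", ]
  ace <- est["S.ACE", ]
  # no rare species => ACE degenerates; report observed richness
  ace[!is.finite(ace)] <- richness[!is.finite(ace)]
  out <- data.frame(sample_id = rownames(x), richness = richness,
                    chao1 = chao1, ace = ace, shannon = sh, simpson = si,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[empty, c("richness", "chao1", "ace", "shannon", "simpson")] <- NA_real_
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}: 0 for identical
#' samples, 1 for disjoint supports. Defined only when every sample has a
#' positive total.
#'
#' @param table a [feature_table()] (counts or relative abundances).
#' @return symmetric `dist`-backed matrix with sample ids, zero diagonal.
#' @export
bray_curtis <- function(table) {
  x <- ft_values(table)
  if (nrow(x) < 2) {
    invanet_error("invanet_invalid_argument", "need at least 2 samples")
  }
  if (any(rowSums(x) == 0)) {
    invanet_error("invanet_invalid_table", sprintf(
      "Bray-Curtis undefined for all-zero sample(s): %s",
      paste(rownames(x)[rowSums(x) == 0], collapse = ", ")
    ))
  }
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of \eqn{-d^2/2},
#' eigendecomposition, coordinates scaled by the square root of the
#' eigenvalues. Negative eigenvalues (Bray-Curtis is semi-metric) are
#' retained in the eigenvalue report but excluded from coordinates and from
#' the proportion of variance explained.
#'
#' @param dm symmetric distance matrix with sample ids.
#' @return list: `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, descending), `proportion_explained` (over positive eigenvalues).
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    invanet_error("invanet_invalid_argument", "distance matrix must be symmetric")
  }
  n <- nrow(dm)
  fit <- stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))
  coords <- fit$points[, seq_len(sum(pos[seq_len(ncol(fit$points))])),
                       drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  prop <- eig[eig > 0] / sum(eig[eig > 0])
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

# Mean between/within ranks over the distance vector; shared by the observed
# statistic and every permutation (ranks are computed once).
anosim_r <- function(rank_d, between) {
  m <- length(rank_d)
  (mean(rank_d[between]) - mean(rank_d[!between])) / (m / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a distance matrix.
#' All \eqn{M = n(n-1)/2} distances are ranked (mid-ranks for ties) and
#' \deqn{R = (\bar r_{between} - \bar r_{within}) / (M/2),}
#' so \eqn{R \in [-1, 1]} with 1 meaning every between-group distance
#' exceeds every within-group distance. Significance comes from permuting
#' group labels; the p-value uses the add-one convention
#' \eqn{p = (1 + \#\{R^* \ge R\}) / (1 + n_{perm})} and can therefore never
#' be zero.
#'
#' For paired or blocked designs, pass `strata` (e.g. the site id): labels
#' then permute only within each block. This matters for calibration: when
#' paired samples are correlated, the observed all-pairs-discordant
#' labeling of a paired survey is an extreme configuration among free
#' permutations and the unrestricted test loses its nominal level.
#'
#' @param dm symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations number of label permutations.
#' @param seed RNG seed for the permutations.
#' @param strata optional blocking factor, one value per sample.
#' @return list: `statistic` (R), `p_value`, `n_permutations`, `seed`.
#' @export
anosim <- function(dm, groups, n_permutations = 999, seed = NULL,
                   strata = NULL) {
  dm <- as.matrix(dm)
  groups <- as.character(groups)
  n <- nrow(dm)
  if (length(groups) != n) {
    invanet_error("invanet_invalid_argument", "one group label per sample required")
  }
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    invanet_error("invanet_invalid_argument", "ANOSIM needs >= 2 groups with >= 2 samples each")
  }
  shuffle <- if (is.null(strata)) {
    function() sample(groups)
  } else {
    if (length(strata) != n) {
      invanet_error("invanet_invalid_argument", "one stratum per sample required")
    }
    blocks <- split(seq_len(n), strata)
    function() {
      g <- groups
      for (b in blocks) g[b] <- g[b][sample.int(length(b))]
      g
    }
  }
  d_vec <- dm[lower.tri(dm)]
  rank_d <- rank(d_vec)
  pair_i <- row(dm)[lower.tri(dm)]
  pair_j <- col(dm)[lower.tri(dm)]
  between <- groups[pair_i] != groups[pair_j]
  r_obs <- anosim_r(rank_d, between)
  r_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(k) {
    g <- shuffle()
    anosim_r(rank_d, g[pair_i] != g[pair_j])
  }, numeric(1)))
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_permutations)
  list(statistic = r_obs, p_value = p, n_permutations = n_permutations,
       seed = seed)
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums feature columns sharing the same lineage label at `rank`.
#'
#' @param table a [feature_table()] of OTUs.
#' @param taxonomy taxonomy data.frame ([read_taxonomy()]).
#' @param rank one of the taxonomy's rank columns (e.g. `"phylum"`).
#' @return samples x taxa matrix.
#' @export
collapse_rank <- function(table, taxonomy, rank) {
  if (!rank %in% names(taxonomy)) {
    invanet_error("invanet_invalid_argument",
                  sprintf("rank '%s' absent from taxonomy", rank))
  }
  x <- ft_values(table)
  lineage <- taxonomy[[rank]][match(colnames(x), taxonomy$otu_id)]
  lineage[is.na(lineage)] <- "unclassified"
  t(rowsum(t(x), lineage))
}

#' Kruskal-Wallis differential-abundance screen
#'
#' Collapses the OTU table to a taxonomic rank, keeps the `top_n` most
#' abundant taxa (by overall mean relative abundance; the survey convention
#' is the top 10 phyla and top 20 families), and tests each for a group
#' difference with the tie-corrected Kruskal-Wallis H (chi-square p,
#' df = groups - 1). Raw p-values are compared against 0.05 by convention;
#' `p_adjust = "BH"` applies Benjamini-Hochberg instead.
#'
#' @param table a [feature_table()].
#' @param groups group label per sample.
#' @param taxonomy optional taxonomy; when `NULL` features are tested as-is.
#' @param rank taxonomy rank to collapse to (with `taxonomy`).
#' @param top_n keep this many most-abundant taxa (`NULL` = all).
#' @param p_adjust `"none"` (default, raw p) or `"BH"`.
#' @return data.frame: taxon, H, p_value (adjusted if requested), and the
#'   per-group medians of relative abundance.
#' @export
kruskal_wallis_screen <- function(table, groups, taxonomy = NULL,
                                  rank = "phylum", top_n = NULL,
                                  p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  x <- ft_values(table)
  if (!is.null(taxonomy)) {
    x <- collapse_rank(table, taxonomy, rank)
  }
  rel <- x / rowSums(x)
  if (!is.null(top_n)) {
    keep <- order(colMeans(rel), decreasing = TRUE)[seq_len(min(top_n, ncol(rel)))]
    rel <- rel[, keep, drop = FALSE]
  }
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  res <- lapply(colnames(rel), function(taxon) {
    v <- rel[, taxon]
    med <- vapply(glev, function(g) stats::median(v[groups == g]), numeric(1))
    if (length(unique(v)) == 1L) {
      # fully tied: no evidence of any difference (kruskal.test's ties
      # correction is 0/0 here)
      return(c(H = 0, p_value = 1, med))
    }
    kt <- stats::kruskal.test(v, factor(groups))
    c(H = unname(kt$statistic), p_value = unname(kt$p.value), med)
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("H", "p_value", paste0("median_", glev))
  out <- cbind(taxon = colnames(rel), out)
  rownames(out) <- NULL
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}
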