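# LMG relative importance: average over all predictor orderings of the
# R^2 increase when a predictor enters the model. Computed from the
# covariance matrix, so each of the 2^p subset R^2 values is a single solve.
lmg_shares <- function(x, y) {
  p <- ncol(x)
  if (p > 20) {
    invanet_error("invanet_invalid_argument",
                  "LMG decomposition is limited to 20 predictors (2^p subsets)")
  }
  keep <- apply(x, 2, stats::sd) > 0
  shares <- stats::setNames(rep(0, p), colnames(x))
  xk <- x[, keep, drop = FALSE]
  pk <- ncol(xk)
  if (pk == 0) return(shares)
  cxx <- stats::cor(xk)
  cxy <- stats::cor(xk, y)[, 1]
  r2_of <- function(members) {
    if (!length(members)) return(0)
    drop(crossprod(cxy[members],
                   solve(cxx[members, members, drop = FALSE], cxy[members])))
  }
  # R^2 for every subset, indexed by bitmask
  n_sub <- 2^pk
  r2 <- numeric(n_sub)
  for (mask in seq_len(n_sub - 1)) {
    r2[mask + 1] <- r2_of(which(bitwAnd(mask, bitwShiftL(1, seq_len(pk) - 1)) > 0))
  }
  size <- vapply(0:(n_sub - 1), function(m) sum(bitwAnd(m, bitwShiftL(1, 0:(pk - 1))) > 0),
                 numeric(1))
  w <- function(s) factorial(s) * factorial(pk - 1 - s) / factorial(pk)
  sh <- numeric(pk)
  for (j in seq_len(pk)) {
    bit <- bitwShiftL(1, j - 1)
    without <- which(bitwAnd(0:(n_sub - 1), bit) == 0) - 1
    gains <- r2[without + bit + 1] - r2[without + 1]
    sh[j] <- sum(w(size[without + 1]) * gains)
  }
  shares[keep] <- sh
  shares
}

rf_importance_once <- function(x, y, n_trees) {
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  # report as percentage increase in out-of-bag MSE
  100 * imp / mean((y - mean(y))^2)
}

#' Driver importance for functional-gene profiles
#'
#' Quantifies how strongly each predictor (edaphic variable or keystone
#' abundance) drives a response (typically total absolute gene abundance per
#' sample), by one of two methods sharing an interface:
#'
#' * `rf_permutation` — random-forest permutation importance: the
#'   percentage increase in out-of-bag mean squared error when the
#'   predictor is permuted (%IncMSE).
#' * `lmg` — the LMG decomposition of a linear model's R-squared, averaged
#'   over all predictor orderings (contributions sum to the full-model
#'   R-squared).
#'
#' Significance for either method comes from a response-permutation null:
#' the response is permuted `n_perm` times, importances recomputed, and
#' each predictor's p-value is the add-one upper tail probability of its
#' observed importance.
#'
#' @param predictors samples x variables numeric matrix (no missing values).
#' @param response numeric vector, one value per sample.
#' @param method `"rf_permutation"` (default) or `"lmg"`.
#' @param n_trees trees per forest.
#' @param n_perm response permutations for the null.
#' @param seed RNG seed.
#' @return data.frame: predictor, importance, p_value, method. For `lmg`
#'   the attribute `r_squared` holds the full-model R-squared.
#' @export
importance <- function(predictors, response,
                       method = c("rf_permutation", "lmg"),
                       n_trees = 500, n_perm = 99, seed = NULL) {
  method <- match.arg(method)
  x <- as.matrix(predictors)
  y <- as.numeric(response)
  if (anyNA(x) || anyNA(y)) {
    invanet_error("invanet_invalid_argument", "missing values are not supported")
  }
  if (length(y) != nrow(x)) {
    invanet_error("invanet_invalid_argument", "response length must match predictor rows")
  }
  if (stats::sd(y) == 0) {
    invanet_error("invanet_invalid_argument", "constant response")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (method == "lmg" && nrow(x) <= ncol(x)) {
    warning("fewer samples than predictors: LMG subset fits may be unstable")
  }
  imp_fun <- if (method == "rf_permutation") {
    function(yy) rf_importance_once(x, yy, n_trees)
  } else {
    function(yy) lmg_shares(x, yy)
  }
  with_seed(seed, {
    obs <- imp_fun(y)
    exceed <- rep(0L, ncol(x))
    for (b in seq_len(n_perm)) {
      perm <- imp_fun(sample(y))
      exceed <- exceed + (perm >= obs)
    }
    p <- (1 + exceed) / (1 + n_perm)
    out <- data.frame(predictor = colnames(x), importance = unname(obs),
                      p_value = unname(p), method = method,
                      stringsAsFactors = FALSE)
    if (method == "lmg") attr(out, "r_squared") <- sum(obs)
    out
  })
}

#' Keystone-to-gene linear regression
#'
#' Regresses log functional-gene abundance on the average standardised
#' keystone abundance: each keystone OTU's abundance is ln-transformed,
#' z-scored across samples, and the z-scores averaged per sample; the
#' response is the ln gene abundance. Ordinary least squares with the
#' two-sided slope test.
#'
#' Zeros have no logarithm; the default policy is to fail with the list of
#' offending samples, `zero_policy = "pseudo"` instead adds half the
#' smallest positive value of the offending variable (logged via message).
#'
#' @param keystones samples x keystone-OTU abundance matrix.
#' @param genes numeric vector of gene abundance per sample (e.g. a
#'   category total or total copies).
#' @param zero_policy `"error"` (default) or `"pseudo"`.
#' @return list: slope, intercept, r_squared, p_value, n.
#' @export
keystone_gene_regression <- function(keystones, genes,
                                     zero_policy = c("error", "pseudo")) {
  zero_policy <- match.arg(zero_policy)
  k <- as.matrix(keystones)
  g <- as.numeric(genes)
  fix_zeros <- function(v, what) {
    bad <- v <= 0
    if (!any(bad)) return(v)
    if (zero_policy == "error") {
      offenders <- if (is.null(names(v))) which(bad) else names(v)[bad]
      invanet_error("invanet_nonpositive_value", sprintf(
        "%s has non-positive values in sample(s) %s; ln transform undefined (set zero_policy = 'pseudo' or filter)",
        what, paste(offenders, collapse = ", ")
      ))
    }
    pc <- min(v[v > 0]) / 2
    message(sprintf("keystone_gene_regression: added pseudo-count %g to %s", pc, what))
    v + pc
  }
  for (j in seq_len(ncol(k))) {
    v <- stats::setNames(k[, j], rownames(k))
    k[, j] <- fix_zeros(v, colnames(k)[j] %||% paste0("keystone ", j))
  }
  g <- fix_zeros(stats::setNames(g, rownames(k)), "gene abundance")
  z <- scale(log(k))
  x <- rowMeans(z)
  y <- log(g)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(y))
}

#' Redundancy analysis of gene profiles on edaphic variables
#'
#' Constrained ordination: response columns are standardised, regressed on
#' the predictors, and the fitted values decomposed into constrained axes
#' (vegan's RDA). Overall significance comes from a permutation F-test on
#' the rows of the predictors.
#'
#' @param response samples x genes numeric matrix.
#' @param predictors samples x edaphic-variables numeric matrix (full rank
#'   after centering; collinear predictors fail with the offending columns
#'   named).
#' @param n_perm permutations for the F-test.
#' @param seed RNG seed.
#' @return list: `eigenvalues` (constrained), `proportion_constrained`,
#'   `site_scores`, `biplot_scores`, `p_value`, `n_perm`.
#' @export
rda_genes <- function(response, predictors, n_perm = 999, seed = NULL) {
  y <- as.matrix(response)
  x <- as.data.frame(predictors)
  xc <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  qr_x <- qr(xc)
  if (qr_x$rank < ncol(xc)) {
    dep <- colnames(xc)[qr_x$pivot[(qr_x$rank + 1):ncol(xc)]]
    invanet_error("invanet_collinear_predictors", sprintf(
      "predictors are collinear after centering; drop: %s",
      paste(dep, collapse = ", ")
    ))
  }
  keep <- apply(y, 2, stats::sd) > 0
  y_std <- scale(y[, keep, drop = FALSE])
  fit <- vegan::rda(y_std ~ ., data = x)
  pval <- with_seed(seed, {
    stats::anova(fit, permutations = n_perm)$`Pr(>F)`[1]
  })
  eig <- fit$CCA$eig
  list(eigenvalues = eig,
       proportion_constrained = sum(eig) / fit$tot.chi,
       site_scores = vegan::scores(fit, display = "sites",
                                   choices = seq_along(eig)),
       biplot_scores = fit$CCA$biplot,
       p_value = pval,
       n_perm = n_perm)
}
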