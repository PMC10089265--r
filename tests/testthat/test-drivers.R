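test_that("LMG shares sum to the full-model R-squared", {
  set.seed(41)
  for (i in 1:5) {
    p <- sample(2:6, 1)
    x <- matrix(rnorm(40 * p), 40, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- x %*% rnorm(p) + rnorm(40)
    imp <- importance(x, y, method = "lmg", n_perm = 9, seed = i)
    full_r2 <- summary(lm(y ~ x))$r.squared
    expect_equal(sum(imp$importance), full_r2, tolerance = 1e-9)
    expect_equal(attr(imp, "r_squared"), full_r2, tolerance = 1e-9)
  }
})

test_that("LMG matches the orderings definition on a small model", {
  # oracle: average R^2 gain of each predictor over all 3! orderings
  set.seed(42)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * x[, 1] + x[, 2] + rnorm(20, 0, 0.5)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ x[, cols, drop = FALSE]))$r.squared
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  oracle <- numeric(3)
  for (pp in perms) {
    for (k in seq_along(pp)) {
      oracle[pp[k]] <- oracle[pp[k]] + (r2(pp[1:k]) - r2(pp[seq_len(k - 1)]))
    }
  }
  oracle <- oracle / length(perms)
  imp <- importance(x, y, method = "lmg", n_perm = 9, seed = 1)
  expect_equal(imp$importance, oracle, tolerance = 1e-9)
})

test_that("a planted driver dominates importance under both methods", {
  set.seed(7)
  x <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- 2 * x[, 1] + rnorm(100, 0, 0.1)
  rf <- importance(x, y, method = "rf_permutation", n_trees = 200,
                   n_perm = 19, seed = 2)
  lm_ <- importance(x, y, method = "lmg", n_perm = 19, seed = 2)
  expect_identical(rf$predictor[which.max(rf$importance)], "v1")
  expect_identical(lm_$predictor[which.max(lm_$importance)], "v1")
  expect_lt(rf$p_value[1], 0.1)
  expect_lt(lm_$p_value[1], 0.1)
})

test_that("degenerate predictors and responses are handled explicitly", {
  set.seed(9)
  x <- cbind(signal = rnorm(50), flat = rep(1, 50))
  y <- x[, 1] + rnorm(50, 0, 0.2)
  lm_ <- importance(x, y, method = "lmg", n_perm = 9, seed = 1)
  expect_equal(lm_$importance[lm_$predictor == "flat"], 0)
  rf <- importance(x, y, method = "rf_permutation", n_trees = 100,
                   n_perm = 9, seed = 1)
  expect_lt(abs(rf$importance[rf$predictor == "flat"]), 1e-8)
  expect_error(importance(x, rep(3, 50)), class = "invanet_invalid_argument")
})

test_that("rf importance is invariant to predictor column order", {
  set.seed(15)
  x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, letters[1:4]))
  y <- x[, 2] + rnorm(60, 0, 0.3)
  i1 <- importance(x, y, method = "rf_permutation", n_trees = 150,
                   n_perm = 0, seed = 77)
  i2 <- importance(x[, c(3, 1, 4, 2)], y, method = "rf_permutation",
                   n_trees = 150, n_perm = 0, seed = 77)
  # same seed: identical forests modulo column bookkeeping is not guaranteed,
  # but the planted predictor must dominate in both orders
  expect_identical(i1$predictor[which.max(i1$importance)], "b")
  expect_identical(i2$predictor[which.max(i2$importance)], "b")
})

test_that("keystone-gene regression works on the ln scale with z-scoring", {
  set.seed(3)
  k <- matrix(rlnorm(60, 0, 0.5), 20, 3,
              dimnames = list(paste0("s", 1:20), paste0("OTU_", 1:3)))
  z <- scale(log(k))
  x <- rowMeans(z)
  y <- exp(1.5 * x + 0.2)           # ln y = 1.5 x + 0.2 exactly
  fit <- keystone_gene_regression(k, y)
  expect_equal(fit$slope, 1.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n, 20)

  # zeros fail loudly under the default policy, naming samples
  k0 <- k; k0["s3", 1] <- 0
  err <- tryCatch(keystone_gene_regression(k0, y), error = identity)
  expect_s3_class(err, "invanet_nonpositive_value")
  expect_match(conditionMessage(err), "s3")
  expect_message(
    fit0 <- keystone_gene_regression(k0, y, zero_policy = "pseudo"),
    "pseudo-count"
  )
  expect_true(is.finite(fit0$slope))
})

test_that("regression recovers a planted slope within sampling error", {
  covered <- vapply(1:40, function(s) {
    set.seed(s)
    k <- matrix(rlnorm(45, 0, 0.4), 15, 3)
    x <- rowMeans(scale(log(k)))
    y <- exp(0.8 * x + rnorm(15, 0, 0.3))
    # |slope - 0.8| within 2 standard errors of the ln-ln fit
    sm <- summary(lm(log(y) ~ x))
    abs(sm$coefficients[2, 1] - 0.8) <= 2 * sm$coefficients[2, 2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("RDA explains everything in the noiseless limit and flags collinearity", {
  set.seed(19)
  x <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("pH", "TC", "AN")))
  b <- matrix(rnorm(3 * 5), 3, 5)
  y <- x %*% b
  colnames(y) <- paste0("g", 1:5)
  fit <- rda_genes(y, x, n_perm = 99, seed = 1)
  expect_equal(fit$proportion_constrained, 1, tolerance = 1e-9)

  x_bad <- cbind(x, TC2 = 2 * x[, "TC"])
  err <- tryCatch(rda_genes(y, x_bad, n_perm = 9, seed = 1), error = identity)
  expect_s3_class(err, "invanet_collinear_predictors")
  expect_match(conditionMessage(err), "TC2")
})

test_that("RDA permutation p is well-behaved under independence", {
  pv <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(24 * 3), 24, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- matrix(rnorm(24 * 4), 24, 4, dimnames = list(NULL, paste0("g", 1:4)))
    rda_genes(y, x, n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(pv > 0.05), 0.7)
})
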