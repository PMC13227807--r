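test_that("quantile normalization matches the brute-force oracle", {
  x <- as_expr(matrix(c(5, 2, 9, 4, 1, 7, 8, 6, 3), nrow = 3))
  # oracle: replace each column's rank-k value by the mean of rank-k values
  target <- rowMeans(apply(x, 2, sort))
  oracle <- x
  for (j in seq_len(ncol(x))) oracle[order(x[, j]), j] <- target
  expect_equal(normalize_log2_quantile(x, already_log2 = TRUE), oracle)
})

test_that("quantile normalization fixed points and idempotence", {
  same <- as_expr(matrix(rep(c(1, 5, 3, 8), 3), nrow = 4))
  expect_equal(normalize_log2_quantile(same, already_log2 = TRUE), same)
  one <- as_expr(matrix(c(2, 8, 32), nrow = 3))
  expect_equal(normalize_log2_quantile(one), log2(one))
  x <- as_expr(matrix(rexp(60, 1 / 8) + 1, nrow = 10))
  once <- normalize_log2_quantile(x)
  twice <- normalize_log2_quantile(once, already_log2 = TRUE)
  expect_equal(twice, once, tolerance = 1e-12)
  expect_error(normalize_log2_quantile(as_expr(matrix(c(-1, 2, 3, 4), 2))),
               "non-positive")
})

test_that("row-SD filter applies the linear-interpolation quantile", {
  set.seed(1)
  base <- matrix(rnorm(8 * 40), nrow = 8)
  x <- as_expr(base * (1:8))  # row SDs approximately 1..8
  sds <- apply(x, 1, sd)
  thr <- quantile(sds, 0.25, type = 7)
  kept <- filter_by_rowsd(x, 0.25)
  expect_identical(rownames(kept), rownames(x)[sds >= thr])
  expect_equal(nrow(filter_by_rowsd(x, 0)), 8)
  # constant row removed at any positive quantile
  x2 <- rbind(x, const = rep(5, 40))
  expect_false("const" %in% rownames(filter_by_rowsd(x2, 0.1)))
})

test_that("BH adjustment matches the step-through values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in p after sorting
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p))
})

test_that("moderated fit is null on identical groups and reduces to OLS t", {
  set.seed(3)
  half <- matrix(rnorm(20 * 10), nrow = 20)
  x <- as_expr(cbind(half, half))  # AD columns duplicate control columns
  ph <- toy_pheno(x, diagnosis = rep(c("AD", "control"), each = 10))
  ph$age <- rep(ph$age[1:10], 2)
  ph$sex <- rep(ph$sex[1:10], 2)
  ph$apoe4 <- rep(ph$apoe4[1:10], 2)
  de <- fit_moderated_de(x, ph, covariates = character(), trend = FALSE,
                         min_group_n = 2)
  expect_equal(de$results$log2fc, rep(0, 20), tolerance = 1e-10)

  # d0 = 0 disables moderation: t_mod equals the ordinary regression t
  ch <- tiny_cohort(seed = 4, n_ad = 25, n_control = 25, n_features = 30)
  de0 <- fit_moderated_de(ch$expr, ch$pheno, covariates = "age",
                          trend = FALSE, d0_override = 0, min_group_n = 2)
  t_ols <- sapply(de0$results$feature_id, function(f) {
    fit <- lm(ch$expr[f, ] ~ I(ch$pheno$diagnosis == "AD") + ch$pheno$age)
    summary(fit)$coefficients[2, "t value"]
  })
  expect_equal(de0$results$t_mod, unname(t_ols), tolerance = 1e-8)
})

test_that("posterior variances shrink between the sample and prior values", {
  ch <- tiny_cohort(seed = 6, n_ad = 30, n_control = 30, n_features = 80)
  de <- fit_moderated_de(ch$expr, ch$pheno, trend = FALSE, min_group_n = 2)
  d0 <- de$priors$d0
  s0 <- de$priors$s0_sq
  expect_true(d0 > 0)  # possibly unbounded (Inf = complete shrinkage)
  # recompute per-feature residual variances and check the squeeze bounds
  X <- model.matrix(~ I(ch$pheno$diagnosis == "AD") + ch$pheno$age +
                      I(ch$pheno$sex == "female") + factor(ch$pheno$apoe4))
  for (f in sample(de$results$feature_id, 10)) {
    s2 <- sum(lm.fit(X, ch$expr[f, ])$residuals^2) / (60 - ncol(X))
    tmod <- de$results$t_mod[de$results$feature_id == f]
    stilde2 <- (de$results$log2fc[de$results$feature_id == f] / tmod)^2 /
      chol2inv(chol(crossprod(X)))[2, 2]
    expect_gte(stilde2, min(s2, s0) - 1e-8)
    expect_lte(stilde2, max(s2, s0) + 1e-8)
  }
})

test_that("moderated statistics agree with the reference EB implementation", {
  ch <- tiny_cohort(seed = 7, n_ad = 40, n_control = 30, n_features = 100)
  ph <- ch$pheno
  X <- model.matrix(~ I(ph$diagnosis == "AD") + ph$age +
                      I(ph$sex == "female") + factor(ph$apoe4))
  de <- fit_moderated_de(ch$expr, ph, trend = FALSE, min_group_n = 2)
  fit <- limma::eBayes(limma::lmFit(ch$expr, X), trend = FALSE)
  expect_equal(de$priors$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(de$priors$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$results$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(de$results$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  # with a trend the smoother span differs between implementations, so the
  # agreement is close but not exact
  de_t <- fit_moderated_de(ch$expr, ph, trend = TRUE, min_group_n = 2)
  fit_t <- limma::eBayes(limma::lmFit(ch$expr, X), trend = TRUE)
  expect_gt(cor(de_t$results$t_mod, fit_t$t[, 2]), 0.999)
  expect_lt(max(abs(de_t$results$p - fit_t$p.value[, 2])), 0.02)
})

test_that("rank-deficient designs fail naming the collinear column", {
  ch <- tiny_cohort(seed = 8, n_ad = 10, n_control = 10, n_features = 5)
  ch$pheno$sex <- "female"  # sexfemale column collinear with intercept
  expect_error(fit_moderated_de(ch$expr, ch$pheno, covariates = "sex",
                                min_group_n = 2),
               "sexfemale")
})

test_that("robust flag is a documented no-op with a warning", {
  ch <- tiny_cohort(seed = 9, n_ad = 12, n_control = 12, n_features = 10)
  expect_warning(
    fit_moderated_de(ch$expr, ch$pheno, robust = TRUE, min_group_n = 2),
    "not implemented")
})

test_that("covariate model comparison computes Jaccard and Spearman", {
  res <- data.frame(feature_id = letters[1:5],
                    log2fc = c(1, -2, 0.5, 0.1, -0.3),
                    q = c(0.01, 0.02, 0.03, 0.5, 0.9))
  cmp <- compare_covariate_models(res, res)
  expect_equal(cmp$jaccard, 1)
  expect_equal(cmp$spearman_log2fc, 1)

  res_b <- res
  res_b$q <- c(0.5, 0.01, 0.02, 0.03, 0.9)  # significant {b,c,d} vs {a,b,c}
  expect_equal(compare_covariate_models(res, res_b)$jaccard, 0.5)

  res_c <- res
  res_c$q <- c(0.5, 0.5, 0.5, 0.5, 0.01)
  res_d <- res
  res_d$q <- c(0.01, 0.5, 0.5, 0.5, 0.5)
  expect_equal(compare_covariate_models(res_c, res_d)$jaccard, 0)

  none <- res
  none$q <- rep(0.9, 5)
  expect_true(is.na(compare_covariate_models(none, none)$jaccard))
})
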