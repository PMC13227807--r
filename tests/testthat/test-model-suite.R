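test_that("penalized logistic obeys its shrinkage limits", {
  set.seed(51)
  n <- 200
  x <- c(rnorm(n / 2, 2), rnorm(n / 2, -2))
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(feat = x)
  # near-unpenalized fit separates the two sides
  lo <- fit_penalized_logistic(X, y, l1_ratio = 0.5, strength = 1e-4)
  p <- predict(lo, X)
  expect_gt(mean(p[y == 1]), 0.9)
  expect_lt(mean(p[y == 0]), 0.1)
  # heavy penalty collapses to the (weighted) base rate
  hi <- fit_penalized_logistic(X, y, l1_ratio = 0.5, strength = 100)
  expect_equal(unname(hi$beta), 0, tolerance = 1e-6)
  expect_equal(unique(round(predict(hi, X), 6)), round(mean(y), 6))
  # lasso keeps at most one of two duplicated columns
  X2 <- cbind(a = x, b = x)
  la <- fit_penalized_logistic(X2, y, l1_ratio = 1, strength = 0.05)
  expect_lte(sum(abs(la$beta) > 1e-6), 1)
})

test_that("median imputation and standardization live inside the pipeline", {
  set.seed(52)
  X <- cbind(a = rnorm(100), b = rnorm(100, 50, 10))
  y <- rbinom(100, 1, plogis(X[, 1]))
  Xna <- X
  Xna[1:10, 2] <- NA
  fit <- fit_penalized_logistic(Xna, y, strength = 0.01)
  expect_equal(unname(fit$median["b"]), median(Xna[-(1:10), 2]))
  expect_true(all(is.finite(predict(fit, X))))
  Xbad <- X
  Xbad[1, 1] <- Inf
  expect_error(fit_penalized_logistic(Xbad, y), "non-finite")
})

test_that("nested OOF evaluation separates signal and is reproducible", {
  set.seed(53)
  n <- 150
  risk <- rnorm(n)
  expr <- as_expr(rbind(risk, rnorm(n)))
  y <- ifelse(plogis(6 * risk) > runif(n), "AD", "control")
  ph <- toy_pheno(expr, diagnosis = y)
  spec <- model_spec(features = rownames(expr), baseline = character(),
                     seed = 99)
  grid <- data.frame(strength = c(0.01, 0.1), l1_ratio = 0.5)
  ev1 <- nested_oof_eval(expr, ph, spec, grid = grid, n_boot = 200)
  ev2 <- nested_oof_eval(expr, ph, spec, grid = grid, n_boot = 200)
  expect_identical(ev1, ev2)
  expect_gt(ev1$auc, 0.9)
  expect_true(ev1$auc_ci[1] <= ev1$auc && ev1$auc <= ev1$auc_ci[2])

  # a perfectly predictive feature gives near-perfect OOF metrics
  expr2 <- as_expr(rbind(ifelse(ph$diagnosis == "AD", 5, -5) + rnorm(n, 0, 0.1),
                         rnorm(n)))
  ev3 <- nested_oof_eval(expr2, ph, model_spec(features = rownames(expr2),
                                               baseline = character(),
                                               seed = 1),
                         grid = grid, n_boot = 2)
  expect_gt(ev3$auc, 0.99)
  expect_lt(ev3$brier, 0.05)
})

test_that("calibration error matches hand computations", {
  # constant prob 1.0 with half-positive labels
  out <- calibration_metrics(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(out$ece, 0.5)
  # probabilities equal to the observed rate inside one bin
  out2 <- calibration_metrics(rep(0.32, 50), rep(c(1, 0, 0, 1, 0), 10))
  expect_equal(out2$ece, abs(0.32 - 0.4))
  # large-sample calibrated forecaster
  set.seed(54)
  p <- runif(1e5)
  yy <- rbinom(1e5, 1, p)
  expect_lt(calibration_metrics(p, yy)$ece, 0.02)
})

test_that("Brier score of the constant-prevalence predictor is exact", {
  y <- rep(c(1, 0), c(30, 70))
  prev <- mean(y)
  expect_equal(mean((rep(prev, 100) - y)^2), prev * (1 - prev))
})

test_that("decision curves satisfy the closed-form identities", {
  set.seed(55)
  n <- 500
  y <- rbinom(n, 1, 0.78)
  dca <- decision_curve(runif(n), y)
  expect_equal(dca$treat_none, rep(0, nrow(dca)))
  prev <- mean(y)
  expect_equal(dca$treat_all,
               prev - (1 - prev) * dca$pt / (1 - dca$pt))
  # treat-all closed form at pt = 0.2 and prevalence 0.78
  ta <- decision_curve(rep(0.5, 100), rep(c(1, 0), c(78, 22)))
  expect_equal(ta$treat_all[ta$pt == 0.2], 0.78 - 0.22 * 0.25)
  # perfect predictor: NB = prevalence at every pt in the grid
  perf <- decision_curve(y, y)
  expect_equal(perf$net_benefit, rep(prev, nrow(perf)))
  # model NB never exceeds prevalence
  expect_true(all(dca$net_benefit <= prev + 1e-12))
})

test_that("operating points honor the prespecified constraints", {
  probs <- seq(0.1, 1, by = 0.1)
  y <- rep(c(0, 1), each = 5)
  op <- operating_points(probs, y)
  # exhaustive-threshold oracle at specificity >= 0.9: the cut must sit
  # above the best-scoring negative (0.5), keeping all positives
  row <- op[op$constraint == "specificity>=0.90", ]
  expect_gt(row$threshold, 0.5)
  expect_equal(row$sensitivity, 1)
  expect_equal(row$specificity, 1)
  # perfect predictor reaches sensitivity 1 under the constraint
  op2 <- operating_points(c(0.1, 0.2, 0.9, 0.95), c(0, 0, 1, 1))
  expect_equal(op2$sensitivity[op2$constraint == "specificity>=0.90"], 1)
  # adversarial flipped probabilities: constrained sensitivity collapses
  op3 <- operating_points(1 - probs, y)
  expect_equal(op3$sensitivity[op3$constraint == "specificity>=0.90"], 0)
  expect_error(operating_points(probs, rep(1, 10)), "both classes")
})

test_that("irrelevant features barely move the OOF AUC", {
  ch <- tiny_cohort(seed = 56, n_ad = 150, n_control = 150, n_features = 40)
  grid <- data.frame(strength = 0.01, l1_ratio = 0.5)
  feats <- default_candidate_sets()$feature_id[1:3]
  base <- nested_oof_eval(ch$expr, ch$pheno,
                          model_spec(features = feats, seed = 3),
                          grid = grid, n_boot = 2)
  noisy <- nested_oof_eval(ch$expr, ch$pheno,
                           model_spec(features = c(feats, "miR-sim-0001"),
                                      seed = 3),
                           grid = grid, n_boot = 2)
  expect_lt(abs(base$auc - noisy$auc), 0.02)
})
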