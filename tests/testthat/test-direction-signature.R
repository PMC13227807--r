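test_that("directional consistency needs significance and the expected sign", {
  de <- data.frame(feature_id = c("p1", "p2", "p3", "n1", "absent_ref"),
                   log2fc = c(-0.5, +0.5, -0.4, +0.3, 0),
                   q = c(0.01, 0.01, 0.5, 0.01, 1))
  sets <- data.frame(feature_id = c("p1", "p2", "p3", "n1", "gone"),
                     direction = c("positive", "positive", "positive",
                                   "negative", "negative"))
  out <- assess_direction(de, sets)
  expect_true(out$consistent[out$feature_id == "p1"])    # down + significant
  expect_false(out$consistent[out$feature_id == "p2"])   # sign flip
  expect_false(out$consistent[out$feature_id == "p3"])   # not significant
  expect_true(out$consistent[out$feature_id == "n1"])    # up + significant
  expect_false(out$present[out$feature_id == "gone"])
  expect_true(is.na(out$consistent[out$feature_id == "gone"]))
})

test_that("mean-rank set test tracks exhaustive enumeration for small n", {
  n <- 8; m <- 3
  stats <- setNames(seq_len(n) * 1.0, paste0("f", seq_len(n)))
  # exhaustive oracle over all C(n, m) member subsets
  subsets <- combn(n, m)
  sums <- colSums(matrix(seq_len(n)[subsets], nrow = m))
  for (j in sample(ncol(subsets), 15)) {
    w <- sums[j]
    p_exact <- mean(sums >= w)
    p_norm <- mean_rank_set_test(stats, paste0("f", subsets[, j]),
                                 "greater")
    expect_lt(abs(p_norm - p_exact), 0.02)
  }
  # the top-m set attains the minimum p for that (m, n)
  p_top <- mean_rank_set_test(stats, paste0("f", (n - m + 1):n), "greater")
  expect_equal(p_top, min(sapply(seq_len(ncol(subsets)), function(j)
    mean_rank_set_test(stats, paste0("f", subsets[, j]), "greater"))))
})

test_that("mean-rank p-values are uniform under random set membership", {
  set.seed(101)
  stats <- setNames(rnorm(100), paste0("f", 1:100))
  ps <- replicate(2000, {
    mean_rank_set_test(stats, sample(names(stats), 10), "greater")
  })
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("one-sided mean-rank alternatives are complementary", {
  stats <- setNames(c(5, 3, 9, 1, 7, 2), paste0("f", 1:6))
  pg <- mean_rank_set_test(stats, c("f1", "f3"), "greater")
  pl <- mean_rank_set_test(stats, c("f1", "f3"), "less")
  # the one-sided p-values overlap only by the point mass at the observed
  # rank sum, so their sum sits just above 1
  expect_gte(pg + pl, 1)
  expect_lt(pg + pl, 1.2)
  expect_error(mean_rank_set_test(stats, names(stats), "greater"),
               "complement")
})

test_that("sign test gives exact binomial tails", {
  out <- signed_shift_tests(rep(0.3, 10), +1)
  expect_equal(out$sign_test_p, 2^-10)
  out2 <- signed_shift_tests(c(rep(0.5, 7), -0.1), +1)
  expect_equal(out2$sign_test_p, 9 / 256)
  # zeros dropped; all-zero input undefined
  expect_equal(signed_shift_tests(c(rep(0.5, 7), -0.1, 0, 0), +1)$sign_test_p,
               9 / 256)
  expect_true(is.na(signed_shift_tests(rep(0, 4), +1)$sign_test_p))
})

test_that("signed-rank p is near 0.5 for symmetric values", {
  x <- c(-3, -2, -1, 1, 2, 3)
  expect_equal(signed_shift_tests(x, +1)$signed_rank_p, 0.5, tolerance = 0.1)
  expect_equal(signed_shift_tests(x, -1)$signed_rank_p, 0.5, tolerance = 0.1)
})

test_that("signature score matches the hand-computed toy example", {
  x <- matrix(c(1, 4, 3, 2), nrow = 2,
              dimnames = list(c("neg1", "pos1"), c("s1", "s2")))
  sets <- data.frame(feature_id = c("neg1", "pos1"),
                     direction = c("negative", "positive"))
  sc <- compute_signature_score(x, sets)$scores
  expect_equal(unname(sc), c(-2, 2) / sqrt(2), tolerance = 1e-10)
})

test_that("signature score is invariant to affine feature transforms", {
  ch <- tiny_cohort(seed = 31, n_ad = 20, n_control = 20, n_features = 40)
  sets <- default_candidate_sets()
  s1 <- compute_signature_score(ch$expr, sets)$scores
  expr2 <- ch$expr
  expr2[5, ] <- 3 * expr2[5, ] + 10
  expr2[20, ] <- -0.5 * expr2[20, ] + 1  # note: sign flip does change z
  expr2[20, ] <- ch$expr[20, ]
  s2 <- compute_signature_score(expr2, sets)$scores
  expect_equal(s1, s2, tolerance = 1e-10)
  # identical rows in both sets cancel exactly
  x <- matrix(c(1, 5, 2, 1, 5, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  sets2 <- data.frame(feature_id = c("a", "b"),
                      direction = c("positive", "negative"))
  expect_equal(unname(compute_signature_score(x, sets2)$scores),
               rep(0, 3), tolerance = 1e-12)
})

test_that("score-group association recovers exact and null relationships", {
  ch <- tiny_cohort(seed = 32, n_ad = 50, n_control = 50, n_features = 10)
  score <- setNames(as.numeric(ch$pheno$diagnosis == "AD"),
                    ch$pheno$sample_id)
  fit <- suppressWarnings(test_signature_association(score, ch$pheno))
  expect_equal(fit$coefficient, 1, tolerance = 1e-10)
  expect_lt(fit$p, 1e-12)

  # null: score independent of everything
  set.seed(33)
  hits <- replicate(200, {
    s <- setNames(rnorm(100), ch$pheno$sample_id)
    test_signature_association(s, ch$pheno)$p < 0.05
  })
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.08)
})

test_that("signature group effect is positive when sets shift as expected", {
  signs <- sapply(1:20, function(s) {
    ch <- tiny_cohort(seed = 100 + s, n_ad = 100, n_control = 100,
                      n_features = 40)
    sets <- default_candidate_sets()
    sc <- compute_signature_score(ch$expr, sets)$scores
    sign(test_signature_association(sc, ch$pheno)$coefficient)
  })
  expect_gte(mean(signs > 0), 0.95)
})
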