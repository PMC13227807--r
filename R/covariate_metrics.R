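#' Operating-point metrics from confusion counts
#'
#' @param tp,fp,tn,fn non-negative counts (total >= 1).
#' @return list: sensitivity, specificity, ppv, npv, accuracy, youden_j.
#'   A metric whose denominator is zero is `NA`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("all-zero confusion counts")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  list(sensitivity = sens,
       specificity = spec,
       ppv = frac(tp, tp + fp),
       npv = frac(tn, tn + fn),
       accuracy = (tp + tn) / sum(counts),
       youden_j = sens + spec - 1)
}

#' Rank-based AUC and average precision
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counting one half (midrank formula, exactly the
#' exhaustive pairwise count). AP is the step sum over distinct descending
#' score thresholds of precision times recall increment (no interpolation).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return list: `auc`, `ap`.
#' @export
rank_metrics <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # AP over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  block <- cumsum(!duplicated(s))
  tp <- tapply(y, block, sum)
  npos_block <- tapply(rep(1, length(y)), block, sum)
  ctp <- cumsum(tp)
  cn <- cumsum(npos_block)
  prec <- ctp / cn
  recall_inc <- tp / n1
  ap <- sum(prec * recall_inc)
  list(auc = as.numeric(auc), ap = as.numeric(ap))
}

#' Youden-optimal threshold
#'
#' Candidate thresholds are the midpoints between adjacent distinct sorted
#' scores plus minus/plus infinity; the classification rule is
#' `score >= threshold => positive`. Ties in J are broken toward the lowest
#' threshold. Also reports the smallest attained score in the positive
#' region (`threshold_attained`), which matches integer-valued covariates'
#' printed cutoffs.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return list: threshold, threshold_attained, sensitivity, specificity,
#'   ppv, npv, accuracy, youden_j.
#' @export
youden_select <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  best <- NULL
  for (thr in cand) {
    pred <- scores >= thr
    m <- confusion_metrics(sum(pred & labels == 1), sum(pred & labels == 0),
                           sum(!pred & labels == 0), sum(!pred & labels == 1))
    j <- ifelse(is.na(m$youden_j), -Inf, m$youden_j)
    if (is.null(best) || j > best$youden_j + 1e-12) {
      best <- c(list(threshold = thr), m)
      best$youden_j <- j
    }
  }
  pos_scores <- scores[scores >= best$threshold]
  best$threshold_attained <- if (length(pos_scores)) min(pos_scores) else NA_real_
  best
}

#' Stratified cross-validated univariate diagnostics
#'
#' Per fold: logistic regression of label on the single variable fitted on
#' the training split, Youden threshold chosen on training predictions and
#' applied unchanged to validation predictions. Reports validation
#' sensitivity/specificity/ppv/npv/accuracy plus AUC and AP, and their
#' mean and SD across folds.
#'
#' @param scores numeric predictor values.
#' @param labels binary labels (each class count >= k).
#' @param k number of folds (default 5).
#' @param seed integer seed for the stratified fold assignment.
#' @return list: `folds` (per-fold metric data.frame), `mean`, `sd`.
#' @export
crossval_univariate <- function(scores, labels, k = 5, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  fold <- stratified_folds(labels, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial(),
                 data = data.frame(y = labels[tr], x = scores[tr])))
    p_tr <- stats::predict(fit, type = "response")
    p_va <- stats::predict(fit, type = "response",
                           newdata = data.frame(x = scores[!tr]))
    thr <- youden_select(p_tr, labels[tr])$threshold
    yv <- labels[!tr]
    pred <- p_va >= thr
    cm <- confusion_metrics(sum(pred & yv == 1), sum(pred & yv == 0),
                            sum(!pred & yv == 0), sum(!pred & yv == 1))
    rm_ <- rank_metrics(p_va, yv)
    data.frame(fold = f, sensitivity = cm$sensitivity,
               specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv,
               accuracy = cm$accuracy, auc = rm_$auc, ap = rm_$ap)
  })
  folds <- do.call(rbind, per_fold)
  metrics <- folds[, -1, drop = FALSE]
  list(folds = folds,
       mean = colMeans(metrics, na.rm = TRUE),
       sd = apply(metrics, 2, stats::sd, na.rm = TRUE))
}

#' Cramer's V association of a contingency table
#'
#' Pearson chi-square without continuity correction;
#' `V = sqrt(chi2 / (n * min(r - 1, c - 1)))`.
#'
#' @param tab r x c matrix of non-negative counts (r, c >= 2).
#' @return list: `chi2`, `v`, `n`.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal row or column")
  }
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  v <- sqrt(as.numeric(chi2) / (n * min(nrow(tab) - 1, ncol(tab) - 1)))
  list(chi2 = as.numeric(chi2), v = v, n = n)
}

#' Partial Spearman correlations between features and a covariate
#'
#' All variables are rank-transformed (average ties); the feature and the
#' target covariate are then OLS-residualized against the remaining
#' covariates plus an intercept, and the coefficient is the Pearson
#' correlation of the residuals. Two-sided p from the t distribution with
#' `n - 2 - n_adjusters` degrees of freedom; q by Benjamini-Hochberg across
#' features. With no adjusters this reduces exactly to Spearman's rho
#' (point-biserial on ranks for a binary target).
#'
#' @param expr features x samples matrix.
#' @param pheno phenotype table.
#' @param target covariate name: one of `"age"`, `"sex"`, `"apoe4"`.
#' @param adjust_for character vector of remaining covariates (possibly
#'   empty).
#' @return data.frame: feature_id, covariate, coefficient, p, q. Constant
#'   features get `NA` coefficients.
#' @export
partial_rank_assoc <- function(expr, pheno, target,
                               adjust_for = setdiff(c("age", "sex", "apoe4"),
                                                    target)) {
  check_expr(expr)
  check_pheno(pheno, expr)
  pheno <- pheno[match(colnames(expr), pheno$sample_id), , drop = FALSE]
  covar_num <- function(v) {
    switch(v,
           age = pheno$age,
           sex = as.numeric(pheno$sex == "female"),
           apoe4 = as.numeric(pheno$apoe4),
           stop("unknown covariate: ", v))
  }
  tgt <- covar_num(target)
  adj <- if (length(adjust_for)) {
    sapply(adjust_for, covar_num)
  } else NULL
  complete <- stats::complete.cases(cbind(tgt, adj))
  n <- sum(complete)
  if (n < 10) stop("need >= 10 complete samples")

  res <- lapply(rownames(expr), function(fid) {
    x <- expr[fid, ]
    ok <- complete & !is.na(x)
    ni <- sum(ok)
    if (ni < 10 || stats::sd(x[ok]) == 0) {
      return(data.frame(feature_id = fid, covariate = target,
                        coefficient = NA_real_, p = NA_real_))
    }
    rx <- rank(x[ok])
    rt <- rank(tgt[ok])
    if (!is.null(adj)) {
      ra <- apply(adj[ok, , drop = FALSE], 2, rank)
      A <- cbind(1, ra)
      rx <- stats::residuals(stats::lm.fit(A, rx))
      rt <- stats::residuals(stats::lm.fit(A, rt))
    }
    if (stats::sd(rx) == 0 || stats::sd(rt) == 0) {
      return(data.frame(feature_id = fid, covariate = target,
                        coefficient = NA_real_, p = NA_real_))
    }
    r <- stats::cor(rx, rt)
    df <- ni - 2 - length(adjust_for)
    tt <- r * sqrt(df / (1 - r^2))
    data.frame(feature_id = fid, covariate = target,
               coefficient = r, p = 2 * stats::pt(-abs(tt), df))
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
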