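#' Specify a diagnostic classification model
#'
#' @param features character vector of miRNA feature IDs (possibly empty).
#' @param baseline subset of `c("age", "sex")` used as clinical covariates.
#' @param classifier classifier name; `"penalized_logistic"` (elastic net,
#'   the primary classifier) is built in, `"linear_svm"`, `"rbf_svm"` and
#'   `"random_forest"` are optional comparators requiring the e1071 /
#'   randomForest packages.
#' @param class_weighting balance class weights inversely to class
#'   frequency (default TRUE).
#' @param seed integer seed driving every random draw of the evaluation.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(features = character(), baseline = c("age", "sex"),
                       classifier = "penalized_logistic",
                       class_weighting = TRUE, seed = 1L) {
  baseline <- if (length(baseline)) {
    match.arg(baseline, c("age", "sex"), several.ok = TRUE)
  } else character()
  if (length(features) + length(baseline) == 0) {
    stop("model needs at least one predictor")
  }
  structure(list(features = features, baseline = baseline,
                 classifier = classifier,
                 class_weighting = class_weighting,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# Assemble the samples x predictors design from expression + phenotype.
build_predictor_matrix <- function(expr, pheno, features, baseline) {
  pheno <- pheno[match(colnames(expr), pheno$sample_id), , drop = FALSE]
  blocks <- list()
  if (length(features)) {
    miss <- setdiff(features, rownames(expr))
    if (length(miss)) stop("features not in matrix: ",
                           paste(miss, collapse = ", "))
    blocks$feat <- t(expr[features, , drop = FALSE])
  }
  if ("age" %in% baseline) blocks$age <- matrix(pheno$age, ncol = 1,
                                                dimnames = list(NULL, "age"))
  if ("sex" %in% baseline) {
    blocks$sex <- matrix(as.numeric(pheno$sex == "female"), ncol = 1,
                         dimnames = list(NULL, "sexfemale"))
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- colnames(expr)
  X
}

#' Elastic-net penalized logistic regression with a training pipeline
#'
#' Median imputation and standardization are fitted on the training data and
#' stored for prediction. The penalized log-likelihood uses
#' `strength * (l1_ratio * L1 + (1 - l1_ratio)/2 * L2)`; optional class
#' weighting scales sample weights inversely to class frequency.
#'
#' @param X samples x features numeric matrix.
#' @param y binary outcome (0/1).
#' @param l1_ratio elastic-net mixing in `[0, 1]` (1 = lasso).
#' @param strength penalty strength (glmnet lambda).
#' @param weights optional per-sample weights.
#' @param class_weighting balance classes via weights.
#' @return object of class `penalized_logistic`; use [predict()] to obtain
#'   probabilities.
#' @export
fit_penalized_logistic <- function(X, y, l1_ratio = 0.5, strength = 0.01,
                                   weights = NULL, class_weighting = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    mi <- is.na(X[, j])
    if (any(mi)) X[mi, j] <- med[j]
  }
  if (any(!is.finite(X))) stop("non-finite predictor values after imputation")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (class_weighting) {
    tab <- table(y)
    weights <- weights * (length(y) / (2 * as.numeric(tab[as.character(y)])))
  }
  padded <- ncol(Xs) == 1
  if (padded) Xs <- cbind(Xs, `.dummy` = 0)
  lambda_path <- sort(unique(strength * c(64, 16, 4, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = l1_ratio,
                        lambda = lambda_path, weights = weights,
                        standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = strength))
  if (padded) beta <- beta[-length(beta)]
  structure(list(intercept = beta[1], beta = beta[-1],
                 median = med, center = ctr, scale = scl,
                 l1_ratio = l1_ratio, strength = strength),
            class = "penalized_logistic")
}

#' @export
predict.penalized_logistic <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  for (j in seq_len(ncol(X))) {
    mi <- is.na(X[, j])
    if (any(mi)) X[mi, j] <- object$median[j]
  }
  Xs <- scale(X, center = object$center, scale = object$scale)
  as.numeric(stats::plogis(object$intercept + Xs %*% object$beta))
}

# Fit/predict a classifier for one hyperparameter setting; the plug-in
# surface shared by the elastic net and the optional comparators.
fit_classifier <- function(X, y, classifier, params, class_weighting) {
  if (classifier == "penalized_logistic") {
    return(fit_penalized_logistic(X, y, l1_ratio = params$l1_ratio,
                                  strength = params$strength,
                                  class_weighting = class_weighting))
  }
  if (classifier %in% c("linear_svm", "rbf_svm")) {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stop("classifier '", classifier, "' needs the e1071 package")
    }
    kern <- if (classifier == "linear_svm") "linear" else "radial"
    fit <- e1071::svm(X, factor(y), kernel = kern, probability = TRUE,
                      cost = params$cost %||% 1)
    return(structure(list(fit = fit), class = "svm_prob"))
  }
  if (classifier == "random_forest") {
    if (!requireNamespace("randomForest", quietly = TRUE)) {
      stop("classifier 'random_forest' needs the randomForest package")
    }
    fit <- randomForest::randomForest(X, factor(y),
                                      ntree = params$ntree %||% 500)
    return(structure(list(fit = fit), class = "rf_prob"))
  }
  stop("unknown classifier: ", classifier)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.svm_prob <- function(object, newdata, ...) {
  pr <- attr(stats::predict(object$fit, newdata, probability = TRUE),
             "probabilities")
  as.numeric(pr[, "1"])
}

#' @export
predict.rf_prob <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newdata, type = "prob")[, "1"])
}

#' Default elastic-net hyperparameter grid
#'
#' Strength in `{0.001, 0.01, 0.1, 1, 10}` crossed with l1 mixing in
#' `{0.1, 0.5, 0.9}`.
#'
#' @return data.frame with columns `strength`, `l1_ratio`.
#' @export
default_enet_grid <- function() {
  expand.grid(strength = c(0.001, 0.01, 0.1, 1, 10),
              l1_ratio = c(0.1, 0.5, 0.9))
}

#' Nested cross-validated out-of-fold evaluation
#'
#' Outer stratified folds estimate generalization; inner stratified folds
#' tune hyperparameters by pooled inner-CV AUC. Each sample's out-of-fold
#' (OOF) probability comes from a model never trained on it; with repeats,
#' OOF probabilities are averaged across repeats before pooled metrics.
#' Reports AUC (with stratified-bootstrap percentile CI), average
#' precision, Brier score, calibration, decision curve, and operating
#' points. Deterministic given `spec$seed`.
#'
#' @param expr features x samples matrix.
#' @param pheno phenotype table.
#' @param spec a [model_spec()].
#' @param outer,inner fold counts (default 5 x 5).
#' @param repeats outer-CV repeats (default 1).
#' @param grid hyperparameter data.frame (default [default_enet_grid()]).
#' @param n_boot bootstrap draws for the AUC CI (default 2000).
#' @return list of class `eval_report`: oof_probs, y, auc, auc_ci, ap,
#'   brier, ece, calibration, dca, operating_points, best_params.
#' @export
nested_oof_eval <- function(expr, pheno, spec, outer = 5, inner = 5,
                            repeats = 1, grid = default_enet_grid(),
                            n_boot = 2000) {
  check_expr(expr)
  check_pheno(pheno, expr)
  X <- build_predictor_matrix(expr, pheno, spec$features, spec$baseline)
  y <- diagnosis_indicator(pheno, colnames(expr))
  if (min(table(y)) < outer) stop("each class must have >= outer members")

  oof <- matrix(NA_real_, nrow = repeats, ncol = length(y))
  chosen <- list()
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, outer,
                              derive_seed(spec$seed, paste0("outer", r)))
    for (f in seq_len(outer)) {
      tr <- folds != f
      best <- tune_inner(X[tr, , drop = FALSE], y[tr], spec, inner, grid,
                         derive_seed(spec$seed, paste0("inner", r, "_", f)))
      fit <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec$classifier,
                            best, spec$class_weighting)
      oof[r, !tr] <- stats::predict(fit, X[!tr, , drop = FALSE])
      chosen[[length(chosen) + 1]] <- best
    }
  }
  probs <- colMeans(oof)
  rm_ <- rank_metrics(probs, y)
  brier <- mean((probs - y)^2)
  ci <- auc_bootstrap_ci(probs, y, n_boot,
                         derive_seed(spec$seed, "bootstrap"))
  calib <- calibration_metrics(probs, y)
  structure(list(
    oof_probs = stats::setNames(probs, rownames(X)), y = y,
    auc = rm_$auc, auc_ci = ci, ap = rm_$ap, brier = brier,
    ece = calib$ece, calibration = calib$bins,
    dca = decision_curve(probs, y),
    operating_points = operating_points(probs, y),
    best_params = chosen
  ), class = "eval_report")
}

# Pooled inner-CV AUC for each grid row; returns the best row (ties go to
# the earlier grid row, so the grid order is the tie-break).
tune_inner <- function(X, y, spec, inner, grid, seed) {
  if (nrow(grid) == 1) return(as.list(grid[1, , drop = FALSE]))
  folds <- stratified_folds(y, inner, seed)
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    probs <- rep(NA_real_, length(y))
    for (f in seq_len(inner)) {
      tr <- folds != f
      fit <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec$classifier,
                            params, spec$class_weighting)
      probs[!tr] <- stats::predict(fit, X[!tr, , drop = FALSE])
    }
    rank_metrics(probs, y)$auc
  }, numeric(1))
  as.list(grid[which.max(aucs), , drop = FALSE])
}

# Stratified bootstrap percentile CI for the pooled-OOF AUC.
auc_bootstrap_ci <- function(probs, y, n_boot, seed) {
  if (n_boot < 2) return(c(NA_real_, NA_real_))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  pos <- which(y == 1)
  neg <- which(y == 0)
  draws <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    rank_metrics(probs[idx], y[idx])$auc
  }, numeric(1))
  stats::quantile(draws, c(0.025, 0.975), names = FALSE)
}

#' Expected calibration error over equal-width probability bins
#'
#' @param oof_probs probabilities in `[0, 1]`.
#' @param y binary outcomes.
#' @param n_bins number of equal-width bins (default 10).
#' @return list: `ece`, `bins` (data.frame: bin, n, mean_prob,
#'   observed_rate); empty bins are skipped.
#' @export
calibration_metrics <- function(oof_probs, y, n_bins = 10) {
  stopifnot(all(oof_probs >= 0 & oof_probs <= 1))
  y <- as.integer(as.logical(y))
  bin <- pmin(floor(oof_probs * n_bins) + 1L, n_bins)
  n <- length(y)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel), mean_prob = mean(oof_probs[sel]),
               observed_rate = mean(y[sel]))
  })
  bins <- do.call(rbind, rows)
  list(ece = sum(bins$n / n * abs(bins$mean_prob - bins$observed_rate)),
       bins = bins)
}

#' Decision-curve analysis
#'
#' At each threshold probability `pt`, samples with `prob >= pt` are
#' classified positive and the net benefit is
#' `TP/N - (FP/N) * pt / (1 - pt)`; reference strategies treat-all
#' (`prevalence - (1 - prevalence) * pt / (1 - pt)`) and treat-none (0).
#'
#' @param oof_probs probabilities in `[0, 1]`.
#' @param y binary outcomes.
#' @param pt_grid threshold probabilities (default 0.01 to 0.50 by 0.01);
#'   values of 1 are excluded.
#' @return data.frame: pt, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(oof_probs, y,
                           pt_grid = seq(0.01, 0.50, by = 0.01)) {
  stopifnot(all(oof_probs >= 0 & oof_probs <= 1))
  y <- as.integer(as.logical(y))
  pt_grid <- pt_grid[pt_grid < 1]
  n <- length(y)
  prev <- mean(y)
  rows <- lapply(pt_grid, function(pt) {
    pred <- oof_probs >= pt
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    odds <- pt / (1 - pt)
    data.frame(pt = pt,
               net_benefit = tp / n - (fp / n) * odds,
               treat_all = prev - (1 - prev) * odds,
               treat_none = 0)
  })
  do.call(rbind, rows)
}

#' Operating points of an out-of-fold probability classifier
#'
#' Three prespecified rows: the Youden-optimal threshold, the
#' highest-sensitivity threshold with specificity >= 0.90, and the
#' highest-specificity threshold with sensitivity >= 0.90; the rule is
#' `prob >= threshold => AD`, with the constraints evaluated on the OOF set
#' itself. An unattainable constraint yields a row of missing metrics with
#' a warning.
#'
#' @param oof_probs probabilities.
#' @param y binary outcomes (both classes present).
#' @param min_spec,min_sens constraint levels (default 0.90).
#' @return data.frame: constraint, threshold, sensitivity, specificity,
#'   ppv, npv.
#' @export
operating_points <- function(oof_probs, y, min_spec = 0.90,
                             min_sens = 0.90) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  cand <- c(sort(unique(oof_probs)), Inf)
  grid <- lapply(cand, function(thr) {
    pred <- oof_probs >= thr
    m <- confusion_metrics(sum(pred & y == 1), sum(pred & y == 0),
                           sum(!pred & y == 0), sum(!pred & y == 1))
    data.frame(threshold = thr, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               youden_j = m$youden_j)
  })
  grid <- do.call(rbind, grid)
  na_row <- function(constraint) {
    data.frame(constraint = constraint, threshold = NA_real_,
               sensitivity = NA_real_, specificity = NA_real_,
               ppv = NA_real_, npv = NA_real_)
  }
  take <- function(df, constraint) {
    data.frame(constraint = constraint,
               df[, c("threshold", "sensitivity", "specificity",
                      "ppv", "npv")])
  }
  youden <- grid[which.max(grid$youden_j), ]
  ok_spec <- grid[grid$specificity >= min_spec, , drop = FALSE]
  row_spec <- if (nrow(ok_spec)) {
    take(ok_spec[which.max(ok_spec$sensitivity), ],
         sprintf("specificity>=%.2f", min_spec))
  } else {
    warning("specificity constraint unattainable")
    na_row(sprintf("specificity>=%.2f", min_spec))
  }
  ok_sens <- grid[grid$sensitivity >= min_sens, , drop = FALSE]
  row_sens <- if (nrow(ok_sens)) {
    take(ok_sens[which.max(ok_sens$specificity), ],
         sprintf("sensitivity>=%.2f", min_sens))
  } else {
    warning("sensitivity constraint unattainable")
    na_row(sprintf("sensitivity>=%.2f", min_sens))
  }
  out <- rbind(take(youden, "youden"), row_spec, row_sens)
  rownames(out) <- NULL
  out
}
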