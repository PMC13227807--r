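#' Log2 transform and quantile-normalize an expression matrix
#'
#' After optional log2 transformation, every sample's sorted value vector is
#' replaced by the across-sample mean of sorted vectors (ties share the mean
#' of their tied target positions). Feature and sample IDs are preserved.
#'
#' @param expr features x samples numeric matrix.
#' @param already_log2 if `FALSE` (default) values must be strictly positive
#'   and are log2-transformed first.
#' @return normalized matrix, log2 scale.
#' @export
normalize_log2_quantile <- function(expr, already_log2 = FALSE) {
  check_expr(expr)
  if (!already_log2) {
    if (any(expr <= 0, na.rm = TRUE)) {
      stop("non-positive values: data cannot be log2-transformed")
    }
    expr <- log2(expr)
  }
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Filter features by row standard deviation
#'
#' Retains features whose row SD is at least the given quantile (linear
#' interpolation definition) of all row SDs; feature order is preserved.
#' All-missing rows are excluded with a warning.
#'
#' @param expr features x samples matrix (>= 2 samples).
#' @param quantile fraction in `[0, 1]`; default 0.25 (Q25 threshold).
#' @return filtered matrix.
#' @export
filter_by_rowsd <- function(expr, quantile = 0.25) {
  check_expr(expr)
  if (ncol(expr) < 2) stop("need >= 2 samples to compute row SDs")
  stopifnot(quantile >= 0, quantile <= 1)
  sds <- apply(expr, 1, stats::sd, na.rm = TRUE)
  if (anyNA(sds)) {
    warning(sum(is.na(sds)), " all-missing or single-value feature(s) excluded")
  }
  keep <- !is.na(sds)
  thr <- stats::quantile(sds[keep], probs = quantile, type = 7, names = FALSE)
  expr[keep & sds >= thr, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# Solve trigamma(y) = x by Newton iteration on the inverse scale.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment estimation of the scaled inverse-chi-square prior for residual
# variances, on the log scale (optionally with a lowess mean-expression
# trend). Returns d0 (possibly Inf) and s0_sq (scalar, or per-feature vector
# when a trend is fitted).
estimate_variance_prior <- function(s2, df, trend_covariate = NULL,
                                    span = 0.5) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) stop("too few positive residual variances for moderation")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (!is.null(trend_covariate)) {
    a <- trend_covariate[ok]
    fit <- stats::lowess(a, e, f = span)
    emean <- stats::approx(fit$x, fit$y, xout = trend_covariate,
                           rule = 2, ties = mean)$y
    resid_e <- e - emean[ok]
  } else {
    emean <- rep(mean(e), length(s2))
    resid_e <- e - mean(e)
  }
  n <- length(resid_e)
  evar <- sum(resid_e^2) / (n - 1) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Build the DE design matrix: intercept, AD indicator, then covariates.
build_de_design <- function(pheno, covariates, apoe_coding) {
  cols <- list(`(Intercept)` = rep(1, nrow(pheno)),
               diagnosisAD = as.numeric(pheno$diagnosis == "AD"))
  if ("age" %in% covariates) cols$age <- pheno$age
  if ("sex" %in% covariates) {
    cols$sexfemale <- as.numeric(pheno$sex == "female")
  }
  if ("apoe4" %in% covariates && apoe_coding != "excluded") {
    if (apoe_coding == "continuous") {
      cols$apoe4 <- as.numeric(pheno$apoe4)
    } else {
      cols$apoe4_1 <- as.numeric(pheno$apoe4 == 1)
      cols$apoe4_2 <- as.numeric(pheno$apoe4 == 2)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Covariate-adjusted moderated differential expression
#'
#' Fits, per feature, ordinary (optionally weighted) least squares on the
#' design `[intercept, diagnosis, covariates]`, then shrinks residual
#' variances toward an empirical-Bayes prior: `s_tilde^2 =
#' (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` with `(d0, s0^2)` estimated by
#' moments on log residual variances. With `trend = TRUE` the prior variance
#' is a smooth (lowess, span 0.5) function of mean log2 expression. The
#' moderated t uses `s_tilde` with `d0 + d_g` degrees of freedom. The
#' diagnosis coefficient is reported as log2FC with AD-minus-control sign.
#'
#' Missing expression values are handled per feature (complete cases within
#' feature); features with fewer than `min_group_n` complete samples in
#' either group are dropped with a warning.
#'
#' @param expr features x samples log2 matrix.
#' @param pheno phenotype table matching the matrix columns.
#' @param covariates subset of `c("age", "sex", "apoe4")`.
#' @param apoe_coding `"categorical"` (0/1/2 as factor dummies),
#'   `"continuous"` (allele count as numeric), or `"excluded"`.
#' @param trend model the prior variance as a function of average
#'   expression (default `TRUE`).
#' @param sample_weights optional positive per-sample weights (uniform
#'   default).
#' @param robust reserved; robust hyperparameter estimation is not
#'   implemented and the flag is ignored with a warning.
#' @param d0_override force the prior degrees of freedom (0 disables
#'   moderation, giving ordinary per-feature t statistics).
#' @param min_group_n minimum complete samples per group per feature.
#' @return list with `results` (data.frame: feature_id, log2fc, avg_expr,
#'   t_mod, p, q) and `priors` (list: d0, s0_sq).
#' @export
fit_moderated_de <- function(expr, pheno,
                             covariates = c("age", "sex", "apoe4"),
                             apoe_coding = c("categorical", "continuous",
                                             "excluded"),
                             trend = TRUE, sample_weights = NULL,
                             robust = FALSE, d0_override = NULL,
                             min_group_n = 10) {
  check_expr(expr)
  check_pheno(pheno, expr)
  apoe_coding <- match.arg(apoe_coding)
  if (length(covariates)) {
    covariates <- match.arg(covariates, c("age", "sex", "apoe4"),
                            several.ok = TRUE)
  }
  if (robust) {
    warning("robust hyperparameter estimation is not implemented; ",
            "proceeding with the plain empirical-Bayes fit")
    robust <- FALSE
  }
  pheno <- pheno[match(colnames(expr), pheno$sample_id), , drop = FALSE]
  if (min(table(pheno$diagnosis)) < 2) {
    stop("need >= 2 samples per diagnosis group")
  }
  if (is.null(sample_weights)) sample_weights <- rep(1, ncol(expr))
  if (any(sample_weights <= 0) || length(sample_weights) != ncol(expr)) {
    stop("sample_weights must be positive, one per sample")
  }

  X <- build_de_design(pheno, covariates, apoe_coding)
  p_des <- ncol(X)
  is_ad <- pheno$diagnosis == "AD"

  # group-wise complete counts per feature
  obs <- !is.na(expr)
  n_ad_ok <- rowSums(obs[, is_ad, drop = FALSE])
  n_ctl_ok <- rowSums(obs[, !is_ad, drop = FALSE])
  keep <- n_ad_ok >= min_group_n & n_ctl_ok >= min_group_n
  if (any(!keep)) {
    warning(sum(!keep), " feature(s) dropped: fewer than ", min_group_n,
            " complete samples in a diagnosis group")
    expr <- expr[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
  }
  if (nrow(expr) == 0) stop("no features left to fit")

  nfeat <- nrow(expr)
  coef_diag <- se_unscaled <- s2 <- df_resid <- rep(NA_real_, nfeat)
  avg_expr <- rowMeans(expr, na.rm = TRUE)

  w <- sample_weights
  sw <- sqrt(w)
  complete <- rowSums(obs) == ncol(expr)

  if (any(complete)) {
    Xw <- X * sw
    XtXinv <- chol2inv(chol(crossprod(Xw)))
    pinv <- XtXinv %*% t(Xw)                      # p x n
    Yw <- expr[complete, , drop = FALSE] * rep(sw, each = sum(complete))
    B <- Yw %*% t(pinv)                           # features x p
    fitted <- B %*% t(Xw)
    res <- Yw - fitted
    df <- ncol(expr) - p_des
    coef_diag[complete] <- B[, 2]           # column 2 = diagnosisAD
    se_unscaled[complete] <- sqrt(XtXinv[2, 2])
    s2[complete] <- rowSums(res^2) / df
    df_resid[complete] <- df
  }
  for (i in which(!complete)) {
    ok <- obs[i, ]
    fit <- stats::lm.wfit(X[ok, , drop = FALSE], expr[i, ok], w[ok])
    XtXinv_i <- chol2inv(chol(crossprod(X[ok, , drop = FALSE] * sqrt(w[ok]))))
    coef_diag[i] <- fit$coefficients["diagnosisAD"]
    se_unscaled[i] <- sqrt(XtXinv_i[2, 2])
    df_resid[i] <- sum(ok) - p_des
    s2[i] <- sum(w[ok] * fit$residuals^2) / df_resid[i]
  }

  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_sq <- mean(s2)
  } else {
    prior <- estimate_variance_prior(
      s2, df_resid, trend_covariate = if (trend) avg_expr else NULL)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  }
  s0_vec <- if (length(s0_sq) == 1) rep(s0_sq, nfeat) else s0_sq
  if (is.infinite(d0)) {
    s2_post <- s0_vec
    df_total <- rep(Inf, nfeat)
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- df_resid
  } else {
    s2_post <- (d0 * s0_vec + df_resid * s2) / (d0 + df_resid)
    df_total <- d0 + df_resid
  }
  t_mod <- coef_diag / (se_unscaled * sqrt(s2_post))
  pval <- 2 * stats::pt(-abs(t_mod), df = df_total)

  results <- data.frame(
    feature_id = rownames(expr),
    log2fc = coef_diag,
    avg_expr = avg_expr,
    t_mod = t_mod,
    p = pval,
    q = bh_adjust(pval),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(results = results,
       priors = list(d0 = d0,
                     s0_sq = if (length(s0_sq) == 1) s0_sq else
                       stats::median(s0_sq)))
}

#' Compare two differential-expression covariate models
#'
#' Jaccard overlap of the significant feature sets (q < alpha) and Spearman
#' correlation of log2FC over features present in both results.
#'
#' @param res_a,res_b DE result data.frames (as in [fit_moderated_de()]).
#' @param alpha significance level on q (default 0.05).
#' @return list: `jaccard` (NA when both significant sets are empty),
#'   `spearman_log2fc`, `n_sig_a`, `n_sig_b`.
#' @export
compare_covariate_models <- function(res_a, res_b, alpha = 0.05) {
  stopifnot(nrow(res_a) >= 1, nrow(res_b) >= 1)
  sig_a <- res_a$feature_id[res_a$q < alpha]
  sig_b <- res_b$feature_id[res_b$q < alpha]
  uni <- union(sig_a, sig_b)
  jaccard <- if (length(uni) == 0) NA_real_ else
    length(intersect(sig_a, sig_b)) / length(uni)
  shared <- intersect(res_a$feature_id, res_b$feature_id)
  rho <- if (length(shared) >= 2) {
    stats::cor(res_a$log2fc[match(shared, res_a$feature_id)],
               res_b$log2fc[match(shared, res_b$feature_id)],
               method = "spearman")
  } else NA_real_
  list(jaccard = jaccard, spearman_log2fc = rho,
       n_sig_a = length(sig_a), n_sig_b = length(sig_b))
}
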