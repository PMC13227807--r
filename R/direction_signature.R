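#' Per-member directional consistency of candidate miRNAs
#'
#' A member of the positively correlated set (positive correlation with
#' cognitive score) is expected to be down-regulated in AD, so it is
#' consistent iff `q < alpha` and `log2fc < 0`; the negatively correlated
#' set expects `log2fc > 0`. Members absent from the DE results are listed
#' with `present = FALSE` rather than raising an error.
#'
#' @param de DE result data.frame ([fit_moderated_de()] `$results`).
#' @param sets candidate set data.frame (feature_id, direction).
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame: feature_id, direction, present, log2fc, q, consistent.
#' @export
assess_direction <- function(de, sets, alpha = 0.05) {
  idx <- match(sets$feature_id, de$feature_id)
  present <- !is.na(idx)
  log2fc <- de$log2fc[idx]
  q <- de$q[idx]
  expected <- ifelse(sets$direction == "positive", -1, +1)
  consistent <- ifelse(present, q < alpha & sign(log2fc) == expected, NA)
  data.frame(feature_id = sets$feature_id, direction = sets$direction,
             present = present, log2fc = log2fc, q = q,
             consistent = consistent, stringsAsFactors = FALSE)
}

#' Mean-rank gene set test
#'
#' Wilcoxon rank-sum comparison of the set members' statistics against all
#' remaining features, using the normal approximation with tie and
#' continuity corrections; one-sided per `alternative`. The two one-sided
#' p-values sum to one plus the (continuity-correction) point mass at the
#' observed rank sum.
#'
#' @param stats named numeric vector of per-feature statistics over the
#'   whole (post-filter) feature universe.
#' @param set feature IDs (or logical/integer index into `stats`).
#' @param alternative `"greater"` (set shifted up) or `"less"`.
#' @return one-sided p-value.
#' @export
mean_rank_set_test <- function(stats, set,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.character(set)) {
    if (is.null(names(stats))) stop("stats must be named to index by ID")
    in_set <- names(stats) %in% set
  } else if (is.logical(set)) {
    in_set <- set
  } else {
    in_set <- seq_along(stats) %in% set
  }
  n <- length(stats)
  m <- sum(in_set)
  if (m < 1) stop("empty set")
  if (m >= n) stop("set must not cover all features (no complement)")
  r <- rank(stats)
  W <- sum(r[in_set])
  mu <- m * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- m * (n - m) / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  # continuity correction keeps the approximation within 0.02 of the exact
  # enumeration down to n = 7
  if (alternative == "greater") {
    stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  } else {
    stats::pnorm((W - mu + 0.5) / sqrt(sigma2))
  }
}

#' One-tailed sign and signed-rank shift tests for one direction set
#'
#' The sign test is the exact binomial tail on the count of values matching
#' the expected sign (exact zeros dropped). The signed-rank test is a
#' one-sided Wilcoxon of the (sign-aligned) values against median 0, exact
#' for n <= 25, normal approximation with continuity correction otherwise.
#'
#' @param log2fc numeric values (e.g. log2 fold changes of set members).
#' @param expected_sign `+1` or `-1`.
#' @return list: `sign_test_p`, `signed_rank_p` (both `NA` when all values
#'   are zero).
#' @export
signed_shift_tests <- function(log2fc, expected_sign) {
  stopifnot(expected_sign %in% c(-1, 1))
  x <- log2fc[!is.na(log2fc)]
  nz <- x[x != 0]
  if (length(nz) == 0) {
    return(list(sign_test_p = NA_real_, signed_rank_p = NA_real_))
  }
  k <- sum(sign(nz) == expected_sign)
  sign_p <- stats::pbinom(k - 1, length(nz), 0.5, lower.tail = FALSE)
  aligned <- x * expected_sign
  sr_p <- suppressWarnings(stats::wilcox.test(
    aligned, mu = 0, alternative = "greater",
    exact = length(nz) <= 25, correct = TRUE)$p.value)
  list(sign_test_p = sign_p, signed_rank_p = sr_p)
}

#' Set-level directionality report
#'
#' Runs the mean-rank set test (preferring moderated t, falling back to
#' log2FC), the one-tailed sign test and the one-sided signed-rank test for
#' each direction set, with the one-sided alternative implied by the
#' expected shift (positive set: down in AD; negative set: up).
#'
#' @param de DE result data.frame over the post-filter feature universe.
#' @param sets candidate set data.frame (feature_id, direction).
#' @param alpha FDR level for the per-member consistency flags.
#' @return list with `members` (per-member flags, [assess_direction()]) and
#'   `sets` (data.frame: direction, n_present, n_consistent, mean_rank_p,
#'   sign_test_p, signed_rank_p).
#' @export
direction_report <- function(de, sets, alpha = 0.05) {
  members <- assess_direction(de, sets, alpha)
  stat <- if (all(is.finite(de$t_mod))) de$t_mod else de$log2fc
  names(stat) <- de$feature_id
  rows <- lapply(c("positive", "negative"), function(dir) {
    ids <- intersect(sets$feature_id[sets$direction == dir], de$feature_id)
    alt <- if (dir == "positive") "less" else "greater"
    expected <- if (dir == "positive") -1 else +1
    mr <- if (length(ids) >= 1 && length(ids) < length(stat)) {
      mean_rank_set_test(stat, ids, alternative = alt)
    } else NA_real_
    sh <- signed_shift_tests(de$log2fc[match(ids, de$feature_id)], expected)
    data.frame(direction = dir, n_present = length(ids),
               n_consistent = sum(members$consistent[
                 members$direction == dir], na.rm = TRUE),
               mean_rank_p = mr, sign_test_p = sh$sign_test_p,
               signed_rank_p = sh$signed_rank_p, stringsAsFactors = FALSE)
  })
  list(members = members, sets = do.call(rbind, rows))
}

#' Weighted signature score
#'
#' Each candidate feature is z-scored across all samples (so the score needs
#' no label knowledge); the per-sample score is the mean z-value of the
#' negatively correlated set (weight +1) minus the mean z-value of the
#' positively correlated set (weight -1). Zero-SD features are excluded
#' with a warning.
#'
#' @param expr features x samples log2 matrix.
#' @param sets candidate set data.frame (feature_id, direction).
#' @return list: `scores` (named per-sample vector) and `used` (feature IDs
#'   entering each set mean).
#' @export
compute_signature_score <- function(expr, sets) {
  check_expr(expr)
  pick <- function(dir) intersect(sets$feature_id[sets$direction == dir],
                                  rownames(expr))
  pos <- pick("positive")
  neg <- pick("negative")
  if (length(pos) + length(neg) == 0) {
    stop("no candidate set member present in the expression matrix")
  }
  zrow <- function(ids) {
    if (!length(ids)) return(NULL)
    m <- expr[ids, , drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    sd <- apply(m, 1, stats::sd, na.rm = TRUE)
    bad <- !is.finite(sd) | sd == 0
    if (any(bad)) {
      warning("excluding zero-SD feature(s): ",
              paste(ids[bad], collapse = ", "))
      m <- m[!bad, , drop = FALSE]
      mu <- mu[!bad]
      sd <- sd[!bad]
    }
    if (!nrow(m)) return(NULL)
    (m - mu) / sd
  }
  zpos <- zrow(pos)
  zneg <- zrow(neg)
  if (is.null(zpos) && is.null(zneg)) stop("all set members have zero SD")
  mean0 <- function(z) if (is.null(z)) 0 else colMeans(z, na.rm = TRUE)
  scores <- mean0(zneg) - mean0(zpos)
  if (length(scores) == 1 && is.numeric(scores) && is.null(names(scores))) {
    names(scores) <- colnames(expr)
  }
  list(scores = stats::setNames(as.numeric(scores), colnames(expr)),
       used = list(positive = if (is.null(zpos)) character()
                   else rownames(zpos),
                   negative = if (is.null(zneg)) character()
                   else rownames(zneg)))
}

#' Covariate-adjusted group effect of the signature score
#'
#' Ordinary least squares of the per-sample score on diagnosis (AD = 1),
#' age, sex and APOE epsilon-4 allele count; reports the diagnosis
#' coefficient and its two-sided p-value.
#'
#' @param score named per-sample numeric vector.
#' @param pheno phenotype table.
#' @return list: `coefficient`, `p`, `fit` (the `lm` object).
#' @export
test_signature_association <- function(score, pheno) {
  check_pheno(pheno)
  pheno <- pheno[match(names(score), pheno$sample_id), , drop = FALSE]
  df <- data.frame(score = as.numeric(score),
                   diagnosis = as.numeric(pheno$diagnosis == "AD"),
                   age = pheno$age,
                   sex = as.numeric(pheno$sex == "female"),
                   apoe4 = as.numeric(pheno$apoe4))
  X <- stats::model.matrix(~ diagnosis + age + sex + apoe4, df)
  if (qr(X)$rank < ncol(X)) stop("collinear design for the score model")
  fit <- stats::lm(score ~ diagnosis + age + sex + apoe4, data = df)
  sm <- summary(fit)$coefficients
  list(coefficient = sm["diagnosis", "Estimate"],
       p = sm["diagnosis", "Pr(>|t|)"],
       fit = fit)
}
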