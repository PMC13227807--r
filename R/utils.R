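#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds so that both classes are spread
#' as evenly as possible across folds.
#'
#' @param y binary vector (two levels) of class labels.
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, same length as `y`.
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("stratified_folds() needs exactly two classes")
  if (min(table(y)) < k) {
    stop("each class must have at least k = ", k,
         " members; use a smaller k")
  }
  folds <- integer(length(y))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Derive a per-stage seed from a top-level seed
#'
#' Deterministically maps (seed, label) to a new 31-bit seed so that stages
#' of the pipeline draw from decoupled random streams.
#'
#' @param seed integer top-level seed.
#' @param label character tag (e.g. stage name).
#' @return integer seed in `[0, 2^31)`.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# Set the RNG to a fixed state and return a restorer function; keeps the
# caller's global RNG stream untouched.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

# Validate a features-x-samples expression matrix.
check_expr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate feature IDs")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample IDs")
  invisible(expr)
}

# Validate a phenotype table against an expression matrix.
check_pheno <- function(pheno, expr = NULL) {
  need <- c("sample_id", "diagnosis", "age", "sex", "apoe4")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(pheno$sample_id)) stop("duplicate sample IDs in phenotype")
  if (anyNA(pheno$diagnosis)) stop("missing diagnosis values")
  if (!all(pheno$diagnosis %in% c("AD", "control"))) {
    stop("diagnosis must be 'AD' or 'control'")
  }
  if (!is.null(expr) && !setequal(colnames(expr), pheno$sample_id)) {
    stop("phenotype sample IDs do not match expression matrix columns")
  }
  invisible(pheno)
}

# 0/1 diagnosis indicator (AD = 1), aligned to `sample_ids` when given.
diagnosis_indicator <- function(pheno, sample_ids = NULL) {
  if (!is.null(sample_ids)) {
    pheno <- pheno[match(sample_ids, pheno$sample_id), , drop = FALSE]
  }
  as.integer(pheno$diagnosis == "AD")
}
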