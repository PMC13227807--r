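# Small cohort fixtures shared across tests; everything generated in code.

tiny_cohort <- function(seed = 1, n_ad = 40, n_control = 30,
                        n_features = 60, ...) {
  args <- list(n_ad = n_ad, n_control = n_control,
               n_features = n_features, seed = seed, ...)
  if (n_features < nrow(default_candidate_sets())) {
    # too few features for the full default candidate set: shrink it
    args$candidate_positive <- args$candidate_positive %||% "cand-pos"
    args$candidate_negative <- args$candidate_negative %||% "cand-neg"
    args$effect_sizes <- args$effect_sizes %||%
      c(`cand-pos` = -0.5, `cand-neg` = 0.5)
    args$cluster_spec <- args$cluster_spec %||% list()
  }
  generate_cohort(do.call(cohort_config, args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal phenotype table for hand-built expression matrices.
toy_pheno <- function(expr, diagnosis = NULL, seed = 1) {
  n <- ncol(expr)
  if (is.null(diagnosis)) diagnosis <- rep(c("AD", "control"), length.out = n)
  set.seed(seed)
  data.frame(sample_id = colnames(expr), diagnosis = diagnosis,
             age = round(runif(n, 60, 90)),
             sex = sample(c("male", "female"), n, replace = TRUE),
             apoe4 = sample(0:2, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Named feature matrix from a numeric matrix.
as_expr <- function(m) {
  rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}
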