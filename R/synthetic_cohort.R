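#' Default literature-derived candidate miRNA sets
#'
#' Serum miRNAs reported to correlate with cognitive performance (MMSE) in
#' Alzheimer's disease, split by the sign of that correlation, together with
#' arm/family-expanded forms used when a platform carries arm-specific probes.
#' Positively correlated miRNAs are expected to be *down*-regulated in AD
#' serum; negatively correlated miRNAs are expected to be *up*-regulated.
#'
#' @return data.frame with columns `feature_id`, `direction`
#'   (`"positive"`/`"negative"`) and `expanded` (logical flag for
#'   arm/family-expanded additions). 32 rows.
#' @export
default_candidate_sets <- function() {
  pos <- c("miR-133b", "miR-137", "miR-148a-3p", "miR-193a-3p", "miR-202-3p",
           "miR-211-5p", "miR-211-3p", "miR-222-3p", "miR-223-3p",
           "miR-26b-5p", "miR-27a-3p", "miR-320a", "miR-331-3p", "miR-340-5p",
           "miR-511-3p", "miR-342-3p", "miR-222-5p", "miR-320b",
           "miR-148a-5p", "miR-27a-5p")
  pos_exp <- c("miR-211-5p", "miR-211-3p", "miR-222-5p", "miR-320b",
               "miR-148a-5p", "miR-27a-5p")
  neg <- c("miR-128-3p", "miR-128-1-5p", "miR-128-2-5p", "miR-9-5p",
           "miR-9-3p", "miR-138-5p", "miR-24-3p", "miR-28-3p", "miR-98-5p",
           "miR-142-5p", "miR-138-1-3p", "miR-24-2-5p")
  neg_exp <- c("miR-128-3p", "miR-128-1-5p", "miR-128-2-5p", "miR-9-5p",
               "miR-9-3p", "miR-138-1-3p", "miR-24-2-5p")
  data.frame(
    feature_id = c(pos, neg),
    direction  = rep(c("positive", "negative"), c(length(pos), length(neg))),
    expanded   = c(pos %in% pos_exp, neg %in% neg_exp),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic cohort configuration
#'
#' Defaults emulate the serum miRNA microarray cohort the workflow targets:
#' 1021 AD vs 288 control samples with strong age imbalance (AD location 80
#' vs control 71 years), a female-skewed AD group, APOE epsilon-4 enrichment
#' in AD, ~2500 background features carrying a 32-miRNA candidate set, one
#' large correlated candidate cluster, and group effects of 0.5 log2 units on
#' the candidates (positively correlated set down in AD, negatively
#' correlated set up).
#'
#' @param n_ad,n_control group sizes (each >= 2).
#' @param n_features total number of features including candidates.
#' @param candidate_positive,candidate_negative character vectors of feature
#'   IDs forming the two direction sets (disjoint).
#' @param age_params list with elements `ad` and `control`, each
#'   `c(location, scale)` in years; ages are drawn from a normal truncated to
#'   `age_bounds`.
#' @param age_bounds length-2 numeric truncation bounds in years.
#' @param female_prob named vector `c(ad=, control=)` of female probabilities.
#' @param apoe_probs list with `ad` and `control` 3-vectors of probabilities
#'   over APOE epsilon-4 allele counts 0/1/2 (each summing to 1).
#' @param cluster_spec list of `list(members=<ids>, rho=<target Spearman>)`
#'   blocks; members share a Gaussian latent factor.
#' @param effect_sizes named numeric vector of log2 fold changes (AD minus
#'   control) injected before noise.
#' @param noise_sd residual standard deviation in log2 units.
#' @param baseline_mean,baseline_sd distribution of per-feature baseline
#'   log2 intensities.
#' @param missing_rate fraction of cells set missing at random (default 0).
#' @param seed integer seed; the same config yields byte-identical cohorts.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_ad = 1021, n_control = 288, n_features = 2500,
                          candidate_positive = NULL, candidate_negative = NULL,
                          age_params = list(ad = c(80, 6), control = c(71, 6)),
                          age_bounds = c(55, 95),
                          female_prob = c(ad = 714 / 1021, control = 137 / 288),
                          apoe_probs = list(ad = c(577, 376, 68) / 1021,
                                            control = c(238, 46, 4) / 288),
                          cluster_spec = NULL,
                          effect_sizes = NULL,
                          noise_sd = 0.5,
                          baseline_mean = 7, baseline_sd = 1.5,
                          missing_rate = 0,
                          seed = 1L) {
  cand <- default_candidate_sets()
  if (is.null(candidate_positive)) {
    candidate_positive <- cand$feature_id[cand$direction == "positive"]
  }
  if (is.null(candidate_negative)) {
    candidate_negative <- cand$feature_id[cand$direction == "negative"]
  }
  if (is.null(effect_sizes)) {
    effect_sizes <- c(
      stats::setNames(rep(-0.5, length(candidate_positive)), candidate_positive),
      stats::setNames(rep(+0.5, length(candidate_negative)), candidate_negative)
    )
  }
  if (is.null(cluster_spec)) {
    members <- c(candidate_positive[seq_len(min(12, length(candidate_positive)))],
                 candidate_negative[seq_len(min(6, length(candidate_negative)))])
    cluster_spec <- list(list(members = members, rho = 0.85))
  }
  cfg <- structure(list(
    n_ad = as.integer(n_ad), n_control = as.integer(n_control),
    n_features = as.integer(n_features),
    candidate_positive = candidate_positive,
    candidate_negative = candidate_negative,
    age_params = age_params, age_bounds = age_bounds,
    female_prob = female_prob, apoe_probs = apoe_probs,
    cluster_spec = cluster_spec, effect_sizes = effect_sizes,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_ad < 2 || cfg$n_control < 2) {
    stop("n_ad and n_control must both be >= 2")
  }
  probs <- c(cfg$female_prob, unlist(cfg$apoe_probs), cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (g in c("ad", "control")) {
    if (abs(sum(cfg$apoe_probs[[g]]) - 1) > 1e-8) {
      stop("apoe_probs for group '", g, "' must sum to 1")
    }
  }
  if (length(intersect(cfg$candidate_positive, cfg$candidate_negative))) {
    stop("candidate sets must be disjoint")
  }
  cand <- c(cfg$candidate_positive, cfg$candidate_negative)
  if (anyDuplicated(cand)) stop("duplicate candidate feature IDs")
  if (length(cand) > cfg$n_features) {
    stop("n_features smaller than the candidate set")
  }
  feats <- cohort_feature_ids(cfg)
  for (cl in cfg$cluster_spec) {
    if (!all(cl$members %in% feats)) {
      stop("cluster members must be feature IDs of the cohort")
    }
    if (cl$rho < 0 || cl$rho > 1) stop("cluster rho must lie in [0, 1]")
  }
  if (!all(names(cfg$effect_sizes) %in% feats)) {
    stop("effect_sizes names must be feature IDs of the cohort")
  }
  cfg
}

# Candidates first (in config order), then numbered background features.
cohort_feature_ids <- function(cfg) {
  cand <- c(cfg$candidate_positive, cfg$candidate_negative)
  n_bg <- cfg$n_features - length(cand)
  c(cand, if (n_bg > 0) sprintf("miR-sim-%04d", seq_len(n_bg)))
}

# Truncated-normal ages by inverse-CDF sampling.
rtrunc_norm <- function(n, location, scale, lower, upper) {
  lo <- stats::pnorm((lower - location) / scale)
  hi <- stats::pnorm((upper - location) / scale)
  location + scale * stats::qnorm(stats::runif(n, lo, hi))
}

#' Generate a synthetic serum-miRNA cohort
#'
#' Draws covariates per diagnosis group (truncated-normal age, Bernoulli sex,
#' categorical APOE epsilon-4 count), then builds a log2-scale expression
#' matrix as baseline + group effect + correlated noise. Members of a
#' configured cluster share a Gaussian latent factor with loading
#' `sqrt(rho)`, so the expected pairwise correlation within the cluster
#' equals `rho`. Features listed in `effect_sizes` have a true AD-minus-
#' control mean difference exactly equal to the configured log2FC before
#' noise. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()] object.
#' @return list with `expr` (features x samples numeric matrix, log2 scale)
#'   and `pheno` (data.frame: sample_id, diagnosis, age, sex, apoe4).
#' @examples
#' cfg <- cohort_config(n_ad = 30, n_control = 20, n_features = 50, seed = 7)
#' cohort <- generate_cohort(cfg)
#' dim(cohort$expr)
#' table(cohort$pheno$diagnosis)
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  n <- config$n_ad + config$n_control
  sample_id <- sprintf("S%05d", seq_len(n))
  diagnosis <- rep(c("AD", "control"), c(config$n_ad, config$n_control))

  age <- numeric(n)
  sex <- character(n)
  apoe4 <- integer(n)
  for (g in c("ad", "control")) {
    idx <- which(diagnosis == ifelse(g == "ad", "AD", "control"))
    ap <- config$age_params[[g]]
    age[idx] <- rtrunc_norm(length(idx), ap[1], ap[2],
                            config$age_bounds[1], config$age_bounds[2])
    sex[idx] <- ifelse(stats::runif(length(idx)) < config$female_prob[[g]],
                       "female", "male")
    apoe4[idx] <- sample(0:2, length(idx), replace = TRUE,
                         prob = config$apoe_probs[[g]])
  }
  pheno <- data.frame(sample_id = sample_id, diagnosis = diagnosis,
                      age = age, sex = sex, apoe4 = apoe4,
                      stringsAsFactors = FALSE)

  feats <- cohort_feature_ids(config)
  p <- length(feats)
  baseline <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
  expr <- matrix(baseline, nrow = p, ncol = n,
                 dimnames = list(feats, sample_id))
  is_ad <- diagnosis == "AD"
  if (length(config$effect_sizes)) {
    expr[names(config$effect_sizes), is_ad] <-
      expr[names(config$effect_sizes), is_ad] + config$effect_sizes
  }

  noise <- matrix(stats::rnorm(p * n), nrow = p,
                  dimnames = list(feats, sample_id))
  for (cl in config$cluster_spec) {
    lambda <- sqrt(cl$rho)
    z <- stats::rnorm(n)
    noise[cl$members, ] <-
      lambda * matrix(z, nrow = length(cl$members), ncol = n, byrow = TRUE) +
      sqrt(1 - lambda^2) * noise[cl$members, , drop = FALSE]
  }
  expr <- expr + config$noise_sd * noise

  if (config$missing_rate > 0) {
    drop <- stats::runif(p * n) < config$missing_rate
    expr[drop] <- NA_real_
  }

  list(expr = expr, pheno = pheno)
}
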