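#' Configuration for cluster-constrained panel selection
#'
#' @param outer_folds,repeats outer cross-validation layout; the default
#'   5 folds x 4 repeats gives 20 outer training runs.
#' @param inner_folds folds of the inner CV scoring each candidate gain.
#' @param delta_min minimum cross-validated AUC gain to admit a candidate
#'   (default 0.005).
#' @param delta_within_cluster stricter gain gate for a candidate whose
#'   cluster already holds a selected member (default 0.010; must be >=
#'   `delta_min`).
#' @param baseline clinical covariates always in the model: subset of
#'   `c("age", "sex")` or empty.
#' @param cluster_mode `"add"`: a second same-cluster member may join via
#'   the stricter gate; `"replace"`: a same-cluster candidate may only swap
#'   with the resident member (accepted when the swap gains >= `delta_min`).
#' @param strength,l1_ratio fixed elastic-net penalty used inside the
#'   greedy loop (full tuning happens in final evaluation).
#' @param seed integer seed.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(outer_folds = 5, repeats = 4, inner_folds = 5,
                             delta_min = 0.005, delta_within_cluster = 0.010,
                             baseline = "age",
                             cluster_mode = c("add", "replace"),
                             strength = 0.01, l1_ratio = 0.5, seed = 1L) {
  cluster_mode <- match.arg(cluster_mode)
  if (!(delta_within_cluster >= delta_min && delta_min > 0)) {
    stop("need delta_within_cluster >= delta_min > 0")
  }
  if (outer_folds < 2 || inner_folds < 2) stop("folds must be >= 2")
  if (length(baseline)) {
    baseline <- match.arg(baseline, c("age", "sex"), several.ok = TRUE)
  }
  structure(list(outer_folds = outer_folds, repeats = repeats,
                 inner_folds = inner_folds, delta_min = delta_min,
                 delta_within_cluster = delta_within_cluster,
                 baseline = baseline, cluster_mode = cluster_mode,
                 strength = strength, l1_ratio = l1_ratio,
                 seed = as.integer(seed)),
            class = "selection_config")
}

# Pooled OOF AUC of the fixed-penalty elastic net over given folds.
# An empty predictor set scores an uninformative 0.5.
cv_auc_fixed <- function(X, y, folds, config) {
  if (is.null(X) || ncol(X) == 0) return(0.5)
  probs <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_penalized_logistic(X[tr, , drop = FALSE], y[tr],
                                  l1_ratio = config$l1_ratio,
                                  strength = config$strength,
                                  class_weighting = TRUE)
    probs[!tr] <- stats::predict(fit, X[!tr, , drop = FALSE])
  }
  rank_metrics(probs, y)$auc
}

# Cluster id lookup; features outside the map are their own singleton.
cluster_of <- function(ids, clusters) {
  asg <- if (inherits(clusters, "cluster_map")) clusters$assignments
         else clusters
  out <- asg[ids]
  out[is.na(out)] <- ids[is.na(out)]
  stats::setNames(as.character(out), ids)
}

#' Greedy cluster-constrained forward selection on one training fold
#'
#' At each step every remaining candidate's inner-CV AUC gain over the
#' current model (baseline covariates + selected features) is evaluated;
#' the best candidate is accepted iff its gain meets `delta_min`, or the
#' stricter `delta_within_cluster` when its cluster already holds a
#' selected member (the one-representative-per-cluster rule, relaxed only
#' through the stricter gate). Selection stops when no candidate passes.
#' Ties break toward higher univariate CV-AUC, then lexicographic feature
#' ID. Deterministic given `config$seed`.
#'
#' @param train_expr features x samples matrix (training samples only).
#' @param train_pheno matching phenotype rows.
#' @param candidates candidate feature IDs.
#' @param clusters a `cluster_map` (or named assignment vector).
#' @param config a [selection_config()].
#' @param seed optional seed override for the inner folds.
#' @return character vector of selected features, in selection order.
#' @export
forward_select_fold <- function(train_expr, train_pheno, candidates,
                                clusters, config, seed = config$seed) {
  candidates <- intersect(candidates, rownames(train_expr))
  if (length(candidates) == 0) return(character())
  y <- diagnosis_indicator(train_pheno, colnames(train_expr))
  folds <- stratified_folds(y, config$inner_folds,
                            derive_seed(seed, "forward"))
  Xall <- build_predictor_matrix(train_expr, train_pheno, candidates,
                                 config$baseline)
  base_cols <- setdiff(colnames(Xall), candidates)
  clu <- cluster_of(candidates, clusters)
  univ <- vapply(candidates, function(cand) {
    cv_auc_fixed(Xall[, cand, drop = FALSE], y, folds, config)
  }, numeric(1))

  selected <- character()
  current_auc <- cv_auc_fixed(
    if (length(base_cols)) Xall[, base_cols, drop = FALSE] else NULL,
    y, folds, config)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    gains <- vapply(remaining, function(cand) {
      cols <- c(base_cols, selected, cand)
      cv_auc_fixed(Xall[, cols, drop = FALSE], y, folds, config) - current_auc
    }, numeric(1))
    gate <- ifelse(clu[remaining] %in% clu[selected],
                   config$delta_within_cluster, config$delta_min)
    if (config$cluster_mode == "replace") {
      # same-cluster candidates may only swap with the resident member
      swap <- clu[remaining] %in% clu[selected]
      gains[swap] <- vapply(remaining[swap], function(cand) {
        resident <- selected[clu[selected] == clu[cand]][1]
        cols <- c(base_cols, setdiff(selected, resident), cand)
        cv_auc_fixed(Xall[, cols, drop = FALSE], y, folds, config) -
          current_auc
      }, numeric(1))
      gate[swap] <- config$delta_min
    }
    pass <- gains >= gate
    if (!any(pass)) break
    ord <- order(-gains[pass], -univ[remaining[pass]], remaining[pass])
    best <- remaining[pass][ord[1]]
    if (config$cluster_mode == "replace" && clu[best] %in% clu[selected]) {
      resident <- selected[clu[selected] == clu[best]][1]
      selected <- c(setdiff(selected, resident), best)
    } else {
      selected <- c(selected, best)
    }
    remaining <- setdiff(remaining, best)
    current_auc <- cv_auc_fixed(Xall[, c(base_cols, selected), drop = FALSE],
                                y, folds, config)
  }
  selected
}

#' Aggregate per-run selections into a frequency panel
#'
#' Within each run unit (outer fold x repeat x model) a feature counts at
#' most once; counts are summed across run units, then cluster-level
#' deduplication keeps the highest-frequency member per cluster (ties:
#' higher univariate CV-AUC, then lexicographic ID).
#'
#' @param selections list of character vectors, one per run unit.
#' @param clusters a `cluster_map` (or named assignment vector).
#' @param univ_auc optional named vector of univariate CV-AUCs for
#'   tie-breaking.
#' @return data.frame: feature_id, count, n_runs, cluster; ordered by
#'   non-increasing count.
#' @export
aggregate_panel <- function(selections, clusters, univ_auc = NULL) {
  stopifnot(length(selections) >= 1)
  n_runs <- length(selections)
  dedup <- lapply(selections, unique)
  all_feats <- unique(unlist(dedup))
  if (!length(all_feats)) {
    return(data.frame(feature_id = character(), count = integer(),
                      n_runs = integer(), cluster = character()))
  }
  counts <- vapply(all_feats, function(fid) {
    sum(vapply(dedup, function(s) fid %in% s, logical(1)))
  }, integer(1))
  ua <- if (is.null(univ_auc)) stats::setNames(rep(0, length(all_feats)),
                                               all_feats)
        else univ_auc
  ord <- order(-counts, -ua[all_feats], all_feats)
  feats <- all_feats[ord]
  clu <- cluster_of(feats, clusters)
  keep <- !duplicated(clu)
  data.frame(feature_id = feats[keep], count = as.integer(counts[ord][keep]),
             n_runs = n_runs, cluster = as.character(clu[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-standard-error panel sizing on a K-AUC path
#'
#' The threshold is the best AUC on the path minus the fold SD of that best
#' K divided by `sqrt(n_folds)`; the selected K is the smallest K whose AUC
#' meets the threshold (K = 0 is the baseline-only model).
#'
#' @param k integer panel sizes (0..K_max; repeats allowed for alternative
#'   panels of the same size).
#' @param auc cross-validated AUC per entry.
#' @param sd_fold fold SD of the AUC per entry (scalar recycled).
#' @param n_folds number of CV folds behind each AUC.
#' @return list: `one_se_threshold`, `selected_k`, `path` (data.frame).
#' @export
select_k_one_se <- function(k, auc, sd_fold, n_folds) {
  stopifnot(length(k) == length(auc), length(k) >= 1)
  sd_fold <- rep_len(sd_fold, length(k))
  best <- which.max(auc)
  thr <- auc[best] - sd_fold[best] / sqrt(n_folds)
  meets <- auc >= thr
  selected_k <- min(k[meets])
  list(one_se_threshold = thr, selected_k = selected_k,
       path = data.frame(k = k, auc = auc, sd_fold = sd_fold,
                         meets_threshold = meets))
}

#' Nested-CV panel selection with frequency aggregation and 1-SE sizing
#'
#' Runs [forward_select_fold()] on every outer training fold across
#' repeats (no outer-test information enters selection), aggregates the
#' per-run selections into a frequency panel with cluster deduplication,
#' evaluates the K-AUC path over panel prefixes (K = 0 is the baseline
#' model) by cross-validation on the full data, and applies the 1-SE rule.
#'
#' @param expr features x samples matrix.
#' @param pheno phenotype table.
#' @param candidates candidate feature IDs.
#' @param clusters a `cluster_map` for the candidate set.
#' @param config a [selection_config()].
#' @return list of class `panel_path`: `frequency_panel`, `path`,
#'   `one_se_threshold`, `selected_k`, `panel` (the selected members),
#'   `selections` (per run unit).
#' @export
nested_panel_selection <- function(expr, pheno, candidates, clusters,
                                   config = selection_config()) {
  check_expr(expr)
  check_pheno(pheno, expr)
  y <- diagnosis_indicator(pheno, colnames(expr))
  selections <- list()
  for (r in seq_len(config$repeats)) {
    folds <- stratified_folds(y, config$outer_folds,
                              derive_seed(config$seed, paste0("outer", r)))
    for (f in seq_len(config$outer_folds)) {
      tr <- folds != f
      sel <- forward_select_fold(
        expr[, tr, drop = FALSE],
        pheno[match(colnames(expr)[tr], pheno$sample_id), , drop = FALSE],
        candidates, clusters, config,
        seed = derive_seed(config$seed, paste0("run", r, "_", f)))
      selections[[length(selections) + 1]] <- sel
    }
  }
  # univariate CV-AUCs on the full data, for tie-breaking
  folds_full <- stratified_folds(y, config$outer_folds,
                                 derive_seed(config$seed, "univ"))
  Xall <- build_predictor_matrix(expr, pheno,
                                 intersect(candidates, rownames(expr)),
                                 character())
  univ <- vapply(colnames(Xall), function(cand) {
    cv_auc_fixed(Xall[, cand, drop = FALSE], y, folds_full, config)
  }, numeric(1))

  freq <- aggregate_panel(selections, clusters, univ)
  k_max <- nrow(freq)
  folds_path <- stratified_folds(y, config$outer_folds,
                                 derive_seed(config$seed, "path"))
  path_rows <- lapply(0:k_max, function(k) {
    feats <- if (k > 0) freq$feature_id[seq_len(k)] else character()
    X <- build_predictor_matrix(expr, pheno, feats, config$baseline)
    fold_auc <- vapply(seq_len(config$outer_folds), function(f) {
      tr <- folds_path != f
      if (is.null(X) || ncol(X) == 0) return(0.5)
      fit <- fit_penalized_logistic(X[tr, , drop = FALSE], y[tr],
                                    l1_ratio = config$l1_ratio,
                                    strength = config$strength,
                                    class_weighting = TRUE)
      rank_metrics(stats::predict(fit, X[!tr, , drop = FALSE]), y[!tr])$auc
    }, numeric(1))
    data.frame(k = k, auc = mean(fold_auc), sd_fold = stats::sd(fold_auc))
  })
  path <- do.call(rbind, path_rows)
  one_se <- select_k_one_se(path$k, path$auc, path$sd_fold,
                            config$outer_folds)
  structure(list(
    frequency_panel = freq, path = path,
    one_se_threshold = one_se$one_se_threshold,
    selected_k = one_se$selected_k,
    panel = if (one_se$selected_k > 0)
      freq$feature_id[seq_len(one_se$selected_k)] else character(),
    selections = selections
  ), class = "panel_path")
}
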