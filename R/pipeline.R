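#' Run the full serum-miRNA panel workflow
#'
#' Executes, in order: synthesize (or load) the cohort, normalize and
#' variance-filter, moderated differential expression, directionality and
#' signature scoring, covariate diagnostics, correlation-network
#' clustering, cluster-constrained panel selection, and classifier
#' evaluation. Any stage can be skipped by name; every stage draws its
#' randomness from a seed derived from the single top-level seed, so a
#' config reruns to identical outputs.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized fields: `seed` (default 1), `out_dir` (default tempdir),
#'   `expression`/`phenotype` (paths of TSV inputs; omitted = synthesize),
#'   `cohort` (argument list for [cohort_config()]), `sd_quantile` (0.25),
#'   `alpha` (0.05), `covariates`, `apoe_coding`, `trend`,
#'   `thresholds` (network scan, default 0.90..0.70),
#'   `cluster_threshold` (0.80), `selection` (argument list for
#'   [selection_config()]), `n_boot` (200), `repeats` (1),
#'   `skip` (character vector of stage names).
#' @return list of class `run_manifest`: `config_digest`, `seed`,
#'   `version`, `stages` (per-stage status, outputs, row counts).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = file.path(tempdir(), "seromir-run"),
    sd_quantile = 0.25, alpha = 0.05,
    covariates = c("age", "sex", "apoe4"), apoe_coding = "categorical",
    trend = TRUE, thresholds = c(0.90, 0.85, 0.80, 0.75, 0.70),
    cluster_threshold = 0.80, n_boot = 200, repeats = 1,
    skip = character()
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  digest_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[order(names(cfg))], digest_file)
  digest <- unname(tools::md5sum(digest_file))
  unlink(digest_file)

  stages <- list()
  state <- new.env(parent = emptyenv())
  note <- function(name, status, outputs = character(), rows = NA) {
    stages[[name]] <<- list(stage = name, status = status,
                            outputs = outputs, rows = rows)
  }
  run_stage <- function(name, fun) {
    if (name %in% cfg$skip) {
      note(name, "skipped")
      return(invisible(NULL))
    }
    message("[seromir] stage ", name, " ...")
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message("[seromir] stage ", name, " done (",
            round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
            " s)")
  }
  tsv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    path
  }

  run_stage("synthesize", function() {
    if (!is.null(cfg$expression)) {
      state$expr <- read_expression(cfg$expression)
      state$pheno <- read_phenotype(cfg$phenotype)
      note("synthesize", "loaded", c(cfg$expression, cfg$phenotype),
           nrow(state$expr))
    } else {
      args <- cfg$cohort %||% list()
      args$seed <- derive_seed(cfg$seed, "synthesize")
      cohort <- generate_cohort(do.call(cohort_config, args))
      state$expr <- cohort$expr
      state$pheno <- cohort$pheno
      paths <- write_dataset(cohort$expr, cohort$pheno, cfg$out_dir)
      note("synthesize", "completed", unname(paths), nrow(state$expr))
    }
    state$sets <- default_candidate_sets()
  })

  run_stage("normalize", function() {
    norm <- normalize_log2_quantile(state$expr, already_log2 = TRUE)
    state$norm <- filter_by_rowsd(norm, cfg$sd_quantile)
    note("normalize", "completed", character(), nrow(state$norm))
  })

  run_stage("de", function() {
    de <- fit_moderated_de(state$norm, state$pheno,
                           covariates = cfg$covariates,
                           apoe_coding = cfg$apoe_coding, trend = cfg$trend)
    state$de <- de
    p <- tsv(de$results, "de_results.tsv")
    note("de", "completed", p, nrow(de$results))
  })

  run_stage("direction", function() {
    rep_ <- direction_report(state$de$results, state$sets, cfg$alpha)
    sig <- compute_signature_score(state$norm, state$sets)
    assoc <- test_signature_association(sig$scores, state$pheno)
    state$direction <- rep_
    p1 <- tsv(rep_$members, "direction_members.tsv")
    p2 <- tsv(rep_$sets, "direction_sets.tsv")
    p3 <- tsv(data.frame(sample_id = names(sig$scores),
                         score = sig$scores,
                         diagnosis_coefficient = assoc$coefficient,
                         diagnosis_p = assoc$p),
              "signature_scores.tsv")
    note("direction", "completed", c(p1, p2, p3), nrow(rep_$members))
  })

  run_stage("covariates", function() {
    pheno <- state$pheno
    y <- diagnosis_indicator(pheno)
    covs <- list(age = pheno$age,
                 sex = as.numeric(pheno$sex == "female"),
                 apoe4 = as.numeric(pheno$apoe4))
    rows <- lapply(names(covs), function(v) {
      rm_ <- rank_metrics(covs[[v]], y)
      yj <- youden_select(covs[[v]], y)
      cv <- crossval_univariate(covs[[v]], y, k = 5,
                                seed = derive_seed(cfg$seed, "covariates"))
      data.frame(covariate = v, auc = rm_$auc, ap = rm_$ap,
                 youden_threshold = yj$threshold_attained,
                 youden_j = yj$youden_j,
                 sensitivity = yj$sensitivity, specificity = yj$specificity,
                 cv_auc_mean = cv$mean[["auc"]], cv_auc_sd = cv$sd[["auc"]])
    })
    tab <- do.call(rbind, rows)
    cand <- intersect(state$sets$feature_id, rownames(state$norm))
    assoc <- do.call(rbind, lapply(c("age", "sex", "apoe4"), function(tg) {
      partial_rank_assoc(state$norm[cand, , drop = FALSE], pheno, tg)
    }))
    p1 <- tsv(tab, "covariate_diagnostics.tsv")
    p2 <- tsv(assoc, "mirna_covariate_assoc.tsv")
    note("covariates", "completed", c(p1, p2), nrow(tab))
  })

  run_stage("network", function() {
    cand <- intersect(state$sets$feature_id, rownames(state$norm))
    corr <- spearman_matrix(state$norm[cand, , drop = FALSE])
    scan <- scan_thresholds(corr, cfg$thresholds)
    state$clusters <- cluster_components(corr, cfg$cluster_threshold)
    p1 <- tsv(scan, "threshold_scan.tsv")
    p2 <- tsv(data.frame(feature_id = names(state$clusters$assignments),
                         cluster = state$clusters$assignments),
              "clusters.tsv")
    note("network", "completed", c(p1, p2), length(cand))
  })

  run_stage("select", function() {
    args <- cfg$selection %||% list()
    args$seed <- derive_seed(cfg$seed, "select")
    scfg <- do.call(selection_config, args)
    cand <- intersect(state$sets$feature_id, rownames(state$norm))
    clusters <- state$clusters %||%
      cluster_components(spearman_matrix(state$norm[cand, , drop = FALSE]),
                         cfg$cluster_threshold)
    res <- nested_panel_selection(state$norm, state$pheno, cand, clusters,
                                  scfg)
    state$panel <- res
    p1 <- tsv(res$frequency_panel, "frequency_panel.tsv")
    p2 <- tsv(res$path, "k_auc_path.tsv")
    note("select", "completed", c(p1, p2), nrow(res$frequency_panel))
  })

  run_stage("evaluate", function() {
    feats <- if (!is.null(state$panel)) state$panel$panel else character()
    spec <- model_spec(features = feats, baseline = c("age", "sex"),
                       seed = derive_seed(cfg$seed, "evaluate"))
    ev <- nested_oof_eval(state$norm, state$pheno, spec,
                          repeats = cfg$repeats, n_boot = cfg$n_boot)
    p1 <- tsv(data.frame(sample_id = names(ev$oof_probs),
                         oof_prob = ev$oof_probs, y = ev$y),
              "oof_probabilities.tsv")
    p2 <- tsv(ev$dca, "decision_curve.tsv")
    p3 <- tsv(ev$operating_points, "operating_points.tsv")
    p4 <- tsv(data.frame(auc = ev$auc, auc_ci_low = ev$auc_ci[1],
                         auc_ci_high = ev$auc_ci[2], ap = ev$ap,
                         brier = ev$brier, ece = ev$ece),
              "evaluation_summary.tsv")
    note("evaluate", "completed", c(p1, p2, p3, p4), length(ev$oof_probs))
  })

  manifest <- structure(list(
    config_digest = digest, seed = cfg$seed,
    version = as.character(utils::packageVersion("seromiR")),
    stages = stages
  ), class = "run_manifest")
  manifest_df <- do.call(rbind, lapply(stages, function(s) {
    data.frame(stage = s$stage, status = s$status,
               outputs = paste(s$outputs, collapse = ";"),
               rows = s$rows %||% NA)
  }))
  utils::write.table(manifest_df, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
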