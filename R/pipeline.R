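#' Run the full pipeline on a synthetic or user-supplied cohort
#'
#' Orchestrates the whole analysis: generate (or accept) a cohort and
#' test-retest pairs, extract the 233-feature vectors, filter features by
#' test-retest reproducibility (CCC, dynamic range) and redundancy, screen
#' the survivors per class pair with the Kruskal-Wallis test and per-feature
#' ROC, then train and evaluate the four classifiers on each pairwise task
#' with stratified 10-fold cross-validation, a held-out validation cohort,
#' and bootstrap stability.
#'
#' For each pairwise task the classifiers use the selected features that are
#' significant for that pair, capped at the `max_features` smallest p-values
#' (the study reduced the feature vector before modelling); if none are
#' significant the `max_features` smallest-p survivors are used.
#'
#' @param spec A [phantom_spec()] (ignored when `cohort` is supplied).
#' @param n_per_class,split Passed to [generate_cohort()].
#' @param n_retest Number of test-retest pairs (default 15).
#' @param cohort Optional pre-built `synthetic_cohort` (or list with `rois`
#'   and `cohort`) to analyse instead of generating one.
#' @param retest Optional pre-built list of test/retest `roi_image` pairs.
#' @param config Extraction configuration, see [default_config()].
#' @param models Classifier subset (default all four).
#' @param B Bootstrap resamples for stability (default 100).
#' @param k Cross-validation folds (default 10).
#' @param max_features Per-task feature cap (default 12).
#' @param ccc_min,dr_min,r2_max Selection thresholds.
#' @param alpha Screening significance level.
#' @param seed Seed for fold assignment, ANN initialization and bootstrap.
#' @return Object of class `livertex_report`: feature tables, selection
#'   report, screening table, per-feature ROC table, and per-task,
#'   per-model evaluations (`$models`) with stability results.
#' @export
run_pipeline <- function(spec = phantom_spec(),
                         n_per_class = c(classA = 55, classB = 67,
                                         classC = 40),
                         split = c(112, 50), n_retest = 15L,
                         cohort = NULL, retest = NULL,
                         config = default_config(),
                         models = classifier_models,
                         B = 100L, k = 10L, max_features = 12L,
                         ccc_min = 0.9, dr_min = 0.9, r2_max = 0.95,
                         alpha = 0.05, seed = spec$seed) {
  if (is.null(cohort)) cohort <- generate_cohort(spec, n_per_class, split)
  if (is.null(retest)) retest <- generate_test_retest(spec, n_retest)
  ft <- extract_cohort(cohort$rois, cohort$cohort, config)
  retest_tabs <- list(
    test = extract_cohort(lapply(retest, `[[`, "test"), "retest", config),
    retest = extract_cohort(lapply(retest, `[[`, "retest"), "retest", config))
  train_tab <- feature_table(as.data.frame(ft)[ft$cohort == "training", ])
  valid_tab <- feature_table(as.data.frame(ft)[ft$cohort == "validation", ])
  sel <- select_features(train_tab, retest_tabs, ccc_min, dr_min, r2_max)
  screen_feats <- if (length(sel$selected)) sel$selected
                  else feature_columns(train_tab)
  screening <- kw_screen(train_tab, screen_feats, alpha)
  # per-feature ROC for significant screen hits (oriented so AUC >= 0.5)
  roc_tab <- do.call(rbind, lapply(which(screening$significant), function(i) {
    f <- screening$feature[i]
    pr <- strsplit(screening$pair[i], " vs ")[[1]]
    sub <- as.data.frame(train_tab)[train_tab$label %in% pr, ]
    sc <- sub[[f]]; y <- sub$label == pr[2]
    rr <- roc_analysis(sc, y)
    flipped <- rr$auc < 0.5
    if (flipped) rr <- roc_analysis(-sc, y)
    data.frame(feature = f, pair = screening$pair[i], p = screening$p[i],
               se = rr$se, auc = rr$auc, ci_low = rr$ci[1],
               ci_high = rr$ci[2],
               cutoff = if (flipped) -rr$cutoff else rr$cutoff,
               direction = if (flipped) "below" else "above",
               sensitivity = rr$sensitivity, specificity = rr$specificity,
               stringsAsFactors = FALSE)
  }))
  pairs <- unique(screening$pair)
  tasks <- lapply(pairs, function(pw) {
    pr <- strsplit(pw, " vs ")[[1]]
    sc <- screening[screening$pair == pw, ]
    sig <- sc$feature[sc$significant]
    pool <- if (length(sig)) sig else sc$feature
    pool <- pool[order(sc$p[match(pool, sc$feature)])]
    feats <- utils::head(pool, max_features)
    ttr <- feature_table(as.data.frame(train_tab)[train_tab$label %in% pr, ])
    tva <- feature_table(as.data.frame(valid_tab)[valid_tab$label %in% pr, ])
    evals <- lapply(models, function(m) {
      ev <- cross_validate(m, ttr, tva, feats, k = k, seed = seed,
                           positive = pr[2])
      st <- bootstrap_stability(m, ttr, feats, B = B, seed = seed,
                                hyper = ev$hyper, positive = pr[2])
      list(eval = ev, stability = st)
    })
    names(evals) <- models
    list(pair = pw, features = feats, models = evals)
  })
  names(tasks) <- pairs
  structure(list(features = ft, retest = retest_tabs, selection = sel,
                 screening = screening, roc = roc_tab, tasks = tasks,
                 n_features = length(feature_columns(ft)),
                 config = config, seed = seed),
            class = "livertex_report")
}

#' Summary table of classifier performance across pairwise tasks
#'
#' @param report A `livertex_report`.
#' @return Data frame shaped like a model-comparison table: one row per
#'   (task, model) with Acc/Sens/Spec (percent), MCC, RSD (percent) and
#'   AUC (percent).
#' @export
model_table <- function(report) {
  do.call(rbind, lapply(report$tasks, function(tk)
    do.call(rbind, lapply(names(tk$models), function(m) {
      ev <- tk$models[[m]]$eval; st <- tk$models[[m]]$stability
      data.frame(pair = tk$pair, model = m, acc = 100 * ev$acc,
                 sens = 100 * ev$sens, spec = 100 * ev$spec, mcc = ev$mcc,
                 rsd = st$rsd, auc = 100 * ev$auc, cv_auc = 100 * ev$cv_auc,
                 stringsAsFactors = FALSE)
    }))))
}

#' @export
print.livertex_report <- function(x, digits = 3, ...) {
  cat(sprintf("<livertex_report> %d features, %d training / %d validation subjects\n",
              x$n_features, sum(x$features$cohort == "training"),
              sum(x$features$cohort == "validation")))
  cat(sprintf("selected features: %d; significant (feature, pair) hits: %d\n",
              length(x$selection$selected), sum(x$screening$significant)))
  tab <- model_table(x)
  rownames(tab) <- NULL
  print(format(tab, digits = digits), ...)
  invisible(x)
}

#' Write a machine-readable pipeline report
#'
#' @param report A `livertex_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- list(
    n_features = report$n_features,
    n_selected = length(report$selection$selected),
    selected = report$selection$selected,
    screening = report$screening,
    roc = report$roc,
    models = model_table(report),
    seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
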