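# Screening (Kruskal-Wallis, ROC with Youden cut-off), the four classifiers
# (KNN, one-hidden-layer backprop ANN, C-SVM/RBF, logistic regression) with
# stratified 10-fold cross-validation, and bootstrap stability (relative
# standard deviation of AUC).

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] (rank H statistic with tie
#' correction, chi-square reference with k-1 degrees of freedom) returning
#' just the statistic and p-value. Screening applies it per feature to each
#' class pair.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 observations.
#' @return Named vector `c(H = ..., p = ...)`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs >= 2 observations", call. = FALSE)
  if (length(unique(unlist(groups))) == 1L)
    return(c(H = 0, p = 1))   # all ties: no rank information
  kt <- stats::kruskal.test(groups)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Pairwise Kruskal-Wallis screening of a feature table
#'
#' Tests every feature for a location difference in each pairwise class
#' comparison. Flags use the raw p-value at `alpha` (the study's design);
#' Benjamini-Hochberg adjusted p-values (within each pair, across features)
#' are reported alongside.
#'
#' @param table A `feature_table` (normally the training cohort).
#' @param features Feature names to screen (default: all).
#' @param alpha Significance level (default 0.05).
#' @return Data frame: feature, pair, H, p, p_adj, significant.
#' @export
kw_screen <- function(table, features = feature_columns(table),
                      alpha = 0.05) {
  df <- as.data.frame(table)
  classes <- sort(unique(df$label))
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- df[df$label == pr[1], ]; b <- df[df$label == pr[2], ]
    res <- t(vapply(features, function(f)
      kruskal_wallis(list(a[[f]], b[[f]])), numeric(2)))
    data.frame(feature = features, pair = paste(pr, collapse = " vs "),
               H = res[, 1], p = res[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::ave(out$p, out$pair,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  out$significant <- out$p < alpha
  out
}

#' ROC analysis with Youden-optimal cut-off
#'
#' AUC by the rank (Mann-Whitney) formulation; the cut-off maximizes
#' Youden's J = sensitivity + specificity - 1 over midpoints between
#' adjacent observed scores (ties broken toward the lowest cut-off);
#' standard error and 95% CI by the Hanley-McNeil method. Higher scores are
#' assumed to indicate the positive class.
#'
#' @param scores Numeric vector.
#' @param labels Binary labels (logical, 0/1, or two-level factor/character;
#'   for a factor the second level is positive).
#' @param positive Positive-class label (default: resolved from `labels`).
#' @return Object of class `roc_result`: auc, se, ci (length 2), cutoff,
#'   sensitivity, specificity, n_pos, n_neg.
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  pos <- as_positive_indicator(labels, positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  thr <- c(thr[1] - 1, (thr[-1] + thr[-length(thr)]) / 2)
  sens <- vapply(thr, function(t) mean(scores[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)   # first (lowest) cut-off among ties
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(list(auc = auc, se = se, ci = ci, cutoff = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f), cut-off %.4g: sens %.3f, spec %.3f\n",
              x$auc, x$se, x$ci[1], x$ci[2], x$cutoff,
              x$sensitivity, x$specificity))
  invisible(x)
}

as_positive_indicator <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(labels == 1)
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have two classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(labels)[2]
  labels == positive
}

#' Matthews correlation coefficient
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return MCC in \eqn{[-1, 1]}; 0 when any marginal is empty.
#' @export
mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# ---- classifiers -----------------------------------------------------------

classifier_models <- c("knn", "ann", "svm", "logistic")

# Column-wise z-scoring with training statistics; zero-sd columns pass
# through centered only.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")

#' Train one of the four classifiers
#'
#' Features are z-scored on the training statistics; every model exposes a
#' continuous score in (0, 1) for the positive class (KNN: neighbor vote
#' fraction over the 5 Euclidean nearest neighbors; ANN: one-hidden-layer
#' backprop network output; SVM: logistic link of the C-SVM/RBF decision
#' value; logistic: fitted probability). ANN refits are deterministic given
#' `seed`.
#'
#' @param model One of `"knn"`, `"ann"`, `"svm"`, `"logistic"`.
#' @param x Numeric feature matrix (rows = subjects).
#' @param y Binary labels; second factor level (or `positive`) is positive.
#' @param hyper Hyperparameters: `k` (KNN, default 5), `size`/`decay`
#'   (ANN, defaults 5 / 0.01), `cost`/`gamma` (SVM, defaults 1 / 1/ncol).
#' @param positive Positive-class label.
#' @param seed Seed for the ANN weight initialization.
#' @return Object of class `livertex_classifier` with a [predict] method
#'   returning positive-class scores.
#' @export
train_classifier <- function(model, x, y, hyper = list(), positive = NULL,
                             seed = 1L) {
  model <- match.arg(model, classifier_models)
  x <- as.matrix(x)
  pos <- as_positive_indicator(y, positive)
  sc <- fit_scaler(x)
  xs <- apply_scaler(x, sc)
  fit <- switch(model,
    knn = list(x = xs, y = pos, k = hyper$k %||% 5L),
    ann = {
      set.seed(seed)
      nnet::nnet(xs, as.numeric(pos), size = hyper$size %||% 5L,
                 decay = hyper$decay %||% 0.01, maxit = 300L,
                 entropy = TRUE, trace = FALSE)
    },
    svm = e1071::svm(xs, factor(pos, levels = c(FALSE, TRUE)),
                     kernel = "radial", cost = hyper$cost %||% 1,
                     gamma = hyper$gamma %||% (1 / ncol(xs)), scale = FALSE),
    logistic = {
      cf <- suppressWarnings(
        stats::glm.fit(cbind(1, xs), as.numeric(pos),
                       family = stats::binomial()))$coefficients
      cf[is.na(cf)] <- 0
      cf
    })
  structure(list(model = model, fit = fit, scaler = sc, hyper = hyper),
            class = "livertex_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param object A `livertex_classifier`.
#' @param newdata Feature matrix to score.
#' @param ... Unused.
#' @rdname train_classifier
#' @export
predict.livertex_classifier <- function(object, newdata, ...) {
  xs <- apply_scaler(as.matrix(newdata), object$scaler)
  switch(object$model,
    knn = {
      pr <- class::knn(object$fit$x,
                       xs, factor(object$fit$y, levels = c(FALSE, TRUE)),
                       k = min(object$fit$k, nrow(object$fit$x)), prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "TRUE", p, 1 - p)
    },
    ann = as.vector(stats::predict(object$fit, xs)),
    svm = {
      dv <- attr(stats::predict(object$fit, xs, decision.values = TRUE),
                 "decision.values")
      # decision values are signed toward the first class named in the
      # colname ("A/B" means positive values favor A)
      sign <- if (startsWith(colnames(dv)[1], "TRUE")) 1 else -1
      stats::plogis(sign * as.vector(dv))
    },
    logistic = as.vector(stats::plogis(cbind(1, xs) %*% object$fit)))
}

# Stratified fold assignment: within each class, shuffled 1..k recycling.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k && length(idx) < 1L)
      stop("class ", cl, " absent", call. = FALSE)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

default_hyper_grid <- function(model, p) {
  switch(model,
    ann = lapply(c(3L, 5L, 10L), function(s) list(size = s)),
    svm = {
      g <- expand.grid(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    list(list()))
}

#' Cross-validated training and validation-cohort evaluation
#'
#' Runs stratified `k`-fold cross-validation on the training cohort to pick
#' hyperparameters (ANN hidden units from 3/5/10; SVM cost/gamma over a
#' 3 x 3 grid; KNN and logistic have none) by mean fold AUC, refits on the
#' full training cohort, and reports accuracy, sensitivity, specificity,
#' MCC and AUC on the held-out validation cohort. Class assignment uses a
#' 0.5 score threshold; scaling is fitted on training folds only.
#'
#' @param model One of `"knn"`, `"ann"`, `"svm"`, `"logistic"`.
#' @param train_table,valid_table `feature_table`s with two label classes.
#' @param features Feature names to use.
#' @param k Folds (default 10).
#' @param seed Seed controlling fold assignment and ANN initialization.
#' @param positive Positive-class label (default: second sorted label).
#' @return Object of class `model_eval`: model, chosen hyperparameters,
#'   cv_auc, confusion counts and acc/sens/spec/mcc/auc on validation.
#' @export
cross_validate <- function(model, train_table, valid_table, features,
                           k = 10L, seed = 1L, positive = NULL) {
  model <- match.arg(model, classifier_models)
  tr <- as.data.frame(train_table); va <- as.data.frame(valid_table)
  labs <- sort(unique(c(tr$label, va$label)))
  if (length(labs) != 2L) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- labs[2]
  xtr <- as.matrix(tr[, features, drop = FALSE])
  xva <- as.matrix(va[, features, drop = FALSE])
  ytr <- tr$label == positive
  yva <- va$label == positive
  set.seed(seed)
  fold <- stratified_folds(ytr, k)
  grid <- default_hyper_grid(model, ncol(xtr))
  cv_auc_for <- function(hyper) {
    aucs <- vapply(seq_len(k), function(f) {
      tr_i <- fold != f
      if (length(unique(ytr[!tr_i])) < 2L) return(NA_real_)
      fit <- train_classifier(model, xtr[tr_i, , drop = FALSE], ytr[tr_i],
                              hyper = hyper, seed = seed + f)
      roc_analysis(predict(fit, xtr[!tr_i, , drop = FALSE]), ytr[!tr_i])$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  cv <- vapply(grid, cv_auc_for, numeric(1))
  best <- grid[[which.max(cv)]]
  fit <- train_classifier(model, xtr, ytr, hyper = best, seed = seed)
  sc <- predict(fit, xva)
  pred <- sc >= 0.5
  tp <- sum(pred & yva); fp <- sum(pred & !yva)
  tn <- sum(!pred & !yva); fn <- sum(!pred & yva)
  structure(list(
    model = model, hyper = best, cv_auc = max(cv),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    acc = (tp + tn) / length(yva),
    sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = mcc(tp, fp, tn, fn),
    auc = roc_analysis(sc, yva)$auc,
    positive = positive),
    class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval> %s: Acc %.1f%% Sens %.1f%% Spec %.1f%% MCC %.2f AUC %.1f%% (CV AUC %.3f)\n",
              x$model, 100 * x$acc, 100 * x$sens, 100 * x$spec, x$mcc,
              100 * x$auc, x$cv_auc))
  invisible(x)
}

#' Relative standard deviation of a sample of AUC values
#'
#' \eqn{RSD = \sigma / \mu \times 100} with the sample standard deviation
#' and mean; scale-invariant, and 0 for a constant sample.
#'
#' @param auc_samples Numeric vector (length >= 2) of AUC values.
#' @return RSD in percent.
#' @export
rsd <- function(auc_samples) {
  mu <- mean(auc_samples)
  if (mu <= 0) stop("mean AUC must be positive", call. = FALSE)
  stats::sd(auc_samples) / mu * 100
}

#' Bootstrap classifier stability (relative standard deviation of AUC)
#'
#' For each of `B` resamples: a stratified random half-split of the training
#' cohort, training on one half and AUC on the other. Stability is
#' summarized as \deqn{RSD = \sigma_{AUC} / \mu_{AUC} \times 100} with the
#' sample standard deviation and mean of the B AUC values; the median ± sd
#' is reported alongside. Degenerate resamples (a half with one class) are
#' skipped and logged; at least 0.9 B successful resamples are required.
#'
#' @param model One of `"knn"`, `"ann"`, `"svm"`, `"logistic"`.
#' @param train_table `feature_table` with two label classes.
#' @param features Feature names to use.
#' @param B Number of resamples (default 100, minimum 20).
#' @param seed Seed.
#' @param hyper Hyperparameters passed to [train_classifier()].
#' @param positive Positive-class label.
#' @return Object of class `stability_result`: `auc_samples`, `mu`, `sigma`,
#'   `median`, `rsd` (percent), `n_skipped`.
#' @export
bootstrap_stability <- function(model, train_table, features, B = 100L,
                                seed = 1L, hyper = list(), positive = NULL) {
  if (B < 20L) stop("B must be >= 20", call. = FALSE)
  tr <- as.data.frame(train_table)
  labs <- sort(unique(tr$label))
  if (length(labs) != 2L) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- labs[2]
  x <- as.matrix(tr[, features, drop = FALSE])
  y <- tr$label == positive
  set.seed(seed)
  aucs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    half <- unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, floor(length(idx) / 2))
    }))
    other <- setdiff(seq_along(y), half)
    if (length(unique(y[half])) < 2L || length(unique(y[other])) < 2L) next
    fit <- train_classifier(model, x[half, , drop = FALSE], y[half],
                            hyper = hyper, seed = seed + b)
    aucs[b] <- roc_analysis(predict(fit, x[other, , drop = FALSE]),
                            y[other])$auc
  }
  ok <- aucs[!is.na(aucs)]
  if (length(ok) < 0.9 * B)
    stop("too many degenerate resamples (", B - length(ok), " of ", B, ")",
         call. = FALSE)
  mu <- mean(ok); sg <- stats::sd(ok)
  structure(list(auc_samples = ok, mu = mu, sigma = sg,
                 median = stats::median(ok),
                 rsd = rsd(ok),
                 n_skipped = B - length(ok), model = model),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %s: AUC median %.3f +/- %.3f (B = %d), RSD %.2f%%\n",
              x$model, x$median, x$sigma, length(x$auc_samples), x$rsd))
  invisible(x)
}
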