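test_that("Kruskal-Wallis wrapper: separation, ties, input validation", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  expect_lt(res["p"], 0.05)
  expect_equal(unname(kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))["H"]), 0)
  expect_error(kruskal_wallis(list(1:5)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:5, 3)), ">= 2 observations")
  # agrees with stats::kruskal.test on tied data
  g <- list(c(1, 1, 2, 3), c(2, 2, 3, 4), c(5, 5, 6, 1))
  kt <- stats::kruskal.test(g)
  expect_equal(unname(kruskal_wallis(g)["H"]), unname(kt$statistic))
})

test_that("screening flags separated features per class pair", {
  set.seed(63)
  n <- 20
  df <- data.frame(
    subject_id = as.character(1:(3 * n)),
    label = rep(c("classA", "classB", "classC"), each = n),
    cohort = "training",
    sep_ab = c(stats::rnorm(n), stats::rnorm(n, 4), stats::rnorm(n, 4)),
    flat = stats::rnorm(3 * n), stringsAsFactors = FALSE)
  sc <- kw_screen(feature_table(df))
  expect_equal(nrow(sc), 6L)  # 2 features x 3 pairs
  get <- function(f, pr) sc$significant[sc$feature == f & sc$pair == pr]
  expect_true(get("sep_ab", "classA vs classB"))
  expect_true(get("sep_ab", "classA vs classC"))
  expect_false(get("sep_ab", "classB vs classC"))
  expect_true(all(sc$p >= 0 & sc$p <= 1))
  expect_true(all(sc$p_adj >= sc$p - 1e-12))
})

test_that("ROC: perfect separation, hand-computed toy, Hanley-McNeil SE", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$cutoff, 2); expect_lt(r$cutoff, 3)
  expect_equal(r$se, 0)
  # rank AUC equals the all-pairs (Mann-Whitney) count on tie-free data
  set.seed(65)
  sc <- stats::rnorm(60); y <- rep(c(TRUE, FALSE), 30)
  r <- roc_analysis(sc, y)
  pairs <- outer(sc[y], sc[!y], `>`)
  expect_equal(r$auc, mean(pairs))
  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("ROC cross-checks against pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(67)
  for (rep in 1:5) {
    sc <- stats::rnorm(40)
    y <- sample(c(0, 1), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    ours <- roc_analysis(sc, y)
    ref <- suppressMessages(pROC::roc(y, sc, direction = "<", quiet = TRUE))
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    best <- pROC::coords(ref, "best", best.method = "youden",
                         transpose = FALSE)
    expect_equal(ours$sensitivity + ours$specificity,
                 max(best$sensitivity + best$specificity), tolerance = 1e-12)
  }
})

test_that("label-permuted scores give null AUC and uniform KW p-values", {
  set.seed(69)
  sc <- stats::rnorm(2000)
  y <- sample(rep(c(0, 1), 1000))
  expect_lt(abs(roc_analysis(sc, y)$auc - 0.5), 0.03)
  # KW p-values under the null are uniform
  p <- vapply(1:2000, function(i) {
    g <- split(stats::rnorm(30), rep(1:3, 10))
    kruskal_wallis(g)[["p"]]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("MCC: perfect, inverted and empty-margin confusion matrices", {
  expect_equal(mcc(10, 0, 10, 0), 1)
  expect_equal(mcc(0, 10, 0, 10), -1)
  expect_equal(mcc(5, 5, 0, 0), 0)
})

test_that("all four classifiers separate a linearly separable toy set", {
  set.seed(73)
  n <- 30
  x <- rbind(cbind(stats::rnorm(n, -3), stats::rnorm(n, -3)),
             cbind(stats::rnorm(n, 3), stats::rnorm(n, 3)))
  y <- rep(c("neg", "pos"), each = n)
  for (m in c("knn", "ann", "svm", "logistic")) {
    fit <- train_classifier(m, x, y, seed = 7)
    sc <- predict(fit, x)
    expect_equal(mean((sc >= 0.5) == (y == "pos")), 1,
                 label = paste("training accuracy", m))
  }
})

test_that("ANN refits are deterministic under a fixed seed", {
  set.seed(75)
  x <- matrix(stats::rnorm(200), 50, 4)
  y <- x[, 1] + x[, 2] > 0
  f1 <- train_classifier("ann", x, y, seed = 11)
  f2 <- train_classifier("ann", x, y, seed = 11)
  expect_identical(f1$fit$wts, f2$fit$wts)
  expect_identical(predict(f1, x), predict(f2, x))
})

mini_tables <- function(n = 24, delta = 3, seed = 77) {
  set.seed(seed)
  mk <- function(tag, m) {
    data.frame(subject_id = paste0(tag, 1:(2 * m)),
               label = rep(c("classA", "classB"), each = m),
               cohort = tag,
               f1 = stats::rnorm(2 * m) + rep(c(0, delta), each = m),
               f2 = stats::rnorm(2 * m) + rep(c(0, delta), each = m),
               f3 = stats::rnorm(2 * m), stringsAsFactors = FALSE)
  }
  list(train = feature_table(mk("training", n)),
       valid = feature_table(mk("validation", n %/% 2)))
}

test_that("cross_validate reports coherent validation metrics", {
  tabs <- mini_tables()
  for (m in c("knn", "logistic")) {
    ev <- cross_validate(m, tabs$train, tabs$valid, c("f1", "f2", "f3"),
                         k = 5, seed = 3)
    expect_gt(ev$auc, 0.9)
    cm <- ev$confusion
    expect_equal(unname(ev$acc), unname((cm["tp"] + cm["tn"]) / sum(cm)))
    expect_equal(unname(ev$mcc),
                 mcc(cm["tp"], cm["fp"], cm["tn"], cm["fn"]),
                 ignore_attr = TRUE)
    expect_equal(unname(ev$sens), unname(cm["tp"] / (cm["tp"] + cm["fn"])))
    expect_equal(unname(ev$spec), unname(cm["tn"] / (cm["tn"] + cm["fp"])))
  }
  # label-permuted features: CV AUC near 0.5 for every model
  set.seed(79)
  tabs0 <- mini_tables(delta = 0, seed = 81)
  for (m in c("knn", "ann", "svm", "logistic")) {
    ev <- cross_validate(m, tabs0$train, tabs0$valid, c("f1", "f2", "f3"),
                         k = 5, seed = 5)
    expect_lt(abs(ev$cv_auc - 0.5), 0.25, label = paste("null cv", m))
  }
})

test_that("bootstrap stability reproduces the RSD closed forms", {
  # direct evaluation on a fixed AUC sample via the reported fields
  tabs <- mini_tables(delta = 4, seed = 83)
  st <- bootstrap_stability("logistic", tabs$train, c("f1", "f2"), B = 20,
                            seed = 9)
  expect_equal(st$rsd, rsd(st$auc_samples))
  expect_length(st$auc_samples, 20L)
  expect_true(all(st$auc_samples >= 0 & st$auc_samples <= 1))
  expect_error(bootstrap_stability("knn", tabs$train, "f1", B = 5), ">= 20")
})

test_that("RSD: worked value, constancy, scale invariance, monotonicity", {
  expect_equal(rsd(c(0.8, 0.9)), sqrt(0.005) / 0.85 * 100)
  expect_equal(round(rsd(c(0.8, 0.9)), 2), 8.32)
  expect_equal(rsd(rep(0.7, 10)), 0)
  set.seed(85)
  a <- stats::runif(30, 0.6, 0.9)
  for (cc in c(0.5, 2, 7)) expect_equal(rsd(cc * a), rsd(a))
  # lower sigma at fixed mu gives lower RSD
  b <- mean(a) + (a - mean(a)) * 0.3
  expect_lt(rsd(b), rsd(a))
})
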