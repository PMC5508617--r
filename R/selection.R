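# Reproducibility- and redundancy-driven feature selection: Lin's
# concordance and a dynamic-range statistic on test-retest replicate pairs,
# followed by greedy pairwise-R^2 pruning.

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2\,\mathrm{cov}(x,y)}{\mathrm{var}(x) + \mathrm{var}(y)
#'   + (\bar x - \bar y)^2}}
#' with population (divisor n) moments. Two constant sequences carry no
#' concordance information and return 0 with a warning.
#'
#' @param test,retest Paired numeric vectors (length >= 3, finite).
#' @return CCC in \eqn{[-1, 1]}.
#' @export
ccc <- function(test, retest) {
  if (length(test) != length(retest) || length(test) < 3L)
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  if (!all(is.finite(test)) || !all(is.finite(retest)))
    stop("inputs must be finite", call. = FALSE)
  mx <- mean(test); my <- mean(retest)
  vx <- mean((test - mx)^2); vy <- mean((retest - my)^2)
  den <- vx + vy + (mx - my)^2
  if (den == 0) {
    warning("both sequences constant and equal; CCC undefined, returning 0")
    return(0)
  }
  2 * mean((test - mx) * (retest - my)) / den
}

#' Dynamic range of a feature across replicates
#'
#' \deqn{DR = 1 - \frac{\mathrm{mean}_i |x_i - y_i|}
#'   {\max(x, y) - \min(x, y)}}
#' where the range in the denominator is taken over both replicates jointly.
#' Near 1 means replicate noise is small relative to the inter-subject
#' spread. Clipped to \eqn{[0, 1]}; a zero inter-subject range returns 0
#' with a warning.
#'
#' @param test,retest Paired numeric vectors.
#' @return DR in \eqn{[0, 1]}.
#' @export
dynamic_range <- function(test, retest) {
  if (length(test) != length(retest) || length(test) < 3L)
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  rng <- max(test, retest) - min(test, retest)
  if (rng == 0) {
    warning("zero inter-subject range; DR undefined, returning 0")
    return(0)
  }
  min(max(1 - mean(abs(test - retest)) / rng, 0), 1)
}

#' Greedy redundancy pruning by pairwise R^2
#'
#' Candidates are ranked (by decreasing `ranking`, typically the
#' dynamic range; ties keep input order) and accepted greedily: a feature
#' survives iff its squared Pearson correlation with every already-accepted
#' feature is below `r2_max`. Deterministic given the ranking.
#'
#' @param table A `feature_table` supplying the feature values.
#' @param kept Candidate feature names.
#' @param r2_max R^2 threshold (default 0.95).
#' @param ranking Optional numeric vector (named by feature) used to order
#'   candidates; unranked candidates keep input order.
#' @return Character vector of surviving feature names.
#' @export
redundancy_prune <- function(table, kept, r2_max = 0.95, ranking = NULL) {
  if (length(kept) < 2L) return(kept)
  if (nrow(table) < 4L) stop("need >= 4 subjects", call. = FALSE)
  if (!is.null(ranking))
    kept <- kept[order(-ranking[kept])]
  X <- as.matrix(as.data.frame(table)[, kept, drop = FALSE])
  accepted <- integer(0)
  for (j in seq_along(kept)) {
    if (!length(accepted)) { accepted <- j; next }
    r <- suppressWarnings(stats::cor(X[, j], X[, accepted, drop = FALSE]))
    r[is.na(r)] <- 0   # zero-variance columns carry no redundancy signal
    if (all(r^2 < r2_max)) accepted <- c(accepted, j)
  }
  kept[accepted]
}

#' Reproducibility-driven feature selection
#'
#' Applies the three filters in order: CCC >= `ccc_min` on the test-retest
#' pairs, dynamic range >= `dr_min`, then greedy pairwise-R^2 redundancy
#' pruning (ranked by DR) on the cohort table. An empty survivor set is a
#' valid result, not an error.
#'
#' @param cohort_table `feature_table` of the (training) cohort.
#' @param retest_pairs List with elements `test` and `retest`, two
#'   `feature_table`s covering the same subjects (>= 3) in matching order of
#'   `subject_id`.
#' @param ccc_min,dr_min,r2_max Thresholds (defaults 0.9, 0.9, 0.95).
#' @return Object of class `selection_report`: data frame `stats` (per
#'   feature: ccc, dr, pass flags, selected), `selected` names, and the
#'   thresholds used.
#' @export
select_features <- function(cohort_table, retest_pairs,
                            ccc_min = 0.9, dr_min = 0.9, r2_max = 0.95) {
  tt <- as.data.frame(retest_pairs$test)
  rt <- as.data.frame(retest_pairs$retest)
  if (nrow(tt) < 3L) stop("retest pairs must cover >= 3 subjects", call. = FALSE)
  rt <- rt[match(tt$subject_id, rt$subject_id), ]
  if (anyNA(rt$subject_id))
    stop("test and retest tables cover different subjects", call. = FALSE)
  feats <- feature_columns(cohort_table)
  cc <- dr <- stats::setNames(numeric(length(feats)), feats)
  for (f in feats) {
    cc[f] <- suppressWarnings(ccc(tt[[f]], rt[[f]]))
    dr[f] <- suppressWarnings(dynamic_range(tt[[f]], rt[[f]]))
  }
  pass <- cc >= ccc_min & dr >= dr_min
  selected <- redundancy_prune(cohort_table, feats[pass], r2_max,
                               ranking = dr)
  stats_df <- data.frame(feature = feats, ccc = cc, dr = dr,
                         pass_ccc = cc >= ccc_min, pass_dr = dr >= dr_min,
                         selected = feats %in% selected,
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(stats = stats_df, selected = selected,
                 thresholds = list(ccc_min = ccc_min, dr_min = dr_min,
                                   r2_max = r2_max)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(paste0("<selection_report> %d/%d features selected ",
                     "(CCC >= %.2f: %d; DR >= %.2f: %d; R^2 < %.2f)\n"),
              length(x$selected), nrow(x$stats),
              x$thresholds$ccc_min, sum(x$stats$pass_ccc),
              x$thresholds$dr_min, sum(x$stats$pass_dr),
              x$thresholds$r2_max))
  invisible(x)
}
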