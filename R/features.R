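# The 233-feature vocabulary. Six families:
#   IHF    3   intensity-histogram (variance, skewness, excess kurtosis)
#   GLCM  80   10 Haralick statistics x {mean, variance over 4 directions}
#              x 4 distances
#   GLGCM 15   gray-gradient co-occurrence statistics
#   GLRLM 44   11 run-length statistics x 4 directions
#   GWTF  80   Gabor bank: 40 mean-square-energy + 40 mean-amplitude
#   ISZM  11   intensity-size-zone statistics
# All logarithms in entropy-type features are natural logs; 0 log 0 := 0.

glcm_bases <- c("Energy", "Entropy", "Contrast", "Correlation", "Homogeneity",
                "SumVariance", "ClusterShade", "ClusterTendency",
                "InverseDifferenceMoment", "InverseVariance")

glgcm_names <- c("SmallGradientEmphasis", "LargeGradientEmphasis",
                 "GrayInhomogeneity", "GradientInhomogeneity",
                 "GradientEnergy", "MeanGray", "MeanGradient", "GrayVariance",
                 "GradientVariance", "GradientCorrelation", "GrayEntropy",
                 "GradientEntropy", "MixtureEntropy",
                 "GradientDifferenceMoment",
                 "GradientInverseDifferenceMoment")

glrlm_bases <- c("SRE", "LRE", "GLN", "RLN", "LGRE", "HGRE", "SRLGE", "SRHGE",
                 "LRLGE", "LRHGE", "RunPercentage")

iszm_names <- c("SmallZoneEmphasis", "LargeZoneEmphasis",
                "IntensityVariability", "SizeZoneVariability",
                "ZonePercentage", "LowIntensityEmphasis",
                "HighIntensityEmphasis", "LowIntensitySmallZoneEmphasis",
                "HighIntensitySmallZoneEmphasis",
                "LowIntensityLargeZoneEmphasis",
                "HighIntensityLargeZoneEmphasis")

glcm_directions <- c(0L, 45L, 90L, 135L)
glcm_distances <- c(1L, 2L, 4L, 8L)

#' Canonical feature names
#'
#' The 233 feature names in canonical order, or the subset belonging to one
#' family. Names are `FAMILY_Base_qualifiers`, e.g. `GLCM_Energy_mean_d2`,
#' `GLRLM_SRE_0deg`, `GWTF_S_gabor-13`, `ISZM_SmallZoneEmphasis`.
#'
#' @param family Optional family filter, one of
#'   `"IHF"`, `"GLCM"`, `"GLGCM"`, `"GLRLM"`, `"GWTF"`, `"ISZM"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(family = NULL) {
  nm <- c(
    paste0("IHF_", c("Variance", "Skewness", "Kurtosis")),
    unlist(lapply(glcm_distances, function(d)
      unlist(lapply(glcm_bases, function(b)
        paste0("GLCM_", b, "_", c("mean", "variance"), "_d", d))))),
    paste0("GLGCM_", glgcm_names),
    unlist(lapply(glrlm_bases, function(b)
      paste0("GLRLM_", b, "_", glcm_directions, "deg"))),
    paste0("GWTF_S_gabor-", rep(0:4, each = 8), rep(0:7, 5)),
    paste0("GWTF_A_gabor-", rep(0:4, each = 8), rep(0:7, 5)),
    paste0("ISZM_", iszm_names))
  if (!is.null(family)) nm <- nm[feature_family(nm) == family]
  nm
}

#' Family of each feature name
#' @param names Character vector of feature names.
#' @return Character vector of family tags.
#' @export
feature_family <- function(names) sub("_.*$", "", names)

#' Default extraction configuration
#'
#' @return Nested list of configuration values: Wiener window and switch,
#'   quantization range, GLGCM gradient levels, ISZM connectivity, Gabor
#'   frequency bounds and fill rule.
#' @export
default_config <- function() {
  list(wiener = list(enabled = TRUE, window = 3L),
       quantization = list(range = 32L),
       glgcm = list(gradient_levels = 16L),
       iszm = list(connectivity = 8L),
       gabor = list(n_scales = 5L, n_orientations = 8L,
                    f_low = 0.05, f_high = 0.4, fill = "mean"))
}

entropy_nat <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

#' Intensity-histogram features
#'
#' Variance (unbiased), skewness (\eqn{m_3/m_2^{3/2}}, population moments)
#' and excess kurtosis (\eqn{m_4/m_2^2 - 3}) of in-mask intensities. These
#' three first-order statistics are location-invariant, so they are robust
#' to scanner-dependent global intensity offsets. A zero-variance ROI
#' returns skewness and kurtosis 0 with a warning.
#'
#' @param image A `roi_image`.
#' @return Named numeric vector of the 3 IHF features.
#' @export
ihf_features <- function(image) {
  stopifnot(inherits(image, "roi_image"))
  v <- image$pixels[image$mask]
  if (length(v) < 3L) stop("need at least 3 in-mask pixels", call. = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    warning("degenerate ROI (zero variance); skewness and kurtosis set to 0")
    out <- c(0, 0, 0)
  } else {
    out <- c(stats::var(v), mean((v - m)^3) / m2^1.5, mean((v - m)^4) / m2^2 - 3)
  }
  stats::setNames(out, feature_names("IHF"))
}

# 10 Haralick statistics of one normalized co-occurrence matrix.
glcm_features_single <- function(g) {
  p <- g$matrix
  R <- nrow(p)
  if (g$pair_count == 0)  # no valid pair: documented degenerate limits
    return(stats::setNames(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0), glcm_bases))
  i <- matrix(seq_len(R), R, R)
  j <- t(i)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(seq_len(R) * pi_); mu_j <- sum(seq_len(R) * pj_)
  var_i <- sum((seq_len(R) - mu_i)^2 * pi_)
  var_j <- sum((seq_len(R) - mu_j)^2 * pj_)
  corr <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j) else 0
  k <- 2:(2 * R)
  pxy <- vapply(k, function(s) sum(p[i + j == s]), numeric(1))
  sa <- sum(k * pxy)
  dev <- i + j - mu_i - mu_j
  stats::setNames(c(
    sum(p^2),
    entropy_nat(p),
    sum((i - j)^2 * p),
    corr,
    sum(p / (1 + abs(i - j))),
    sum((k - sa)^2 * pxy),
    sum(dev^3 * p),
    sum(dev^2 * p),
    sum(p / (1 + (i - j)^2)),
    sum(p[i != j] / (i - j)[i != j]^2)), glcm_bases)
}

#' Co-occurrence features for one distance
#'
#' Computes the 10 Haralick statistics for each of the four direction
#' matrices at one distance, then their mean and variance (population,
#' divisor 4) across directions: 20 features per distance, 80 over the four
#' distances.
#'
#' @param glcms List of four `glcm` objects (directions 0/45/90/135) sharing
#'   one distance.
#' @return Named numeric vector of 20 features (`_mean_d*`, `_variance_d*`).
#' @export
glcm_features <- function(glcms) {
  stopifnot(length(glcms) == 4L)
  d <- glcms[[1]]$d
  per_dir <- vapply(glcms, glcm_features_single, numeric(length(glcm_bases)))
  mu <- rowMeans(per_dir)
  va <- rowMeans((per_dir - mu)^2)
  out <- as.vector(rbind(mu, va))
  stats::setNames(out, unlist(lapply(glcm_bases, function(b)
    paste0("GLCM_", b, "_", c("mean", "variance"), "_d", d))))
}

#' Gray-gradient co-occurrence features
#'
#' The 15 standard statistics of the normalized joint gray-level /
#' gradient-level histogram \eqn{p(i,g)}: small/large gradient emphasis,
#' gray and gradient non-uniformity ("inhomogeneity"), energy, marginal
#' means, variances and entropies, gray-gradient correlation, mixture
#' entropy, and the (inverse) difference moments on \eqn{(i-g)}.
#'
#' @param m A `glgcm`.
#' @return Named numeric vector of 15 features.
#' @export
glgcm_features <- function(m) {
  p <- m$matrix
  R <- nrow(p); G <- ncol(p)
  i <- matrix(seq_len(R), R, G)
  g <- matrix(seq_len(G), R, G, byrow = TRUE)
  pi_ <- rowSums(p); pg_ <- colSums(p)
  mu_i <- sum(seq_len(R) * pi_); mu_g <- sum(seq_len(G) * pg_)
  var_i <- sum((seq_len(R) - mu_i)^2 * pi_)
  var_g <- sum((seq_len(G) - mu_g)^2 * pg_)
  corr <- if (var_i > 0 && var_g > 0)
    sum((i - mu_i) * (g - mu_g) * p) / sqrt(var_i * var_g) else 0
  stats::setNames(c(
    sum(p / g^2),
    sum(p * g^2),
    sum(pi_^2),
    sum(pg_^2),
    sum(p^2),
    mu_i,
    mu_g,
    var_i,
    var_g,
    corr,
    entropy_nat(pi_),
    entropy_nat(pg_),
    entropy_nat(p),
    sum((i - g)^2 * p),
    sum(p / (1 + (i - g)^2))), paste0("GLGCM_", glgcm_names))
}

#' Run-length features for one direction
#'
#' The 11 Galloway-style statistics: short/long run emphasis, gray-level and
#' run-length non-uniformity, low/high gray-level run emphasis, their four
#' short/long-run combinations, and run percentage
#' (runs per in-mask pixel).
#'
#' @param m A `glrlm`.
#' @return Named numeric vector of 11 features (suffix `_<theta>deg`).
#' @export
glrlm_features <- function(m) {
  M <- m$matrix
  N <- m$n_runs
  i <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  j <- matrix(seq_len(ncol(M)), nrow(M), ncol(M), byrow = TRUE)
  stats::setNames(c(
    sum(M / j^2) / N,
    sum(M * j^2) / N,
    sum(rowSums(M)^2) / N,
    sum(colSums(M)^2) / N,
    sum(M / i^2) / N,
    sum(M * i^2) / N,
    sum(M / (i^2 * j^2)) / N,
    sum(M * i^2 / j^2) / N,
    sum(M * j^2 / i^2) / N,
    sum(M * i^2 * j^2) / N,
    N / m$n_pixels), paste0("GLRLM_", glrlm_bases, "_", m$theta, "deg"))
}

#' Intensity-size-zone features
#'
#' The 11 size-zone statistics: small/large zone emphasis, intensity and
#' size-zone variability, zone percentage (zones per in-mask pixel),
#' low/high intensity emphasis and their four small/large-zone combinations.
#'
#' @param m An `iszm`.
#' @return Named numeric vector of 11 features.
#' @export
iszm_features <- function(m) {
  M <- m$matrix
  N <- m$n_zones
  i <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  s <- matrix(seq_len(ncol(M)), nrow(M), ncol(M), byrow = TRUE)
  stats::setNames(c(
    sum(M / s^2) / N,
    sum(M * s^2) / N,
    sum(rowSums(M)^2) / N,
    sum(colSums(M)^2) / N,
    N / m$n_pixels,
    sum(M / i^2) / N,
    sum(M * i^2) / N,
    sum(M / (i^2 * s^2)) / N,
    sum(M * i^2 / s^2) / N,
    sum(M * s^2 / i^2) / N,
    sum(M * i^2 * s^2) / N), paste0("ISZM_", iszm_names))
}

# The 150 matrix-derived features (GLCM 80 + GLGCM 15 + GLRLM 44 + ISZM 11)
# of one quantized ROI; `source` supplies the gradient/GLGCM intensities.
matrix_features <- function(q, source, config) {
  glcm_part <- unlist(lapply(glcm_distances, function(d)
    glcm_features(lapply(glcm_directions, function(th) build_glcm(q, d, th)))))
  glgcm_part <- glgcm_features(
    build_glgcm(q, source, config$glgcm$gradient_levels))
  rl <- lapply(glcm_directions, function(th)
    glrlm_features(build_glrlm(q, th)))
  glrlm_part <- unlist(lapply(seq_along(glrlm_bases), function(b)
    vapply(rl, `[`, numeric(1), b)))
  names(glrlm_part) <- unlist(lapply(glrlm_bases, function(b)
    paste0("GLRLM_", b, "_", glcm_directions, "deg")))
  iszm_part <- iszm_features(build_iszm(q, config$iszm$connectivity))
  c(glcm_part, glgcm_part, glrlm_part, iszm_part)
}

#' Extract the full 233-entry feature vector of one ROI
#'
#' Runs the preprocessing chain (adaptive Wiener filter, then fixed-bin
#' discretization), builds all texture matrices, and evaluates all six
#' feature families. Histogram and Gabor features use the denoised,
#' unquantized intensities; matrix features use the quantized levels.
#'
#' @param image A `roi_image`.
#' @param config Configuration list, see [default_config()].
#' @return Named numeric vector of exactly 233 finite values in canonical
#'   [feature_names()] order.
#' @export
extract_all <- function(image, config = default_config()) {
  stopifnot(inherits(image, "roi_image"))
  img <- if (isTRUE(config$wiener$enabled))
    wiener_denoise(image, config$wiener$window) else image
  q <- quantize(img, config$quantization$range)
  bank <- gabor_bank(config$gabor$n_scales, config$gabor$n_orientations,
                     config$gabor$f_low, config$gabor$f_high)
  out <- c(suppressWarnings(ihf_features(img)),
           matrix_features(q, img, config),
           gabor_features(img, bank, fill = config$gabor$fill))
  out <- out[feature_names()]
  if (any(!is.finite(out)))
    stop("non-finite features for subject ", image$subject_id, ": ",
         paste(names(out)[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

#' Extract features for a list of ROIs into a feature table
#'
#' @param rois List of `roi_image` objects (labels are taken from them).
#' @param cohort Character vector recycled over ROIs (e.g. `"training"`).
#' @param config Configuration list, see [default_config()].
#' @return A `feature_table` with one row per ROI.
#' @export
extract_cohort <- function(rois, cohort = "training",
                           config = default_config()) {
  vals <- t(vapply(rois, extract_all, numeric(233L), config = config))
  df <- data.frame(
    subject_id = vapply(rois, `[[`, character(1), "subject_id"),
    label = vapply(rois, `[[`, character(1), "label"),
    cohort = rep_len(cohort, length(rois)),
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(vals))
  feature_table(df)
}

#' Discretization-sensitivity profile
#'
#' Recomputes the matrix-based features of each ROI at two gray-level counts
#' and summarizes, per ROI and per feature group, the mean symmetric relative
#' difference \eqn{|a-b| / ((|a|+|b|)/2)} (0 when both values are 0; bounded
#' by 2). The symmetric form makes features of very different scales
#' comparable, which matters because several co-occurrence statistics grow
#' polynomially with the number of gray levels by construction.
#'
#' @param rois List of `roi_image` objects.
#' @param ranges Two gray-level counts to compare (default 16 vs 128).
#' @param groups Named list of feature-name vectors to summarize; defaults to
#'   the local matrix families (GLCM + GLRLM) versus the low-intensity /
#'   large-zone ISZM statistics.
#' @param config Configuration list.
#' @return Data frame: one row per ROI, one column of mean symmetric relative
#'   differences per group.
#' @export
discretization_sensitivity <- function(rois, ranges = c(16L, 128L),
                                       groups = NULL,
                                       config = default_config()) {
  stopifnot(length(ranges) == 2L)
  if (is.null(groups))
    groups <- list(
      local = c(feature_names("GLCM"), feature_names("GLRLM")),
      iszm_regional = paste0("ISZM_", c("LargeZoneEmphasis",
                                        "LowIntensityEmphasis",
                                        "LowIntensityLargeZoneEmphasis",
                                        "HighIntensityLargeZoneEmphasis")))
  one <- function(roi) {
    img <- if (isTRUE(config$wiener$enabled))
      wiener_denoise(roi, config$wiener$window) else roi
    fa <- matrix_features(quantize(img, ranges[1]), img, config)
    fb <- matrix_features(quantize(img, ranges[2]), img, config)
    srd <- ifelse(fa == 0 & fb == 0, 0,
                  abs(fa - fb) / ((abs(fa) + abs(fb)) / 2))
    vapply(groups, function(g) mean(srd[g]), numeric(1))
  }
  out <- as.data.frame(t(vapply(rois, one, numeric(length(groups)))))
  names(out) <- names(groups)
  out
}
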