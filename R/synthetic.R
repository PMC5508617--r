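# Synthetic lesion-phantom generator. Emulates the statistical structure the
# downstream analysis assumes — three texture-distinct lesion classes on
# 256x256 axial slices, a training/validation cohort split, and test-retest
# replicate pairs — without any claim to MR acquisition physics.

#' Phantom specification
#'
#' Describes how phantom slices are rendered. Each class draws an elliptical
#' lesion (radii from `roi_radius_range`) on a darker background and fills it
#' with `base_intensity` plus up to three structured components and i.i.d.
#' noise:
#' * a Gaussian random field smoothed with `blur_sigma` pixels and scaled to
#'   standard deviation `intensity_sd` (off when `blur_sigma = 0`) —
#'   controls local co-occurrence/run-length structure;
#' * a Voronoi blob field with mean cell diameter `blob_scale` pixels and
#'   i.i.d. `N(0, intensity_sd)` offsets per cell (off when
#'   `blob_scale = 0`) — controls size-zone structure;
#' * a linear ramp of `gradient_slope` intensity units per pixel in a random
#'   direction (off when 0) — controls gradient-matrix structure.
#'
#' The default class parameters are strongly separated along several texture
#' axes; `separation = "none"` gives three identical classes (the null
#' configuration used to check that the pipeline does not hallucinate
#' signal).
#'
#' @param image_size Slice size in pixels (default `c(256, 256)`).
#' @param roi_radius_range Ellipse semi-axis range in pixels (default 8-30).
#' @param class_params Named list of per-class parameter lists with entries
#'   `base_intensity`, `intensity_sd`, `blur_sigma`, `blob_scale`,
#'   `gradient_slope`.
#' @param noise_sd I.i.d. acquisition-noise standard deviation.
#' @param retest_noise_sd Replicate noise used by [generate_test_retest()].
#' @param seed Integer master seed; per-subject streams are derived from it
#'   so adding subjects never perturbs earlier ones.
#' @param separation `"strong"` (default class set) or `"none"`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L),
                         roi_radius_range = c(8, 30),
                         class_params = NULL,
                         noise_sd = 5,
                         retest_noise_sd = 2,
                         seed = 1L,
                         separation = c("strong", "none")) {
  separation <- match.arg(separation)
  if (is.null(class_params)) {
    class_params <- if (separation == "strong") list(
      classA = list(base_intensity = 180, intensity_sd = 8,
                    blur_sigma = 2.5, blob_scale = 0, gradient_slope = 0),
      classB = list(base_intensity = 140, intensity_sd = 20,
                    blur_sigma = 1.0, blob_scale = 6, gradient_slope = 0),
      classC = list(base_intensity = 120, intensity_sd = 30,
                    blur_sigma = 0.5, blob_scale = 3, gradient_slope = 1.5))
    else {
      one <- list(base_intensity = 150, intensity_sd = 15,
                  blur_sigma = 1.0, blob_scale = 4, gradient_slope = 0)
      list(classA = one, classB = one, classC = one)
    }
  }
  if (length(class_params) != 3L || is.null(names(class_params)))
    stop("three named classes are required", call. = FALSE)
  for (cp in class_params) {
    if (cp$intensity_sd < 0 || cp$blur_sigma < 0 || cp$blob_scale < 0)
      stop("class parameter standard deviations and scales must be >= 0",
           call. = FALSE)
  }
  if (noise_sd < 0 || retest_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 roi_radius_range = roi_radius_range,
                 class_params = class_params,
                 noise_sd = noise_sd, retest_noise_sd = retest_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Derived per-subject seed, kept below 2^31 - 1.
subject_seed <- function(master, k, salt = 0L)
  as.integer((as.numeric(master) * 48271 + k * 10007 + salt * 197) %% 2147483647)

# Noiseless lesion field + mask + background for one subject.
phantom_field <- function(spec, label, seed) {
  cp <- spec$class_params[[label]]
  if (is.null(cp)) stop("unknown class label: ", label, call. = FALSE)
  set.seed(seed)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  rr <- spec$roi_radius_range
  a <- stats::runif(1, rr[1], rr[2]); b <- stats::runif(1, rr[1], rr[2])
  phi <- stats::runif(1, 0, pi)
  m <- max(a, b) + 2
  cx <- stats::runif(1, m + 1, nc - m - 1)
  cy <- stats::runif(1, m + 1, nr - m - 1)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  row <- matrix(seq_len(nr), nr, nc) - cy
  u <- col * cos(phi) + row * sin(phi)
  v <- -col * sin(phi) + row * cos(phi)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  bb <- mask_bbox(mask)
  tex <- matrix(cp$base_intensity, length(bb$r), length(bb$c))
  if (cp$blur_sigma > 0 && cp$intensity_sd > 0) {
    f <- gaussian_blur(matrix(stats::rnorm(length(tex)), nrow(tex)),
                       cp$blur_sigma)
    s <- stats::sd(as.vector(f))
    if (s > 0) tex <- tex + f / s * cp$intensity_sd
  }
  if (cp$blob_scale > 0 && cp$intensity_sd > 0)
    tex <- tex + voronoi_field(nrow(tex), ncol(tex), cp$blob_scale,
                               cp$intensity_sd)
  if (cp$gradient_slope != 0) {
    psi <- stats::runif(1, 0, 2 * pi)
    gc <- matrix(seq_len(ncol(tex)), nrow(tex), ncol(tex), byrow = TRUE)
    gr <- matrix(seq_len(nrow(tex)), nrow(tex), ncol(tex))
    ramp <- (gc - mean(gc[1, ])) * cos(psi) + (gr - mean(gr[, 1])) * sin(psi)
    tex <- tex + cp$gradient_slope * ramp
  }
  bg <- 0.5 * min(vapply(spec$class_params, `[[`, numeric(1),
                         "base_intensity"))
  pixels <- matrix(bg, nr, nc)
  sub <- pixels[bb$r, bb$c]
  sub[mask[bb$r, bb$c]] <- tex[mask[bb$r, bb$c]]
  pixels[bb$r, bb$c] <- sub
  list(pixels = pixels, mask = mask)
}

# Piecewise-constant Voronoi tessellation: sites at density matching a mean
# cell diameter `scale`, one N(0, sd) offset per cell.
voronoi_field <- function(nr, nc, scale, sd) {
  n_sites <- max(2L, round(nr * nc / (pi * (scale / 2)^2)))
  sx <- stats::runif(n_sites, 0.5, nc + 0.5)
  sy <- stats::runif(n_sites, 0.5, nr + 0.5)
  off <- stats::rnorm(n_sites, 0, sd)
  px <- rep(seq_len(nc), each = nr)
  py <- rep(seq_len(nr), nc)
  d2 <- outer(px, sx, `-`)^2 + outer(py, sy, `-`)^2
  matrix(off[max.col(-d2, ties.method = "first")], nr, nc)
}

# Separable Gaussian blur, kernel truncated at 3 sigma, edge-renormalized.
gaussian_blur <- function(M, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  blur1 <- function(X) {   # along rows (first dim)
    n <- nrow(X)
    acc <- matrix(0, n, ncol(X)); wt <- matrix(0, n, ncol(X))
    for (o in -h:h) {
      r <- max(1L, 1L - o):min(n, n - o)
      acc[r, ] <- acc[r, ] + k[o + h + 1L] * X[r + o, , drop = FALSE]
      wt[r, ] <- wt[r, ] + k[o + h + 1L]
    }
    acc / wt
  }
  t(blur1(t(blur1(M))))
}

#' Generate one phantom slice
#'
#' @param spec A [phantom_spec()].
#' @param label Class name from `spec$class_params`.
#' @param seed Integer seed; the slice is a deterministic function of
#'   `(spec, label, seed)`.
#' @param subject_id Subject identifier.
#' @return A `roi_image`.
#' @export
generate_phantom <- function(spec, label, seed = spec$seed,
                             subject_id = "phantom") {
  fld <- phantom_field(spec, label, seed)
  set.seed(subject_seed(seed, 1L, salt = 1L))
  pixels <- fld$pixels +
    if (spec$noise_sd > 0)
      matrix(stats::rnorm(length(fld$pixels), 0, spec$noise_sd),
             nrow(fld$pixels)) else 0
  roi_image(pixels, fld$mask, subject_id = subject_id, label = label)
}

#' Generate a labelled, split phantom cohort
#'
#' @param spec A [phantom_spec()].
#' @param n_per_class Named integer vector of subjects per class (default
#'   `c(classA = 55, classB = 67, classC = 40)`, the study cohort sizes).
#' @param split Training/validation split: either a single training fraction
#'   in (0,1) or a length-2 vector of cohort sizes (default `c(112, 50)`).
#'   The split is stratified, preserving class proportions within rounding.
#' @return Object of class `synthetic_cohort`: list with `rois` (list of
#'   `roi_image`), `cohort` (character vector, `"training"`/`"validation"`),
#'   and `spec`.
#' @export
generate_cohort <- function(spec,
                            n_per_class = c(classA = 55, classB = 67,
                                            classC = 40),
                            split = c(112, 50)) {
  classes <- names(spec$class_params)
  if (is.null(names(n_per_class))) names(n_per_class) <- classes
  if (any(n_per_class < 2)) stop("need >= 2 subjects per class", call. = FALSE)
  total <- sum(n_per_class)
  if (length(split) == 1L) {
    if (split <= 0 || split >= 1)
      stop("split fraction must lie in (0, 1)", call. = FALSE)
    n_train <- round(total * split)
  } else {
    if (sum(split) != total)
      stop("split sizes must sum to the cohort size", call. = FALSE)
    n_train <- split[1]
  }
  frac <- n_train / total
  # largest-remainder allocation of training slots across classes
  raw <- n_per_class * frac
  ntr <- floor(raw)
  rem <- n_train - sum(ntr)
  if (rem > 0) {
    ord <- order(raw - ntr, decreasing = TRUE)
    ntr[ord[seq_len(rem)]] <- ntr[ord[seq_len(rem)]] + 1
  }
  rois <- vector("list", total)
  cohort <- character(total)
  k <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    n <- n_per_class[[cl]]
    set.seed(subject_seed(spec$seed, ci, salt = 7L))
    train_idx <- sample.int(n, ntr[[cl]])
    for (s in seq_len(n)) {
      k <- k + 1L
      rois[[k]] <- generate_phantom(
        spec, cl, seed = subject_seed(spec$seed, k),
        subject_id = sprintf("S%03d", k))
      cohort[k] <- if (s %in% train_idx) "training" else "validation"
    }
  }
  structure(list(rois = rois, cohort = cohort, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$rois, `[[`, character(1), "label")
  cat(sprintf("<synthetic_cohort> %d subjects (%s); training %d / validation %d\n",
              length(x$rois),
              paste(names(table(labs)), table(labs), sep = ":", collapse = ", "),
              sum(x$cohort == "training"), sum(x$cohort == "validation")))
  invisible(x)
}

#' Generate test-retest replicate pairs
#'
#' Each subject's two replicates share one underlying noiseless texture
#' field and mask; each replicate adds independent `N(0, retest_noise_sd)`
#' noise. With `retest_noise_sd = 0` the pair is pixel-identical.
#'
#' @param spec A [phantom_spec()].
#' @param n_subjects Number of replicate pairs (default 15).
#' @return List of length `n_subjects`; each element is a list with elements
#'   `test` and `retest` (both `roi_image`).
#' @export
generate_test_retest <- function(spec, n_subjects = 15L) {
  if (n_subjects < 2L) stop("need >= 2 subjects", call. = FALSE)
  classes <- names(spec$class_params)
  lapply(seq_len(n_subjects), function(k) {
    cl <- classes[((k - 1L) %% length(classes)) + 1L]
    fld <- phantom_field(spec, cl, subject_seed(spec$seed, k, salt = 11L))
    one <- function(rep_tag, salt) {
      set.seed(subject_seed(spec$seed, k, salt = salt))
      px <- fld$pixels +
        if (spec$retest_noise_sd > 0)
          matrix(stats::rnorm(length(fld$pixels), 0, spec$retest_noise_sd),
                 nrow(fld$pixels)) else 0
      roi_image(px, fld$mask, subject_id = sprintf("R%03d", k),
                label = cl, replicate = rep_tag)
    }
    list(test = one("test", 13L), retest = one("retest", 17L))
  })
}

#' Write a cohort to disk plus a manifest
#'
#' Images are written as NIfTI (double precision, lossless), masks as PNG;
#' a `manifest.csv` with columns
#' `subject_id,image,mask,label,cohort,replicate` is written alongside.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cohort$rois), function(i) {
    roi <- cohort$rois[[i]]
    img_f <- file.path(dir, paste0(roi$subject_id, ".nii"))
    msk_f <- file.path(dir, paste0(roi$subject_id, "_mask.png"))
    RNifti::writeNifti(roi$pixels, img_f, datatype = "double")
    png::writePNG(roi$mask * 1, msk_f)
    data.frame(subject_id = roi$subject_id, image = basename(img_f),
               mask = basename(msk_f), label = roi$label,
               cohort = cohort$cohort[i], replicate = "",
               stringsAsFactors = FALSE)
  })
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mpath, row.names = FALSE)
  invisible(mpath)
}
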