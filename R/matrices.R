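# Texture-matrix builders. All matrices count in-mask pixels only: nothing
# outside the lesion mask ever contributes (pairs, runs and zones are
# truncated at the mask boundary).

# Unit (row, col) steps for the four canonical directions; 0 deg points along
# +column ("right"), 90 deg along -row (image "up"). Diagonals use unit
# Chebyshev steps, so distance d at 45 deg means offset (-d, +d).
direction_step <- function(theta) {
  switch(as.character(theta),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered in-mask pixel pairs separated by `d` unit steps along
#' direction `theta`, adds the transpose (equivalent to also counting the
#' opposite direction, giving the usual symmetric GLCM), and normalizes by
#' the total pair count. A (d, theta) combination with no valid pair yields
#' an all-zero matrix with `pair_count = 0`; downstream features then take
#' their documented degenerate values.
#'
#' @param q A `quantized_roi`.
#' @param d Pixel distance: 1, 2, 4 or 8.
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @return List of class `glcm`: `matrix` (range x range, sums to 1),
#'   `d`, `theta`, `pair_count`.
#' @export
build_glcm <- function(q, d = 1L, theta = 0L) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!d %in% c(1L, 2L, 4L, 8L))
    stop("`d` must be one of 1, 2, 4, 8", call. = FALSE)
  step <- direction_step(theta) * as.integer(d)
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  R <- q$range
  rlo <- max(1L, 1L - step[1]); rhi <- min(nr, nr - step[1])
  clo <- max(1L, 1L - step[2]); chi <- min(nc, nc - step[2])
  counts <- matrix(0, R, R)
  if (rlo <= rhi && clo <= chi) {
    r1 <- rlo:rhi; c1 <- clo:chi
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + step[1], c1 + step[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      tab <- tabulate((a[ok] - 1L) * R + b[ok], nbins = R * R)
      counts <- matrix(tab, R, R, byrow = TRUE)
    }
  }
  counts <- counts + t(counts)
  pair_count <- sum(counts)
  structure(list(matrix = if (pair_count > 0) counts / pair_count else counts,
                 d = as.integer(d), theta = as.integer(theta),
                 pair_count = as.integer(pair_count)),
            class = "glcm")
}

#' Gray-level gradient co-occurrence matrix
#'
#' Joint histogram of each in-mask pixel's quantized gray level and quantized
#' gradient magnitude. Gradients are 3x3 Sobel responses computed on the
#' (denoised, unquantized) source intensities over the mask bounding box,
#' with out-of-mask pixels filled from their nearest in-mask neighbors so the
#' mask boundary does not create spurious gradients. Gradient magnitudes are
#' then discretized to `1..gradient_levels` by the same fixed-bin-number
#' scheme as the gray levels, and the matrix is normalized by the number of
#' in-mask pixels.
#'
#' @param q A `quantized_roi`.
#' @param source The `roi_image` whose intensities supply the gradients;
#'   defaults to the image `q` was built from. Must share the mask of `q`.
#' @param gradient_levels Number of gradient bins G (default 16).
#' @return List of class `glgcm`: `matrix` (range x G, sums to 1),
#'   `gradient_levels`, `n_pixels`.
#' @export
build_glgcm <- function(q, source = q$source, gradient_levels = 16L) {
  stopifnot(inherits(q, "quantized_roi"), inherits(source, "roi_image"))
  if (!identical(dim(source$mask), dim(q$mask)) || !all(source$mask == q$mask))
    stop("`source` and `q` must share the same mask", call. = FALSE)
  G <- as.integer(gradient_levels)
  bb <- mask_bbox(q$mask, pad = 1L)
  patch <- source$pixels[bb$r, bb$c, drop = FALSE]
  maskp <- q$mask[bb$r, bb$c, drop = FALSE]
  patch[!maskp] <- NA_real_
  patch <- fill_from_mask(patch)
  gmag <- sobel_magnitude(patch)[maskp]
  lo <- min(gmag); hi <- max(gmag)
  glev <- as.integer(floor(G * (gmag - lo) / (hi - lo + 1))) + 1L
  ilev <- q$levels[bb$r, bb$c, drop = FALSE][maskp]
  R <- q$range
  tab <- tabulate((ilev - 1L) * G + glev, nbins = R * G)
  counts <- matrix(tab, R, G, byrow = TRUE)
  structure(list(matrix = counts / sum(counts), gradient_levels = G,
                 n_pixels = sum(maskp)),
            class = "glgcm")
}

# Fill NA cells from already-known neighbors by repeated 8-neighbor
# propagation (grassfire order, so values come from the nearest known pixel).
fill_from_mask <- function(M) {
  while (anyNA(M)) {
    known <- !is.na(M)
    acc <- matrix(0, nrow(M), ncol(M))
    cnt <- matrix(0, nrow(M), ncol(M))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- shift_matrix(M, dr, dc)
      ok <- !is.na(sh)
      acc[ok] <- acc[ok] + sh[ok]
      cnt <- cnt + ok
    }
    fill <- !known & cnt > 0
    if (!any(fill)) break
    M[fill] <- acc[fill] / cnt[fill]
  }
  M
}

# Shift with NA padding: result[r,c] = M[r+dr, c+dc] where defined.
shift_matrix <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(NA_real_, nr, nc)
  r <- max(1L, 1L - dr):min(nr, nr - dr)
  c <- max(1L, 1L - dc):min(nc, nc - dc)
  out[r, c] <- M[r + dr, c + dc, drop = FALSE]
  out
}

# 3x3 Sobel gradient magnitude with replicate padding at the patch border.
sobel_magnitude <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  P <- M[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc), drop = FALSE]
  s <- function(dr, dc) P[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc, drop = FALSE]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along lines of direction `theta`.
#' Runs are truncated at the mask boundary: a run never spans an out-of-mask
#' pixel.
#'
#' @param q A `quantized_roi`.
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @return List of class `glrlm`: `matrix` (range x max-run-length counts),
#'   `theta`, `n_pixels` (in-mask pixels), `n_runs`.
#' @export
build_glrlm <- function(q, theta = 0L) {
  stopifnot(inherits(q, "quantized_roi"))
  bb <- mask_bbox(q$mask)
  lev <- q$levels[bb$r, bb$c, drop = FALSE]
  nr <- nrow(lev); nc <- ncol(lev)
  lines <- switch(as.character(theta),
    "0"   = split(as.vector(t(lev)), rep(seq_len(nr), each = nc)),
    "90"  = split(as.vector(lev), rep(seq_len(nc), each = nr)),
    "45"  = diagonal_lines(lev, anti = TRUE),
    "135" = diagonal_lines(lev, anti = FALSE),
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
  R <- q$range
  Lmax <- max(nr, nc)
  M <- matrix(0, R, Lmax)
  for (v in lines) {
    v[is.na(v)] <- 0L
    r <- rle(v)
    keep <- r$values > 0L
    if (any(keep)) {
      idx <- cbind(r$values[keep], r$lengths[keep])
      for (k in seq_len(nrow(idx))) M[idx[k, 1], idx[k, 2]] <- M[idx[k, 1], idx[k, 2]] + 1
    }
  }
  structure(list(matrix = M, theta = as.integer(theta),
                 n_pixels = sum(q$mask), n_runs = sum(M)),
            class = "glrlm")
}

# Lines of constant row+col (anti = TRUE, the 45 deg lines) or row-col
# (135 deg lines), each ordered along the line.
diagonal_lines <- function(M, anti = FALSE) {
  nr <- nrow(M); nc <- ncol(M)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  key <- if (anti) rows + cols else rows - cols
  ord <- order(key, rows)
  split(as.vector(M)[ord], key[ord])
}

#' Intensity-size-zone matrix
#'
#' Labels connected iso-level in-mask zones (components of pixels sharing one
#' gray level) and counts them by level and size.
#'
#' @param q A `quantized_roi`.
#' @param connectivity Zone connectivity, 4 or 8 (default 8).
#' @return List of class `iszm`: `matrix` (range x max-zone-size counts),
#'   `n_zones`, `n_pixels`, `connectivity`.
#' @export
build_iszm <- function(q, connectivity = 8L) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  bb <- mask_bbox(q$mask)
  lev <- q$levels[bb$r, bb$c, drop = FALSE]
  R <- q$range
  n_pixels <- sum(!is.na(lev))
  M <- matrix(0, R, n_pixels)
  for (i in sort(unique(lev[!is.na(lev)]))) {
    comp <- label_components(!is.na(lev) & lev == i, connectivity)
    if (max(comp) > 0L) {
      sizes <- tabulate(comp[comp > 0L])
      for (s in sizes) M[i, s] <- M[i, s] + 1
    }
  }
  structure(list(matrix = M, n_zones = sum(M), n_pixels = n_pixels,
                 connectivity = as.integer(connectivity)),
            class = "iszm")
}
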