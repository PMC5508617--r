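#' Region-of-interest image
#'
#' Bundles a 2-D grayscale slice with a binary lesion mask. The mask defines
#' the pixel set over which every texture feature is computed; nothing outside
#' it ever enters a feature value.
#'
#' @param pixels Numeric matrix of image intensities (arbitrary units).
#' @param mask Logical (or 0/1) matrix of the same shape; `TRUE` marks
#'   in-lesion pixels. Must contain at least 16 pixels forming a single
#'   8-connected component.
#' @param subject_id Character scalar identifying the subject.
#' @param label Optional class label (e.g. one of the three lesion classes).
#' @param replicate Optional replicate tag, `"test"` or `"retest"`, for
#'   test-retest reproducibility pairs.
#'
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(pixels, mask, subject_id = "subject",
                      label = NULL, replicate = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  mask <- matrix(as.logical(mask), nrow = nrow(pixels))
  if (!identical(dim(pixels), dim(mask)))
    stop("`pixels` and `mask` must have identical dimensions", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite (subject ", subject_id, ")",
         call. = FALSE)
  n_in <- sum(mask)
  if (n_in < 16L)
    stop("mask of subject ", subject_id, " has ", n_in,
         " pixels; at least 16 are required", call. = FALSE)
  if (!mask_is_connected(mask))
    stop("mask of subject ", subject_id,
         " is not a single 8-connected component", call. = FALSE)
  if (!is.null(replicate))
    replicate <- match.arg(replicate, c("test", "retest"))
  structure(
    list(pixels = pixels, mask = mask, subject_id = as.character(subject_id),
         label = if (is.null(label)) NA_character_ else as.character(label),
         replicate = replicate),
    class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  rng <- range(x$pixels[x$mask])
  cat(sprintf("<roi_image> subject %s%s: %dx%d slice, %d in-mask pixels, intensity [%.3g, %.3g]\n",
              x$subject_id,
              if (is.na(x$label)) "" else paste0(" (", x$label, ")"),
              nrow(x$pixels), ncol(x$pixels), sum(x$mask), rng[1], rng[2]))
  invisible(x)
}

# 8-connectivity check: grow from one seed pixel until fixpoint.
mask_is_connected <- function(mask) {
  comp <- label_components(mask, connectivity = 8L)
  max(comp, na.rm = TRUE) == 1L
}

#' Label connected components of a logical matrix
#'
#' Iterative flood fill used for mask validation and for the iso-level zones
#' of the intensity-size-zone matrix.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix: 0 outside `mask`, otherwise the component id
#'   (1-based, in first-encounter order).
#' @keywords internal
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else if (connectivity == 8L) {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  } else stop("connectivity must be 4 or 8", call. = FALSE)
  todo <- which(mask)
  current <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    stack <- seed
    lab[seed] <- current
    while (length(stack)) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- ((px - 1L) %% nr) + 1L
      c0 <- ((px - 1L) %/% nr) + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- current
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Quantized region of interest
#'
#' Integer gray levels on the mask produced by the fixed-bin-number
#' discretization (see [quantize()]); levels span `1..range`, pixels outside
#' the mask are `NA` and are never counted by any matrix builder.
#'
#' @param levels Integer matrix, `NA` outside the mask.
#' @param range Number of gray levels (>= 2). The discretization pipeline
#'   ([quantize()]) only produces 16, 32, 64 or 128; the container accepts
#'   any level count so matrices can be built on hand-crafted level maps.
#' @param mask Logical matrix matching `levels`.
#' @param source The `roi_image` the levels were derived from (kept for
#'   provenance; only its denoised intensities are re-used downstream).
#' @return An object of class `quantized_roi`.
#' @export
quantized_roi <- function(levels, range, mask, source = NULL) {
  range <- as.integer(range)
  if (range < 2L) stop("`range` must be >= 2", call. = FALSE)
  storage.mode(levels) <- "integer"
  inm <- levels[mask]
  if (anyNA(inm) || any(inm < 1L) || any(inm > range))
    stop("in-mask levels must lie in [1, range]", call. = FALSE)
  structure(list(levels = levels, range = range, mask = mask, source = source),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d gray levels, %d in-mask pixels, levels used: %d\n",
              x$range, sum(x$mask), length(unique(x$levels[x$mask]))))
  invisible(x)
}

# Tight bounding box of the mask, optionally padded (clipped to the image).
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  list(r = max(1L, min(idx[, 1]) - pad):min(nrow(mask), max(idx[, 1]) + pad),
       c = max(1L, min(idx[, 2]) - pad):min(ncol(mask), max(idx[, 2]) + pad))
}
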