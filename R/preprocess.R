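#' Adaptive Wiener denoising
#'
#' Local-mean / local-variance (pixel-wise adaptive) Wiener filtering of the
#' whole slice. Within each `window` x `window` neighborhood the local mean
#' \eqn{\mu} and variance \eqn{\sigma^2} are computed (edge windows are
#' truncated to the image), the noise power \eqn{\nu^2} is estimated as the
#' mean of the local variances, and the output is
#' \deqn{\hat I = \mu + \frac{\max(\sigma^2-\nu^2, 0)}{\max(\sigma^2, \nu^2)} (I - \mu).}
#' Where the local variance falls below the noise estimate the filter returns
#' the local mean. The mask is untouched; filtering precedes discretization.
#'
#' @param image A `roi_image`.
#' @param window Odd neighborhood side length in pixels (default 3).
#' @return A `roi_image` with filtered intensities.
#' @export
wiener_denoise <- function(image, window = 3L) {
  stopifnot(inherits(image, "roi_image"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  I <- image$pixels
  n <- box_sum(matrix(1, nrow(I), ncol(I)), window)
  mu <- box_sum(I, window) / n
  sigma2 <- pmax(box_sum(I * I, window) / n - mu^2, 0)
  nu2 <- mean(sigma2)
  gain <- ifelse(sigma2 > nu2, (sigma2 - nu2) / sigma2, 0)
  out <- image
  out$pixels <- mu + gain * (I - mu)
  out
}

# Sliding-window sum with edge truncation, via an integral image.
box_sum <- function(M, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(M); nc <- ncol(M)
  S <- apply(apply(M, 2L, cumsum), 1L, cumsum)  # S is t(cumsum2), nc x nr
  S <- t(S)
  S <- rbind(0, cbind(0, S))                    # (nr+1) x (nc+1), S[i+1,j+1]=sum M[1:i,1:j]
  r2 <- pmin(seq_len(nr) + h, nr); r1 <- pmax(seq_len(nr) - h, 1L)
  c2 <- pmin(seq_len(nc) + h, nc); c1 <- pmax(seq_len(nc) - h, 1L)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

#' Fixed-bin-number gray-level discretization
#'
#' Resamples in-mask intensities onto `range` integer gray levels:
#' \deqn{p(x) = \left\lfloor Range \times \frac{I(x) - \min_{\Theta} I}
#'   {\max_{\Theta} I - \min_{\Theta} I + 1} \right\rfloor}
#' with \eqn{\Theta} the in-mask pixel set, and stored level \eqn{p(x)+1} so
#' levels span `1..range` (several run-length and size-zone features divide
#' by the squared gray level, so level 0 must not occur). A constant ROI maps
#' to level 1 everywhere. The min and max are taken over in-mask pixels only.
#'
#' @param image A `roi_image` (normally already denoised).
#' @param range Number of gray levels: 16, 32, 64 or 128 (default 32).
#' @return A `quantized_roi`.
#' @export
quantize <- function(image, range = 32L) {
  stopifnot(inherits(image, "roi_image"))
  range <- as.integer(range)
  if (!range %in% c(16L, 32L, 64L, 128L))
    stop("`range` must be one of 16, 32, 64, 128", call. = FALSE)
  inm <- image$pixels[image$mask]
  lo <- min(inm); hi <- max(inm)
  lev <- matrix(NA_integer_, nrow(image$pixels), ncol(image$pixels))
  lev[image$mask] <- as.integer(floor(range * (inm - lo) / (hi - lo + 1))) + 1L
  quantized_roi(lev, range, image$mask, source = image)
}
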