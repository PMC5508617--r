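# Gabor wavelet filter bank: 5 scales x 8 orientations, geometrically spaced
# center frequencies, DC-corrected complex kernels. Responses are computed by
# FFT convolution of the ROI bounding-box patch (out-of-mask pixels replaced
# by a fill value), so kernels larger than the ROI need no special casing.

#' Build a Gabor filter bank
#'
#' `n_scales` center frequencies geometrically spaced from `f_high` (scale
#' nu = 0) down to `f_low` (largest nu), and `n_orientations` orientations at
#' angles mu * pi / n_orientations. Each kernel is a complex sinusoid under
#' an isotropic Gaussian envelope (sigma = 0.56 / f, a one-octave bandwidth),
#' truncated at 3 sigma and DC-corrected so its coefficients sum to zero —
#' a constant image therefore gives zero response at every filter.
#'
#' @param n_scales Number of scales (default 5).
#' @param n_orientations Number of orientations (default 8).
#' @param f_low,f_high Frequency bounds in cycles/pixel,
#'   0 < f_low < f_high <= 0.5.
#' @return Object of class `gabor_bank`: list with `kernels` (list indexed
#'   `[[nu+1]][[mu+1]]` of complex matrices), `frequencies`, `orientations`
#'   (radians) and the design parameters.
#' @export
gabor_bank <- function(n_scales = 5L, n_orientations = 8L,
                       f_low = 0.05, f_high = 0.4) {
  if (!(f_low > 0 && f_low < f_high && f_high <= 0.5))
    stop("need 0 < f_low < f_high <= 0.5", call. = FALSE)
  freqs <- f_high * (f_low / f_high)^((seq_len(n_scales) - 1) / (n_scales - 1))
  angles <- (seq_len(n_orientations) - 1) * pi / n_orientations
  kernels <- lapply(freqs, function(f) {
    sigma <- 0.56 / f
    h <- ceiling(3 * sigma)
    x <- matrix(-h:h, 2 * h + 1, 2 * h + 1, byrow = TRUE)   # +column axis
    y <- matrix(h:-h, 2 * h + 1, 2 * h + 1)                 # +y = image "up"
    env <- exp(-(x^2 + y^2) / (2 * sigma^2))
    lapply(angles, function(th) {
      g <- env * exp(2i * pi * f * (x * cos(th) + y * sin(th)))
      g - env * (sum(g) / sum(env))
    })
  })
  structure(list(kernels = kernels, frequencies = freqs,
                 orientations = angles, n_scales = n_scales,
                 n_orientations = n_orientations,
                 f_low = f_low, f_high = f_high),
            class = "gabor_bank")
}

.gabor_cache <- new.env(parent = emptyenv())

# FFT of each kernel zero-padded to N, kernel center at (1,1) with wrap;
# cached per (N, bank design) because cohort ROIs share few distinct sizes.
bank_ffts <- function(bank, N) {
  key <- paste(N[1], N[2], bank$n_scales, bank$n_orientations,
               bank$f_low, bank$f_high, sep = "|")
  if (!is.null(.gabor_cache[[key]])) return(.gabor_cache[[key]])
  out <- lapply(bank$kernels, function(scale) lapply(scale, function(k) {
    h <- (nrow(k) - 1L) %/% 2L
    kp <- matrix(0i, N[1], N[2])
    idx_r <- ((-h:h) %% N[1]) + 1L
    idx_c <- ((-h:h) %% N[2]) + 1L
    kp[idx_r, idx_c] <- k
    stats::fft(kp)
  }))
  .gabor_cache[[key]] <- out
  out
}

#' Gabor wavelet texture features
#'
#' Convolves the ROI bounding-box patch (out-of-mask pixels replaced by the
#' in-mask mean, or zero) with every filter in the bank and summarizes the
#' complex response over in-mask pixels: `S` (mean square energy, mean of
#' |response|^2) and `A` (mean amplitude, mean of |response|), 40 + 40
#' values for the default 5 x 8 bank.
#'
#' @param image A `roi_image` (normally denoised; Gabor features use raw,
#'   unquantized intensities).
#' @param bank A [gabor_bank()].
#' @param fill Out-of-mask fill rule: `"mean"` (default) or `"zero"`.
#' @return Named numeric vector `GWTF_S_gabor-<nu><mu>` then
#'   `GWTF_A_gabor-<nu><mu>`.
#' @export
gabor_features <- function(image, bank = gabor_bank(), fill = c("mean", "zero")) {
  stopifnot(inherits(image, "roi_image"), inherits(bank, "gabor_bank"))
  fill <- match.arg(fill)
  bb <- mask_bbox(image$mask)
  patch <- image$pixels[bb$r, bb$c, drop = FALSE]
  maskp <- image$mask[bb$r, bb$c, drop = FALSE]
  fillval <- if (fill == "mean") mean(patch[maskp]) else 0
  patch[!maskp] <- fillval
  maxh <- (nrow(bank$kernels[[bank$n_scales]][[1]]) - 1L) %/% 2L
  N <- c(stats::nextn(nrow(patch) + 2L * maxh, c(2, 3, 5)),
         stats::nextn(ncol(patch) + 2L * maxh, c(2, 3, 5)))
  canvas <- matrix(fillval, N[1], N[2])
  canvas[seq_len(nrow(patch)), seq_len(ncol(patch))] <- patch
  Fc <- stats::fft(canvas)
  kf <- bank_ffts(bank, N)
  inmask <- which(maskp)
  npx <- N[1] * N[2]
  S <- A <- matrix(NA_real_, bank$n_scales, bank$n_orientations)
  for (nu in seq_len(bank$n_scales)) {
    for (mu in seq_len(bank$n_orientations)) {
      resp <- stats::fft(Fc * kf[[nu]][[mu]], inverse = TRUE) / npx
      mag <- Mod(resp[seq_len(nrow(patch)), seq_len(ncol(patch))][inmask])
      S[nu, mu] <- mean(mag^2)
      A[nu, mu] <- mean(mag)
    }
  }
  idx <- paste0(rep(seq_len(bank$n_scales) - 1L, each = bank$n_orientations),
                rep(seq_len(bank$n_orientations) - 1L, bank$n_scales))
  stats::setNames(c(as.vector(t(S)), as.vector(t(A))),
                  c(paste0("GWTF_S_gabor-", idx), paste0("GWTF_A_gabor-", idx)))
}
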