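test_that("GLCM matches hand enumeration and handles degenerate cases", {
  # 2x2 ROI [[1,1],[2,2]] (rows), d=1, 0 deg: two horizontal pairs + transpose
  q <- make_qroi(rbind(c(1L, 1L), c(2L, 2L)), 4L)
  g <- build_glcm(q, 1, 0)
  want <- matrix(0, 4, 4); want[1, 1] <- 0.5; want[2, 2] <- 0.5
  expect_equal(g$matrix, want)
  expect_equal(g$pair_count, 4L)
  # constant ROI: single nonzero entry = 1
  qc <- quantize(constant_roi(5, 9), 16)
  gc <- build_glcm(qc, 2, 45)
  expect_equal(sum(gc$matrix), 1)
  expect_equal(gc$matrix[1, 1], 1)
  # no valid pair at d = 8 on a 3-pixel-wide ROI: zero-pair matrix flagged
  q3 <- make_qroi(matrix(1:3, 1, 3), 4L)
  g0 <- build_glcm(q3, 8, 0)
  expect_equal(g0$pair_count, 0L)
  expect_equal(sum(g0$matrix), 0)
})

test_that("GLCM equals the brute-force enumerator on random masked ROIs", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(8:12, 1)
    lev <- random_levels(n, n, R = 6L)
    q <- make_qroi(lev, 16L)
    for (d in c(1, 2, 4, 8)) for (th in c(0, 45, 90, 135)) {
      got <- build_glcm(q, d, th)
      want <- oracle_glcm(lev, 16L, d, th)
      expect_equal(got$matrix, want, tolerance = 1e-12,
                   label = sprintf("glcm d=%d theta=%d rep=%d", d, th, rep))
    }
  }
})

test_that("GLCM invariants: symmetry, normalization, mask-only contract", {
  set.seed(11)
  lev <- random_levels(10, 10, R = 5L)
  q <- make_qroi(lev, 16L)
  for (th in c(0, 45, 90, 135)) {
    g <- build_glcm(q, 1, th)
    expect_equal(g$matrix, t(g$matrix))
    expect_equal(sum(g$matrix), 1)
  }
  # changing out-of-mask levels changes nothing
  lev2 <- lev
  lev2[is.na(lev)] <- 3L
  q2 <- quantized_roi(lev2, 16L, !is.na(lev))
  # rebuild with identical mask: out-of-mask entries are NA-sentinels inside
  q2$levels[!q2$mask] <- NA_integer_
  expect_equal(build_glcm(q2, 2, 45)$matrix, build_glcm(q, 2, 45)$matrix)
})

test_that("rotating the ROI by 90 degrees permutes GLCM directions", {
  set.seed(13)
  lev <- random_levels(9, 9, R = 5L, p_mask = 1)
  q <- make_qroi(lev, 16L)
  # counter-clockwise rotation maps 0 deg offsets onto 90 deg offsets
  rot <- apply(t(lev), 2, rev)     # counter-clockwise quarter turn
  qr <- make_qroi(rot, 16L)
  expect_equal(build_glcm(qr, 2, 90)$matrix, build_glcm(q, 2, 0)$matrix)
  expect_equal(build_glcm(qr, 1, 135)$matrix, build_glcm(q, 1, 45)$matrix)
})

test_that("GLRLM matches hand runs and the line-scanning oracle", {
  # row [1,1,1,2,2]: runs (1,3) and (2,2)
  q <- make_qroi(matrix(c(1L, 1L, 1L, 2L, 2L), 1, 5), 4L)
  g <- build_glrlm(q, 0)
  expect_equal(g$matrix[1, 3], 1)
  expect_equal(g$matrix[2, 2], 1)
  expect_equal(g$n_runs, 2)
  # all-distinct levels: every run has length 1
  lev <- matrix(1:9, 3, 3)
  g <- build_glrlm(make_qroi(lev, 16L), 45)
  expect_equal(sum(g$matrix), 9)
  expect_true(all(g$matrix[, -1] == 0))
  set.seed(19)
  for (rep in 1:10) {
    lev <- random_levels(sample(8:12, 1), sample(8:12, 1), R = 4L)
    q <- make_qroi(lev, 16L)
    for (th in c(0, 45, 90, 135)) {
      got <- build_glrlm(q, th)
      want <- oracle_glrlm(lev, 16L, th)
      expect_equal(got$matrix[, seq_len(ncol(want))], want,
                   tolerance = 1e-12,
                   label = sprintf("glrlm theta=%d rep=%d", th, rep))
      # pixel-count identity
      j <- matrix(seq_len(ncol(got$matrix)), nrow(got$matrix),
                  ncol(got$matrix), byrow = TRUE)
      expect_equal(sum(j * got$matrix), sum(!is.na(lev)))
    }
  }
})

test_that("ISZM matches hand zones and the label-propagation oracle", {
  # constant 3x3 ROI: one zone of size 9
  g <- build_iszm(make_qroi(matrix(2L, 3, 3), 4L))
  expect_equal(g$n_zones, 1)
  expect_equal(g$matrix[2, 9], 1)
  # two disjoint 4-pixel squares of the same level
  lev <- matrix(1L, 5, 5)
  lev[1:2, 1:2] <- 3L; lev[4:5, 4:5] <- 3L
  g <- build_iszm(make_qroi(lev, 4L), connectivity = 4)
  expect_equal(g$matrix[3, 4], 2)
  set.seed(23)
  for (rep in 1:8) {
    lev <- random_levels(sample(8:12, 1), sample(8:12, 1), R = 3L)
    for (conn in c(4L, 8L)) {
      got <- build_iszm(make_qroi(lev, 16L), conn)
      want <- oracle_iszm(lev, 16L, conn)
      expect_equal(got$matrix, want, tolerance = 1e-12,
                   label = sprintf("iszm conn=%d rep=%d", conn, rep))
      s <- matrix(seq_len(ncol(got$matrix)), nrow(got$matrix),
                  ncol(got$matrix), byrow = TRUE)
      expect_equal(sum(s * got$matrix), got$n_pixels)
      expect_equal(sum(got$matrix), got$n_zones)
    }
  }
})

test_that("GLGCM: degenerate, ramp and brute-force histogram cases", {
  # constant image: all gradients zero, single nonzero column, sums to 1
  roi <- constant_roi(6, 10)
  m <- build_glgcm(quantize(roi, 16), roi)
  expect_equal(sum(m$matrix), 1)
  expect_equal(sum(m$matrix[, 1] > 0), 1)
  expect_true(all(m$matrix[, -1] == 0))
  # pure linear ramp: constant Sobel magnitude in the interior (the two
  # replicate-padded border columns see half the slope) -> the interior
  # gradient level carries 120/144 of the mass
  M <- matrix(rep(seq(0, 60, length.out = 12), each = 12), 12, 12)
  roi <- roi_image(M, matrix(TRUE, 12, 12))
  m <- build_glgcm(quantize(roi, 16), roi)
  col_mass <- colSums(m$matrix)
  expect_gt(max(col_mass), 120 / 144 - 1e-9)
  # and the raw Sobel response to the ramp is analytic: 8 x slope
  s <- livertex:::sobel_magnitude(M)
  expect_equal(unique(round(as.vector(s[2:11, 2:11]), 9)),
               round(8 * 60 / 11, 9))
  # random full-mask ROI equals a per-pixel joint histogram oracle
  set.seed(29)
  M <- matrix(stats::runif(100, 0, 40), 10, 10)
  roi <- roi_image(M, matrix(TRUE, 10, 10))
  q <- quantize(roi, 16)
  m <- build_glgcm(q, roi, gradient_levels = 8L)
  # oracle: explicit Sobel loops with replicate padding
  P <- M[c(1, 1:10, 10), c(1, 1:10, 10)]
  gm <- matrix(0, 10, 10)
  for (r in 1:10) for (c in 1:10) {
    w <- P[r:(r + 2), c:(c + 2)]
    gx <- sum(w[, 3] * c(1, 2, 1)) - sum(w[, 1] * c(1, 2, 1))
    gy <- sum(w[3, ] * c(1, 2, 1)) - sum(w[1, ] * c(1, 2, 1))
    gm[r, c] <- sqrt(gx^2 + gy^2)
  }
  glev <- floor(8 * (gm - min(gm)) / (max(gm) - min(gm) + 1)) + 1
  H <- matrix(0, 16, 8)
  for (r in 1:10) for (c in 1:10)
    H[q$levels[r, c], glev[r, c]] <- H[q$levels[r, c], glev[r, c]] + 1
  expect_equal(m$matrix, H / 100, tolerance = 1e-12)
  # mask mismatch is a validation error
  other <- constant_roi(10, 1)
  other$mask[1, 1] <- FALSE
  other$mask[2, 2] <- TRUE
  expect_error(build_glgcm(q, other), "mask")
})
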