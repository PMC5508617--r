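# Independent brute-force oracles: explicit per-pixel loops, no shared code
# with the package implementations.

# quantized_roi straight from a level matrix (NA = outside mask)
make_qroi <- function(lev, range = 16L) {
  lev <- as.matrix(lev)
  storage.mode(lev) <- "integer"
  quantized_roi(lev, range, !is.na(lev))
}

# random masked level matrix, ~80% in-mask
random_levels <- function(nr, nc, R = 8L, p_mask = 0.8) {
  lev <- matrix(sample.int(R, nr * nc, replace = TRUE), nr, nc)
  lev[stats::runif(nr * nc) > p_mask] <- NA_integer_
  if (all(is.na(lev))) lev[1, 1] <- 1L
  lev
}

oracle_step <- function(theta)
  switch(as.character(theta), "0" = c(0, 1), "45" = c(-1, 1),
         "90" = c(-1, 0), "135" = c(-1, -1))

# symmetric normalized GLCM by ordered-pair enumeration
oracle_glcm <- function(lev, R, d, theta) {
  st <- oracle_step(theta) * d
  M <- matrix(0, R, R)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + st[1]; c2 <- c + st[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- lev[r, c]; b <- lev[r2, c2]
    if (is.na(a) || is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  if (sum(M) > 0) M / sum(M) else M
}

# run-length counts by explicit line walking
oracle_glrlm <- function(lev, R, theta) {
  st <- -oracle_step(theta)   # walk "forward" along the line
  nr <- nrow(lev); nc <- ncol(lev)
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  # line starts: cells with no in-bounds predecessor along st
  M <- matrix(0, R, max(nr, nc))
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (inb(r0 - st[1], c0 - st[2])) next
    r <- r0; c <- c0
    cur <- NA_integer_; len <- 0L
    flush <- function() if (!is.na(cur) && len > 0L)
      M[cur, len] <<- M[cur, len] + 1
    while (inb(r, c)) {
      v <- lev[r, c]
      if (is.na(v) || (!is.na(cur) && v != cur)) { flush(); cur <- NA; len <- 0L }
      if (!is.na(v)) { if (is.na(cur)) { cur <- v; len <- 1L } else len <- len + 1L }
      r <- r + st[1]; c <- c + st[2]
    }
    flush()
  }
  M
}

# iso-level zones via iterative min-label propagation (not a flood fill)
oracle_iszm <- function(lev, R, connectivity = 8L) {
  nr <- nrow(lev); nc <- ncol(lev)
  id <- matrix(seq_len(nr * nc), nr, nc)
  id[is.na(lev)] <- NA
  nb <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(id[r, c])) next
      for (o in nb) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(id[r2, c2]) || lev[r2, c2] != lev[r, c]) next
        if (id[r2, c2] < id[r, c]) { id[r, c] <- id[r2, c2]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  npix <- sum(!is.na(lev))
  M <- matrix(0, R, npix)
  for (u in unique(id[!is.na(id)])) {
    i <- lev[which(id == u)[1]]
    s <- sum(id == u, na.rm = TRUE)
    M[i, s] <- M[i, s] + 1
  }
  M
}

# direct-summation Haralick statistics of a normalized co-occurrence matrix
oracle_glcm_features <- function(p) {
  R <- nrow(p)
  en <- ent <- con <- hom <- idm <- iv <- cs <- ct <- 0
  mi <- mj <- 0
  for (i in 1:R) for (j in 1:R) { mi <- mi + i * p[i, j]; mj <- mj + j * p[i, j] }
  vi <- vj <- cov <- 0
  for (i in 1:R) for (j in 1:R) {
    vi <- vi + (i - mi)^2 * p[i, j]; vj <- vj + (j - mj)^2 * p[i, j]
    cov <- cov + (i - mi) * (j - mj) * p[i, j]
  }
  sa <- 0
  for (k in 2:(2 * R)) for (i in 1:R) for (j in 1:R)
    if (i + j == k) sa <- sa + k * p[i, j]
  sv <- 0
  for (i in 1:R) for (j in 1:R) sv <- sv + (i + j - sa)^2 * p[i, j]
  for (i in 1:R) for (j in 1:R) {
    v <- p[i, j]
    en <- en + v^2
    if (v > 0) ent <- ent - v * log(v)
    con <- con + (i - j)^2 * v
    hom <- hom + v / (1 + abs(i - j))
    idm <- idm + v / (1 + (i - j)^2)
    if (i != j) iv <- iv + v / (i - j)^2
    cs <- cs + (i + j - mi - mj)^3 * v
    ct <- ct + (i + j - mi - mj)^2 * v
  }
  corr <- if (vi > 0 && vj > 0) cov / sqrt(vi * vj) else 0
  c(Energy = en, Entropy = ent, Contrast = con, Correlation = corr,
    Homogeneity = hom, SumVariance = sv, ClusterShade = cs,
    ClusterTendency = ct, InverseDifferenceMoment = idm, InverseVariance = iv)
}

# direct-summation run-length statistics
oracle_glrlm_features <- function(M, n_pixels) {
  N <- sum(M)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    v <- M[i, j]
    sre <- sre + v / j^2; lre <- lre + v * j^2
    lgre <- lgre + v / i^2; hgre <- hgre + v * i^2
    srlge <- srlge + v / (i^2 * j^2); srhge <- srhge + v * i^2 / j^2
    lrlge <- lrlge + v * j^2 / i^2; lrhge <- lrhge + v * i^2 * j^2
  }
  gln <- sum(sapply(seq_len(nrow(M)), function(i) sum(M[i, ])^2))
  rln <- sum(sapply(seq_len(ncol(M)), function(j) sum(M[, j])^2))
  c(SRE = sre / N, LRE = lre / N, GLN = gln / N, RLN = rln / N,
    LGRE = lgre / N, HGRE = hgre / N, SRLGE = srlge / N, SRHGE = srhge / N,
    LRLGE = lrlge / N, LRHGE = lrhge / N, RunPercentage = N / n_pixels)
}

# direct-summation size-zone statistics
oracle_iszm_features <- function(M, n_pixels) {
  N <- sum(M)
  sze <- lze <- lie <- hie <- lisze <- hisze <- lilze <- hilze <- 0
  for (i in seq_len(nrow(M))) for (s in seq_len(ncol(M))) {
    v <- M[i, s]
    sze <- sze + v / s^2; lze <- lze + v * s^2
    lie <- lie + v / i^2; hie <- hie + v * i^2
    lisze <- lisze + v / (i^2 * s^2); hisze <- hisze + v * i^2 / s^2
    lilze <- lilze + v * s^2 / i^2; hilze <- hilze + v * i^2 * s^2
  }
  iv <- sum(sapply(seq_len(nrow(M)), function(i) sum(M[i, ])^2))
  szv <- sum(sapply(seq_len(ncol(M)), function(s) sum(M[, s])^2))
  c(SmallZoneEmphasis = sze / N, LargeZoneEmphasis = lze / N,
    IntensityVariability = iv / N, SizeZoneVariability = szv / N,
    ZonePercentage = N / n_pixels, LowIntensityEmphasis = lie / N,
    HighIntensityEmphasis = hie / N,
    LowIntensitySmallZoneEmphasis = lisze / N,
    HighIntensitySmallZoneEmphasis = hisze / N,
    LowIntensityLargeZoneEmphasis = lilze / N,
    HighIntensityLargeZoneEmphasis = hilze / N)
}

# direct-summation gray-gradient statistics of a normalized joint histogram
oracle_glgcm_features <- function(p) {
  R <- nrow(p); G <- ncol(p)
  pi_ <- rowSums(p); pg_ <- colSums(p)
  mi <- sum((1:R) * pi_); mg <- sum((1:G) * pg_)
  vi <- sum(((1:R) - mi)^2 * pi_); vg <- sum(((1:G) - mg)^2 * pg_)
  sge <- lge <- ge <- gdm <- gidm <- cov <- 0
  for (i in 1:R) for (g in 1:G) {
    v <- p[i, g]
    sge <- sge + v / g^2; lge <- lge + v * g^2; ge <- ge + v^2
    gdm <- gdm + (i - g)^2 * v; gidm <- gidm + v / (1 + (i - g)^2)
    cov <- cov + (i - mi) * (g - mg) * v
  }
  hent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  c(SmallGradientEmphasis = sge, LargeGradientEmphasis = lge,
    GrayInhomogeneity = sum(pi_^2), GradientInhomogeneity = sum(pg_^2),
    GradientEnergy = ge, MeanGray = mi, MeanGradient = mg,
    GrayVariance = vi, GradientVariance = vg,
    GradientCorrelation = if (vi > 0 && vg > 0) cov / sqrt(vi * vg) else 0,
    GrayEntropy = hent(pi_), GradientEntropy = hent(pg_),
    MixtureEntropy = hent(as.vector(p)),
    GradientDifferenceMoment = gdm,
    GradientInverseDifferenceMoment = gidm)
}

# small constant-ROI helper
constant_roi <- function(n = 8, value = 5, ...) {
  roi_image(matrix(value, n, n), matrix(TRUE, n, n), ...)
}
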