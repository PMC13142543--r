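# Independent brute-force oracles: explicit per-pixel / per-sample loops,
# coded from the definitions, sharing no code with the package internals.

oraclePopSD <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

oracleQuantileType7 <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracleLineSummary <- function(samples) {
  out <- numeric(0)
  for (ch in 1:3) {
    v <- samples[, ch]
    out <- c(out, mean(v), oraclePopSD(v), min(v),
             oracleQuantileType7(v, 0.25), oracleQuantileType7(v, 0.5),
             oracleQuantileType7(v, 0.75), max(v), max(v) - min(v))
  }
  for (ch in 1:3) {
    d <- numeric(nrow(samples) - 1)
    for (i in seq_along(d)) d[i] <- abs(samples[i + 1, ch] - samples[i, ch])
    out <- c(out, mean(d), max(d))
  }
  out
}

# Bilinear interpolation at one point, scalar loop form
oracleBilinear <- function(img, x, y, ch) {
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- min(max(floor(x), 0), W - 1); x1 <- min(x0 + 1, W - 1)
  y0 <- min(max(floor(y), 0), H - 1); y1 <- min(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  img[y0 + 1, x0 + 1, ch] * (1 - fx) * (1 - fy) +
    img[y0 + 1, x1 + 1, ch] * fx * (1 - fy) +
    img[y1 + 1, x0 + 1, ch] * (1 - fx) * fy +
    img[y1 + 1, x1 + 1, ch] * fx * fy
}

# Scalar HSV (hue in degrees) from one RGB triple
oracleHSV <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  h <- if (d == 0) 0
    else if (mx == r) 60 * (((g - b) / d) %% 6)
    else if (mx == g) 60 * ((b - r) / d + 2)
    else 60 * ((r - g) / d + 4)
  s <- if (mx == 0) 0 else d / mx
  c(h %% 360, s, mx)
}

# Scalar CIE Lab (sRGB, D65), independently coded from the standard
oracleLab <- function(r, g, b) {
  lin <- function(c) if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  rl <- lin(r); gl <- lin(g); bl <- lin(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / 0.95047); fy <- f(Y / 1); fz <- f(Z / 1.08883)
  c(L = min(max(116 * fy - 16, 0), 100),
    a = min(max(500 * (fx - fy), -128), 127),
    b = min(max(200 * (fy - fz), -128), 127))
}

oraclePixels <- function(img, space) {
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- matrix(0, H * W, 3)
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {   # column-major pixel order
    k <- k + 1L
    out[k, ] <- switch(space,
      rgb = c(img[i, j, 1], img[i, j, 2], img[i, j, 3]),
      hsv = oracleHSV(img[i, j, 1], img[i, j, 2], img[i, j, 3]),
      lab = oracleLab(img[i, j, 1], img[i, j, 2], img[i, j, 3]))
  }
  out
}

oracleHistogram <- function(v, lo, hi, B) {
  counts <- integer(B)
  for (x in v) {
    k <- floor((x - lo) / (hi - lo) * B) + 1
    if (k < 1) k <- 1
    if (k > B) k <- B
    counts[k] <- counts[k] + 1L
  }
  counts / length(v)
}

oracleCircularMeanSD <- function(deg) {
  r <- deg * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  R <- sqrt(s^2 + c^2)
  m <- (atan2(s, c) * 180 / pi) %% 360
  c(mean = m, sd = sqrt(-2 * log(max(min(R, 1), 1e-300))) * 180 / pi)
}

oracleTileMeans <- function(img, T) {
  H <- dim(img)[1]; W <- dim(img)[2]
  # boundaries: tile j covers columns (round((j-1)W/T), round(jW/T)]
  rb <- floor(seq(0, T) * H / T + 0.5)
  cb <- floor(seq(0, T) * W / T + 0.5)
  out <- numeric(0)
  for (i in seq_len(T)) for (j in seq_len(T)) for (ch in 1:3) {
    acc <- 0; n <- 0L
    for (r in (rb[i] + 1):rb[i + 1]) for (cc in (cb[j] + 1):cb[j + 1]) {
      acc <- acc + img[r, cc, ch]; n <- n + 1L
    }
    out <- c(out, acc / n)
  }
  out
}

oracleTexture <- function(img, entropyBins = 256) {
  H <- dim(img)[1]; W <- dim(img)[2]
  g <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    g[i, j] <- 0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] + 0.114 * img[i, j, 3]
  mag <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    gx <- (g[i, min(j + 1, W)] - g[i, max(j - 1, 1)]) / 2
    gy <- (g[min(i + 1, H), j] - g[max(i - 1, 1), j]) / 2
    mag[i, j] <- sqrt(gx^2 + gy^2)
  }
  m <- as.vector(mag)
  edge <- if (max(m) <= min(m)) 0 else {
    thr <- oracleOtsu(m, 256L)
    mean(m > thr)
  }
  p <- oracleHistogram(as.vector(g), 0, 1, entropyBins)
  p <- p[p > 0]
  c(mean(m), oraclePopSD(m), edge, -sum(p * log2(p)), oraclePopSD(as.vector(g)))
}

oracleOtsu <- function(v, K) {
  lo <- min(v); hi <- max(v)
  p <- oracleHistogram(v, lo, hi, K)
  best <- -Inf; bestK <- 1L
  for (k in seq_len(K - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * (1:k)) / w0
    mu1 <- sum(p[(k + 1):K] * ((k + 1):K)) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; bestK <- k }
  }
  lo + bestK * (hi - lo) / K
}

# Mean silhouette from explicit pairwise distances
oracleMeanSilhouette <- function(coords, labels) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- own[own != i]
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
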