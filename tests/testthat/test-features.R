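test_that("line sampling hits closed forms on constant and ramp images", {
  gray <- constantImage(c(0.5, 0.5, 0.5), 9, 7)
  for (k in c("main_diagonal", "anti_diagonal", "mid_horizontal", "mid_vertical")) {
    s <- sampleLine(gray, k, 13)$samples
    expect_identical(dim(s), c(13L, 3L))
    expect_equal(unname(s), matrix(0.5, 13, 3))
  }
  # horizontal ramp R = x/(W-1): bilinear interpolation is exact on a linear field
  W <- 9; H <- 5
  ramp <- array(0, dim = c(H, W, 3))
  ramp[, , 1] <- matrix(rep((seq_len(W) - 1) / (W - 1), each = H), H, W)
  s <- sampleLine(ramp, "mid_horizontal", 5)$samples
  expect_equal(unname(s[, 1]), c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-12)
  expect_equal(unname(s[, 2]), rep(0, 5))
  # main diagonal of the ramp is linear in x too
  sd <- sampleLine(ramp, "main_diagonal", 5)$samples
  expect_equal(unname(sd[, 1]), c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-12)
  # interpolated values match the scalar bilinear oracle at off-grid points
  img <- randomImage(3, 11, 8)
  s2 <- sampleLine(img, "anti_diagonal", 7)$samples
  t <- seq(0, 1, length.out = 7)
  for (i in seq_len(7)) for (ch in 1:3)
    expect_equal(unname(s2[i, ch]),
                 oracleBilinear(img, (11 - 1) * (1 - t[i]), (8 - 1) * t[i], ch),
                 tolerance = 1e-12)
})

test_that("horizontal flip of a square image mirrors the diagonal profiles", {
  # flip maps (x, y) -> (W-1-x, y), so the flipped main diagonal traverses the
  # original anti-diagonal with the same parameter t; summaries are
  # reversal-invariant anyway, so the diagonal summary blocks simply swap
  img <- randomImage(7, 12, 12)
  flipped <- img[, rev(seq_len(12)), , drop = FALSE]
  a <- sampleLine(flipped, "main_diagonal", 20)$samples
  b <- sampleLine(img, "anti_diagonal", 20)$samples
  expect_equal(unname(a), unname(b), tolerance = 1e-12)
})

test_that("line summaries equal an independent order-statistics oracle", {
  const <- sampleLine(constantImage(c(0.25, 0.5, 0.75), 8, 8), "mid_vertical", 10)
  s <- summarizeLine(const)
  for (ch in c("R", "G", "B")) {
    v <- c(R = 0.25, G = 0.5, B = 0.75)[[ch]]
    for (st in c("mean", "min", "q1", "median", "q3", "max"))
      expect_equal(s[[paste0(ch, "_", st)]], v)
    expect_equal(s[[paste0(ch, "_std")]], 0)
    expect_equal(s[[paste0(ch, "_range")]], 0)
    expect_equal(s[[paste0(ch, "_grad_mean")]], 0)
    expect_equal(s[[paste0(ch, "_grad_max")]], 0)
  }
  # linear 0 -> 1 profile: mean 1/2, mean abs first difference 1/(P-1)
  P <- 17
  lin <- list(line_kind = "mid_horizontal",
              samples = matrix(seq(0, 1, length.out = P), P, 3))
  sl <- summarizeLine(lin)
  expect_equal(sl[["R_mean"]], 0.5)
  expect_equal(sl[["G_grad_mean"]], 1 / (P - 1))
  expect_equal(sl[["B_grad_max"]], 1 / (P - 1))
  # random profiles vs brute-force recomputation
  for (seed in 1:5) {
    set.seed(seed)
    prof <- list(line_kind = "main_diagonal", samples = matrix(runif(33 * 3), 33, 3))
    expect_equal(unname(summarizeLine(prof)), oracleLineSummary(prof$samples),
                 tolerance = 1e-12)
  }
})

test_that("colour histograms are normalized and match per-pixel binning", {
  one <- constantImage(c(0.2, 0.6, 0.9), 6, 6)
  h1 <- colorHistograms(one, 16)
  for (h in h1) {
    expect_equal(sum(h), 1, tolerance = 1e-9)
    expect_identical(sum(h == 1), 1L)            # single occupied bin
  }
  # half-black / half-white: extreme RGB bins get 0.5 each
  bw <- constantImage(c(0, 0, 0), 8, 8)
  bw[, 5:8, ] <- 1
  hb <- colorHistograms(bw, 32)
  for (ch in c("rgb_R", "rgb_G", "rgb_B")) {
    expect_equal(hb[[ch]][1], 0.5)
    expect_equal(hb[[ch]][32], 0.5)
    expect_equal(sum(hb[[ch]][2:31]), 0)
  }
  # random image vs brute-force oracle in all three spaces
  img <- randomImage(11, 9, 7)
  got <- colorHistograms(img, 8)
  ranges <- list(rgb = list(c(0, 1), c(0, 1), c(0, 1)),
                 hsv = list(c(0, 360), c(0, 1), c(0, 1)),
                 lab = list(c(0, 100), c(-128, 127), c(-128, 127)))
  for (space in c("rgb", "hsv", "lab")) {
    px <- oraclePixels(img, space)
    chn <- list(rgb = c("R", "G", "B"), hsv = c("H", "S", "V"),
                lab = c("L", "a", "b"))[[space]]
    tol <- if (space == "lab") 1e-6 else 1e-9
    for (ci in 1:3) {
      r <- ranges[[space]][[ci]]
      expect_equal(got[[paste0(space, "_", chn[ci])]],
                   oracleHistogram(px[, ci], r[1], r[2], 8), tolerance = tol)
    }
  }
})

test_that("global colour statistics treat hue circularly", {
  const <- constantImage(c(0.3, 0.6, 0.1), 5, 5)
  g <- globalColorStats(const)
  expect_equal(unname(g[c("stat_rgb_R_mean", "stat_rgb_G_mean", "stat_rgb_B_mean")]),
               c(0.3, 0.6, 0.1))
  expect_equal(unname(g[c("stat_rgb_R_std", "stat_rgb_G_std", "stat_rgb_B_std")]),
               rep(0, 3))
  # hues at 350 and 10 degrees in equal measure average to 0, not 180
  # (exact RGB triples for full-saturation hues: 350 -> (1,0,1/6), 10 -> (1,1/6,0))
  img <- array(0, dim = c(2, 1, 3))
  img[1, 1, ] <- c(1, 0, 1 / 6); img[2, 1, ] <- c(1, 1 / 6, 0)
  gh <- globalColorStats(img)
  expect_true(gh[["stat_hsv_H_mean"]] < 1e-6 || gh[["stat_hsv_H_mean"]] > 360 - 1e-6)
  # random image: all stats match the per-pixel oracle
  rnd <- randomImage(13, 7, 6)
  got <- globalColorStats(rnd)
  for (space in c("rgb", "hsv", "lab")) {
    px <- oraclePixels(rnd, space)
    chn <- list(rgb = c("R", "G", "B"), hsv = c("H", "S", "V"),
                lab = c("L", "a", "b"))[[space]]
    tol <- if (space == "lab") 1e-6 else 1e-9
    for (ci in 1:3) {
      nm <- paste0("stat_", space, "_", chn[ci])
      if (space == "hsv" && ci == 1) {
        cs <- oracleCircularMeanSD(px[, 1])
        expect_equal(got[[paste0(nm, "_mean")]], unname(cs["mean"]), tolerance = tol)
        expect_equal(got[[paste0(nm, "_std")]], unname(cs["sd"]), tolerance = tol)
      } else {
        expect_equal(got[[paste0(nm, "_mean")]], mean(px[, ci]), tolerance = tol)
        expect_equal(got[[paste0(nm, "_std")]], oraclePopSD(px[, ci]), tolerance = tol)
      }
    }
  }
})

test_that("tile means partition the image exactly, including uneven sizes", {
  const <- constantImage(c(0.4, 0.2, 0.8), 8, 8)
  tm <- tileMeans(const, 2)
  expect_identical(length(tm), 12L)
  expect_equal(unname(tm), rep(c(0.4, 0.2, 0.8), 4))
  # left-half black, right-half white, T=2: R channel tiles 0,1,0,1 row-major
  bw <- constantImage(c(0, 0, 0), 8, 8); bw[, 5:8, ] <- 1
  t2 <- tileMeans(bw, 2)
  expect_equal(unname(t2[c("tile_r1_c1_R", "tile_r1_c2_R",
                           "tile_r2_c1_R", "tile_r2_c2_R")]), c(0, 1, 0, 1))
  # 7x5 image, T=2: column split {0..3},{4..6}, row split {0..2},{3..4}
  img <- randomImage(17, w = 7, h = 5)
  got <- tileMeans(img, 2)
  expect_equal(got[["tile_r1_c1_R"]], mean(img[1:3, 1:4, 1]), tolerance = 1e-12)
  expect_equal(got[["tile_r2_c2_B"]], mean(img[4:5, 5:7, 3]), tolerance = 1e-12)
  expect_equal(unname(got), oracleTileMeans(img, 2), tolerance = 1e-12)
  expect_error(tileMeans(randomImage(1, 3, 3), 4), class = "mediadeck_validation_error")
})

test_that("texture descriptors honor their degenerate and two-level cases", {
  expect_equal(unname(textureDescriptors(constantImage(c(0.5, 0.2, 0.7), 12, 12))),
               rep(0, 5))
  # half-black/half-white: exactly two equally occupied gray levels -> 1 bit
  bw <- constantImage(c(0, 0, 0), 12, 12); bw[, 7:12, ] <- 1
  tx <- textureDescriptors(bw)
  expect_equal(tx[["tex_intensity_entropy"]], 1)
  expect_gt(tx[["tex_gradient_mean"]], 0)
  expect_equal(tx[["tex_global_contrast"]], 0.5)   # popSD of {0,1} half each
})

test_that("texture descriptors match the per-pixel oracle on noise images", {
  for (seed in c(2, 4)) {
    img <- randomImage(seed, 20, 16)
    expect_equal(unname(textureDescriptors(img)), oracleTexture(img),
                 tolerance = 1e-9)
  }
  # large uniform-noise image: entropy near log2(256) sanity bound via oracle
  big <- randomImage(99, 64, 64)
  tx <- textureDescriptors(big)
  expect_equal(tx[["tex_intensity_entropy"]],
               oracleTexture(big)[4], tolerance = 1e-9)
})

test_that("adding noise to a flat image increases gradient and contrast", {
  base <- constantImage(c(0.5, 0.5, 0.5), 24, 24)
  prevG <- 0; prevC <- 0; okG <- 0L; okC <- 0L
  for (amp in c(0.02, 0.06, 0.12)) {
    gs <- sapply(1:10, function(s) {
      set.seed(1000 + s)
      noisy <- MediaDeck:::clip01(base + array(rnorm(24 * 24 * 3, sd = amp),
                                               dim = dim(base)))
      tx <- textureDescriptors(noisy)
      c(tx[["tex_gradient_mean"]], tx[["tex_global_contrast"]])
    })
    g <- mean(gs[1, ]); cc <- mean(gs[2, ])
    if (g >= prevG) okG <- okG + 1L
    if (cc >= prevC) okC <- okC + 1L
    prevG <- g; prevC <- cc
  }
  expect_identical(okG, 3L)
  expect_identical(okC, 3L)
})

test_that("the feature layout is a pure function of the configuration", {
  cfgs <- list(
    list(cfg = featureConfig(), len = 4 * 30 + 4 * 100 * 3 + 9 * 32 + 18 + 48 + 5),
    list(cfg = featureConfig(resamplePoints = 10, histBins = 8, tileGrid = 2,
                             includeRawProfiles = FALSE),
         len = 4 * 30 + 9 * 8 + 18 + 2 * 2 * 3 + 5),
    list(cfg = featureConfig(resamplePoints = 5, histBins = 4, tileGrid = 3),
         len = 4 * 30 + 4 * 5 * 3 + 9 * 4 + 18 + 27 + 5))
  expect_equal(cfgs[[1]]$len, 1679)               # documented default layout
  for (cs in cfgs) {
    expect_identical(featureLength(cs$cfg), as.integer(cs$len))
    expect_identical(length(featureNames(cs$cfg)), as.integer(cs$len))
    v1 <- extractFeatures(randomImage(1, 12, 10), cs$cfg)
    v2 <- extractFeatures(randomImage(2, 20, 24), cs$cfg)
    expect_identical(names(v1), featureNames(cs$cfg))
    expect_identical(names(v1), names(v2))
  }
})

test_that("feature vectors never contain NaN, even on degenerate images", {
  cfg <- featureConfig(resamplePoints = 8, histBins = 4, tileGrid = 2)
  for (img in list(constantImage(c(0, 0, 0), 4, 4),
                   constantImage(c(1, 1, 1), 4, 4),
                   constantImage(c(0.5, 0.5, 0.5), 2, 7))) {
    v <- extractFeatures(img, cfg)
    expect_true(all(is.finite(v)))
  }
  const <- extractFeatures(constantImage(c(0.1, 0.9, 0.4), 8, 8), cfg)
  expect_equal(unname(const[MediaDeck:::TEXTURE_NAMES]), rep(0, 5))
})

test_that("every extracted statistic agrees with the brute-force oracle", {
  # the full equivalence sweep lives in the acceptance suite; spot-check the
  # concatenated vector here so the assembly step itself is covered
  img <- randomImage(23, 15, 13)
  cfg <- featureConfig(resamplePoints = 9, histBins = 6, tileGrid = 3)
  v <- extractFeatures(img, cfg)
  expect_equal(unname(v[paste0("main_diagonal_",
    c("R_mean", "R_std", "R_min", "R_q1", "R_median", "R_q3", "R_max", "R_range"))]),
    oracleLineSummary(sampleLine(img, "main_diagonal", 9)$samples)[1:8],
    tolerance = 1e-12)
  expect_equal(unname(v[sprintf("hist_rgb_R_bin%02d", 1:6)]),
               oracleHistogram(oraclePixels(img, "rgb")[, 1], 0, 1, 6),
               tolerance = 1e-9)
  expect_equal(unname(v[MediaDeck:::TEXTURE_NAMES]), oracleTexture(img),
               tolerance = 1e-9)
  expect_equal(unname(v[paste0("tile_r", rep(1:3, each = 9), "_c",
                               rep(rep(1:3, each = 3), 3), "_",
                               rep(c("R", "G", "B"), 9))]),
               oracleTileMeans(img, 3), tolerance = 1e-12)
})

test_that("square-image horizontal flip swaps the diagonal summaries", {
  img <- randomImage(29, 16, 16)
  flipped <- img[, rev(seq_len(16)), , drop = FALSE]
  cfg <- featureConfig(resamplePoints = 21, includeRawProfiles = FALSE,
                       histBins = 4, tileGrid = 2)
  v0 <- extractFeatures(img, cfg)
  v1 <- extractFeatures(flipped, cfg)
  pick <- function(v, kind) unname(v[startsWith(names(v), kind)])
  # order statistics and |first differences| are reversal-invariant
  expect_equal(pick(v1, "main_diagonal"), pick(v0, "anti_diagonal"), tolerance = 1e-9)
  expect_equal(pick(v1, "anti_diagonal"), pick(v0, "main_diagonal"), tolerance = 1e-9)
  expect_equal(pick(v1, "mid_horizontal"), pick(v0, "mid_horizontal"), tolerance = 1e-9)
})

test_that("overlays mark the lines without touching the source image", {
  p <- writePng(constantImage(c(1, 1, 1), 40, 30))
  before <- sha256File(p)
  out <- renderLineOverlay(p, P = 20)
  expect_true(file.exists(out))
  expect_identical(sha256File(p), before)
  ov <- readImageRGB(out)
  expect_identical(dim(ov)[1:2], c(30L, 40L))     # preview-scaled == input here
  cols <- unique(round(matrix(ov, ncol = 3), 1))
  nonwhite <- cols[rowSums(abs(cols - 1) > 0.15) > 0, , drop = FALSE]
  expect_gte(nrow(nonwhite), 4)                   # four distinct line colours
})

test_that("feature matrices export deterministically with aligned metadata", {
  lib <- tmpLibrary()
  dt <- makeDuplicateTree(tempfile("dt-"), nUnique = 4, nDup = 0, seed = 61)
  importDirectory(lib, dt$root, "feat")
  cfg <- featureConfig(resamplePoints = 6, histBins = 4, tileGrid = 2)
  fs <- featureMatrix(lib, config = cfg)
  expect_s4_class(fs, "DeckFeatureSet")
  vals <- featureValues(fs)
  expect_identical(dim(vals), c(4L, featureLength(cfg)))
  expect_identical(S4Vectors::metadata(fs)$fingerprint, configFingerprint(cfg))

  out1 <- tempfile(fileext = ".csv"); out2 <- tempfile(fileext = ".csv")
  exportFeatureMatrix(lib, config = cfg, outPath = out1)
  exportFeatureMatrix(lib, config = cfg, outPath = out2)
  expect_identical(readLines(out1), readLines(out2))    # byte-identical
  expect_true(file.exists(paste0(out1, ".json")))

  back <- loadFeatureMatrix(out1)
  expect_equal(unname(featureValues(back)), unname(vals), tolerance = 1e-12)
  expect_identical(sourceLabels(back), rep("feat", 4))

  expect_error(featureMatrix(lib, assetIds = integer()),
               class = "mediadeck_validation_error")
  expect_error(featureMatrix(lib, assetIds = 999L),
               class = "mediadeck_notfound_error")
})
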