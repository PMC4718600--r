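demo_curve <- function() {
  list(theta = seq(0, 330, 30),
       values = c(5, 6, 9, 15, 22, 14, 8, 4, 10, 21, 28, 12))
}

test_that("the 12-point demo curve yields the expected positional features", {
  f <- extract_features(demo_curve(), modality = "bimodal")
  expect_equal(f[["GlobalMaximum"]], 28)
  expect_equal(f[["GlobalMinimum"]], 4)
  expect_equal(f[["GlobalMinimumAngle"]], 210)
  expect_equal(f[["MaximumLeft"]], 22)
  expect_equal(f[["MaximumAngleLeft"]], 120)
  expect_equal(f[["MaximumRight"]], 28)
  expect_equal(f[["MaximumAngleRight"]], 300)
  expect_equal(f[["PeakToPeakLeft"]], 18)
  expect_equal(f[["PeakToPeakRight"]], 24)
  # inner minimum searched strictly between the two peak angles
  expect_equal(f[["InnerMinimum"]], 4)
  expect_equal(f[["InnerMinimumAngle"]], 210)
  expect_equal(f[["InnerWidthLeft"]], 90)
  expect_equal(f[["InnerWidthRight"]], 90)
  expect_equal(f[["DeltaInnerWidth"]], 0)
  # outer arc wraps through 0
  expect_equal(f[["OuterMinimumAngle"]], 0)
  expect_equal(f[["OuterWidthLeft"]], 120)
  expect_equal(f[["OuterWidthRight"]], 60)
  expect_equal(f[["DeltaOuterWidth"]], -60)
  # unimodal-only feature absent
  expect_true(is.na(f[["CircularVariance"]]))
})

test_that("a constant curve degenerates gracefully", {
  cur <- list(theta = seq(0, 330, 30), values = rep(9, 12))
  f <- extract_features(cur, modality = "bimodal")
  expect_equal(f[["PeakToPeakLeft"]], 0)
  expect_equal(f[["PeakToPeakRight"]], 0)
  expect_equal(f[["Bandwidth50Right"]], 360)
  expect_true(is.na(f[["SkewnessRight"]]))
  fu <- extract_features(cur, modality = "unimodal")
  expect_equal(fu[["Bandwidth75Right"]], 360)
  expect_equal(fu[["CircularVariance"]], 1)
})

test_that("a noiseless symmetric bimodal profile gives symmetric features", {
  th1 <- seq(0, 359, 1)
  v <- eval_tuning("wG", c(10, 30, 120, 10, 30, 240, 4), th1, modality = "bimodal")
  f <- extract_features(list(theta = th1, values = v), modality = "bimodal")
  expect_equal(f[["MaximumAngleLeft"]], 120)
  expect_equal(f[["MaximumAngleRight"]], 240)
  expect_equal(f[["InnerMinimumAngle"]], 180)
  expect_equal(f[["DeltaInnerWidth"]], 0)
  expect_equal(f[["DeltaPeakToPeak"]], 0, tolerance = 1e-10)
  expect_equal(f[["DeltaSkewness"]], 0, tolerance = 1e-9)
})

test_that("direct-method angular features are quantized in 30-degree steps", {
  for (seed in 1:25) {
    v <- random_curve_values(seed)
    f <- extract_features(list(theta = seq(0, 330, 30), values = v),
                          modality = "bimodal")
    ang <- f[c("GlobalMinimumAngle", "MaximumAngleLeft", "MaximumAngleRight",
               "InnerMinimumAngle", "OuterMinimumAngle", "InnerWidthLeft",
               "InnerWidthRight", "DeltaInnerWidth", "OuterWidthLeft",
               "OuterWidthRight", "Bandwidth50Left", "Bandwidth50Right")]
    ang <- ang[!is.na(ang)]
    expect_true(all(ang %% 30 == 0), info = paste("seed", seed))
  }
})

test_that("adding a constant shifts rate features and fixes angle features", {
  th <- seq(0, 330, 30)
  v <- random_curve_values(42)
  f0 <- extract_features(list(theta = th, values = v), modality = "bimodal")
  f1 <- extract_features(list(theta = th, values = v + 13), modality = "bimodal")
  expect_equal(f1[["GlobalMaximum"]], f0[["GlobalMaximum"]] + 13)
  expect_equal(f1[["InnerMinimum"]], f0[["InnerMinimum"]] + 13)
  expect_equal(f1[["PeakToPeakLeft"]], f0[["PeakToPeakLeft"]])
  expect_equal(f1[["PeakToPeakRight"]], f0[["PeakToPeakRight"]])
  for (nm in c("MaximumAngleLeft", "MaximumAngleRight", "InnerMinimumAngle",
               "OuterMinimumAngle", "DeltaInnerWidth", "Bandwidth50Left")) {
    expect_equal(f1[[nm]], f0[[nm]], info = nm)
  }
})

test_that("mirror reflection swaps left and right features", {
  th <- seq(0, 330, 30)
  for (seed in c(3, 8, 15)) {
    v <- random_curve_values(seed)
    vm <- v[match((360 - th) %% 360, th)]
    f <- extract_features(list(theta = th, values = v), modality = "bimodal")
    g <- extract_features(list(theta = th, values = vm), modality = "bimodal")
    expect_equal(g[["MaximumLeft"]], f[["MaximumRight"]])
    expect_equal(g[["MaximumRight"]], f[["MaximumLeft"]])
    expect_equal(g[["MaximumAngleLeft"]], (360 - f[["MaximumAngleRight"]]) %% 360)
    expect_equal(g[["DeltaInnerWidth"]], -f[["DeltaInnerWidth"]])
    expect_equal(g[["DeltaPeakToPeak"]], -f[["DeltaPeakToPeak"]])
    if (!is.na(f[["DeltaSkewness"]])) {
      expect_equal(g[["DeltaSkewness"]], -f[["DeltaSkewness"]], tolerance = 1e-9)
    }
  }
})

test_that("feature extraction matches the exhaustive-scan oracle", {
  th <- seq(0, 330, 30)
  for (seed in 1:200) {
    v <- random_curve_values(seed)
    f <- extract_features(list(theta = th, values = v), modality = "bimodal")
    o <- oracle_scan_features(th, v, "bimodal")
    for (nm in names(o)) {
      expect_equal(f[[nm]], o[[nm]], info = paste("seed", seed, nm))
    }
    fu <- extract_features(list(theta = th, values = v), modality = "unimodal")
    ou <- oracle_scan_features(th, v, "unimodal")
    for (nm in names(ou)) {
      expect_equal(fu[[nm]], ou[[nm]], info = paste("seed", seed, "uni", nm))
    }
  }
})

test_that("sampling a fit reproduces grid values and locates the peak", {
  th <- seq(0, 330, 30)
  y <- eval_tuning("wG", c(20, 40, 237, 5), th)
  fit <- tunefit(tuning_curve(y, sigma = rep(1, 12)), "wG")
  s30 <- sample_curve(fit, resolution = 30)
  expect_equal(s30$values, fitted(fit), tolerance = 1e-8)
  s1 <- sample_curve(fit, resolution = 1)
  expect_length(s1$theta, 360)
  pk <- s1$theta[which.max(s1$values)]
  expect_lte(min(abs(pk - 237), 360 - abs(pk - 237)), 1)
  expect_error(sample_curve(fit, resolution = 7), "divide")
})

test_that("fine-sampled and direct features agree on well-separated peaks", {
  th <- seq(0, 330, 30)
  p <- c(18, 35, 120, 24, 35, 240, 5)
  y <- eval_tuning("wG", p, th, modality = "bimodal")
  cur <- tuning_curve(y, sigma = rep(1, 12), condition = "afix")
  fit <- tunefit(cur, "wG")
  fd <- extract_features(cur)
  ff <- extract_features(fit, resolution = 1)
  for (nm in c("MaximumAngleLeft", "MaximumAngleRight", "InnerMinimumAngle")) {
    d <- abs(ff[[nm]] - fd[[nm]])
    expect_lte(min(d, 360 - d), 30, label = nm)
  }
})

test_that("normalization divides rate features by the uni maximum", {
  f <- extract_features(demo_curve(), modality = "bimodal", uni_max = 40)
  expect_equal(f[["normalizedGlobalMaximum"]], 28 / 40)
  expect_equal(f[["normalizedPeakToPeakRight"]], 24 / 40)
  expect_equal(f[["normalizedInnerMinimum"]], 4 / 40)
  f2 <- extract_features(demo_curve(), modality = "bimodal")
  expect_true(is.na(f2[["normalizedGlobalMaximum"]]))
})

test_that("z-scores compare model and direct population means", {
  m <- matrix(c(12, 12, 10, 10), 2, dimnames = list(NULL, c("A", "B")))
  d <- matrix(c(8, 12, 10, 10), 2, dimnames = list(NULL, c("A", "B")))
  z <- suppressWarnings(feature_zscores(m, d))
  expect_equal(z[["A"]], (12 - 10) / sd(c(8, 12)))
  expect_true(is.na(z[["B"]]))  # zero direct spread
  expect_equal(suppressWarnings(feature_zscores(d, d))[["A"]], 0)
})
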