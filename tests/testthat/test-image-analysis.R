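make_images <- function(...) {
  generate_droplet_images(image_config(...))
}

test_that("image generator honours occupancy, determinism and placement", {
  # occupancy 0: nothing occupied, interiors smooth up to sensor noise
  gen0 <- make_images(n_images = 1, n_droplets_per_image = 12,
                      image_size = c(320, 320), occupancy_prob = 0, seed = 1)
  expect_false(any(gen0$manifest$occupied))
  d1 <- gen0$manifest[1, ]
  patch <- gen0$images[[1]][round(d1$cy) + 1 + (-4:4), round(d1$cx) + 1 + (-4:4)]
  expect_lt(stats::sd(patch), 3 * 2 / 255)  # only background noise inside
  # occupied count is binomial: 20 x 50 droplets at 0.091 -> 91 +/- 3 SD
  gen <- make_images(n_images = 20, n_droplets_per_image = 50,
                     image_size = c(700, 700), seed = 2)
  n_occ <- sum(gen$manifest$occupied)
  expect_lt(abs(n_occ - 1000 * 0.091), 3 * sqrt(1000 * 0.091 * 0.909))
  # impossible packing is an explicit error
  expect_error(make_images(n_images = 1, n_droplets_per_image = 500,
                           image_size = c(200, 200)),
               "cannot place")
  # bit-identical rendering for a fixed seed
  a <- make_images(n_images = 1, seed = 9)
  b <- make_images(n_images = 1, seed = 9)
  expect_identical(a, b)
})

test_that("detection recovers the manifest within tight tolerances", {
  gen <- make_images(n_images = 1, n_droplets_per_image = 50,
                     image_size = c(700, 700), seed = 21)
  det <- detect_droplets(gen$images[[1]])
  mf <- gen$manifest
  expect_equal(nrow(det), 50)
  # every manifest droplet matched within 3 px and 15% radius error
  for (i in seq_len(nrow(mf))) {
    d <- sqrt((det$cx - mf$cx[i])^2 + (det$cy - mf$cy[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 3)
    expect_lt(abs(det$r[j] - mf$r[i]) / mf$r[i], 0.15)
  }
  # blank image: no detections, no error
  expect_identical(nrow(detect_droplets(matrix(0.5, 64, 64))), 0L)
})

test_that("droplets cut by the image border are excluded", {
  gen <- make_images(n_images = 1, n_droplets_per_image = 9,
                     image_size = c(320, 320), seed = 31)
  mf <- gen$manifest
  victim <- mf[which.max(mf$cx), ]
  # crop the frame through the victim's center: it becomes a half-disc
  img <- gen$images[[1]][, 1:(round(victim$cx) + 1)]
  det <- detect_droplets(img)
  if (nrow(det) > 0) {
    d <- sqrt((det$cx - victim$cx)^2 + (det$cy - victim$cy)^2)
    expect_true(all(d > victim$r))
  }
  expect_lt(nrow(det), 9)
})

test_that("feature points separate grown from empty droplets", {
  gen <- make_images(n_images = 2, seed = 41)
  rec <- classify_droplet_images(gen$images, gen$manifest, seed = 1)
  expect_true(any(rec$truth), info = "benchmark needs occupied droplets")
  w <- stats::wilcox.test(rec$dissimilarity[rec$truth],
                          rec$dissimilarity[!rec$truth],
                          alternative = "greater")
  expect_lt(w$p.value, 1e-6)
  # single-patch droplets: feature point equals the patch's features
  one <- rec[rec$n_patches == 1, ][1, ]
  params <- glcm_params()
  half <- floor((one$r - 1) / sqrt(2))
  r0 <- round(one$cy) + 1 - half; c0 <- round(one$cx) + 1 - half
  patch <- gen$images[[one$image]][r0:(r0 + 15), c0:(c0 + 15)]
  expect_equal(unname(glcm_features(patch, params)["dissimilarity"]),
               one$dissimilarity)
})

test_that("zero texture contrast defeats the classifier", {
  gen <- make_images(n_images = 2, texture_contrast = 0, seed = 51,
                     occupancy_prob = 0.3)
  rec <- classify_droplet_images(gen$images, gen$manifest, seed = 1)
  # occupied and empty droplets are statistically indistinguishable
  w <- stats::wilcox.test(rec$dissimilarity[rec$truth],
                          rec$dissimilarity[!rec$truth])
  expect_gt(w$p.value, 0.01)
})

test_that("k-means labeling follows construction and handles degeneracy", {
  # two well-separated clouds: labels match cloud membership exactly
  n <- 60
  feats <- withr::with_seed(6, data.frame(
    dissimilarity = c(stats::rnorm(n, 0.5, 0.01), stats::rnorm(n, 3, 0.01)),
    homogeneity = c(stats::rnorm(n, 0.9, 0.001), stats::rnorm(n, 0.5, 0.001))
  ))
  lab <- classify_droplets(feats, seed = 1)
  expect_identical(as.character(lab),
                   rep(c("negative", "positive"), each = n))
  # naming is by texture, not by k-means' internal indices: stable across seeds
  for (s in 2:4) expect_identical(classify_droplets(feats, seed = s), lab)
  # identical points: all negative plus a warning
  same <- data.frame(dissimilarity = rep(1, 5), homogeneity = rep(0.5, 5))
  expect_warning(lab0 <- classify_droplets(same, seed = 1), "identical")
  expect_true(all(lab0 == "negative"))
})

test_that("confusion summary reproduces the validation bookkeeping", {
  # fluorescence-validation scale: 15,858 droplets, 1,447 detected positive,
  # 9 false negatives, 10 false positives
  n <- 15858; npos <- 1447; fn <- 9; fp <- 10
  label <- rep("negative", n); label[seq_len(npos)] <- "positive"
  truth <- label == "positive"
  truth[seq_len(fp)] <- FALSE            # detected positive but empty
  truth[npos + seq_len(fn)] <- TRUE      # missed growth
  cs <- evaluate_classification(data.frame(label = label, truth = truth))
  expect_equal(cs$n_detected_positive, npos)
  expect_equal(cs$n_false_negative, fn)
  expect_equal(cs$n_false_positive, fp)
  expect_equal(cs$fn_rate, 0.0062, tolerance = 1e-2)
  expect_equal(cs$fp_rate, 0.0069, tolerance = 1e-2)
  expect_equal(cs$positive_fraction, 0.0912, tolerance = 1e-2)
  # perfect classifier
  perfect <- evaluate_classification(
    data.frame(label = c("positive", "negative"), truth = c(TRUE, FALSE)))
  expect_identical(perfect$n_false_negative + perfect$n_false_positive, 0L)
  # label-flipping classifier on balanced truth: FN rate hits 100%
  flip <- evaluate_classification(
    data.frame(label = rep(c("negative", "positive"), 10),
               truth = rep(c(TRUE, FALSE), 10)))
  expect_equal(flip$fn_rate, 1)
  tp_rate <- with(flip, (n_detected_positive - n_false_positive) /
                          n_detected_positive)
  expect_equal(flip$fn_rate + tp_rate, 1)
  # missing truth is an explicit error naming droplets
  expect_error(evaluate_classification(
    data.frame(droplet_id = 1:2, label = c("positive", "negative"),
               truth = c(TRUE, NA))), "droplet")
})

test_that("image round trip through TIFF and PNG preserves the pixels", {
  gen <- make_images(n_images = 2, n_droplets_per_image = 6,
                     image_size = c(220, 220), seed = 61)
  for (fmt in c("tiff", "png")) {
    dir <- withr::local_tempdir()
    write_droplet_images(gen, dir, format = fmt)
    back <- read_droplet_images(dir)
    expect_length(back$images, 2)
    # 16-bit tiff / 8-bit png quantization error bounds
    tol <- if (fmt == "tiff") 1 / 65535 else 1 / 255
    expect_lt(max(abs(back$images[[1]] - gen$images[[1]])), tol)
    expect_equal(back$manifest$occupied, gen$manifest$occupied)
  }
})

test_that("records tally into the count pair the profile module consumes", {
  gen <- make_images(n_images = 1, seed = 71)
  rec <- classify_droplet_images(gen$images, gen$manifest, seed = 1)
  tally <- tally_droplet_records(rec)
  expect_equal(unname(tally["n_total"]), nrow(rec))
  expect_equal(unname(tally["n_positive"]),
                   sum(rec$label == "positive"))
})
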