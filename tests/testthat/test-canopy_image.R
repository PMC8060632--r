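test_that("G-R index is the exact signed green-minus-red difference", {
  img <- tiny_rgb(r = matrix(c(10L, 200L), 1), g = matrix(c(200L, 10L), 1),
                  b = matrix(c(0L, 255L), 1))
  gr <- gr_index(img)
  expect_identical(as.vector(gr), c(190L, -190L))

  uniform <- array(128L, c(4, 5, 3))
  expect_true(all(gr_index(uniform) == 0L))
  expect_identical(dim(gr_index(uniform)), c(4L, 5L))
})

test_that("non-RGB input raises a format error naming the mode", {
  expect_error(gr_index(matrix(1L, 3, 3)), "grayscale")
  expect_error(gr_index(array(1L, c(3, 3, 2))), "gray\\+alpha")
  # alpha channel is dropped, not an error
  img4 <- array(100L, c(2, 2, 4))
  img4[, , 2] <- 150L
  expect_true(all(gr_index(img4) == 50L))
})

test_that("segmentation uses strict inequality and yields cc = canopy/total", {
  all50 <- matrix(50L, 10, 10)
  expect_equal(segment_canopy(all50, 0)$cc, 1.0)
  zeros <- matrix(0L, 10, 10)
  expect_equal(segment_canopy(zeros, 0)$cc, 0.0)  # boundary -> background

  # exactly 3000 of 10000 pixels above threshold
  gr <- matrix(-5L, 100, 100)
  set.seed(11)
  above <- sample(10000, 3000)
  gr[above] <- 40L
  seg <- segment_canopy(gr, 0)
  expect_equal(seg$n_canopy, 3000L)
  expect_equal(seg$cc, 0.3)
  expect_identical(which(seg$mask), sort(above))
})

test_that("segmentation mask equals a single-pass g - r > t comparison", {
  set.seed(2)
  img <- array(sample(0:255, 3 * 30 * 20, replace = TRUE), c(30, 20, 3))
  for (t in c(-10L, 0L, 25L)) {
    seg <- segment_canopy(gr_index(img), t)
    direct <- (img[, , 2] - img[, , 1]) > t
    expect_identical(seg$mask, direct)
  }
})

test_that("cc is in [0,1] and non-increasing in the threshold", {
  set.seed(3)
  gr <- matrix(sample(-255:255, 400, replace = TRUE), 20, 20)
  ccs <- vapply(seq(-255, 255, by = 15),
                function(t) segment_canopy(gr, t)$cc, 0)
  expect_true(all(ccs >= 0 & ccs <= 1))
  expect_true(all(diff(ccs) <= 0))
})

test_that("Otsu threshold separates a bimodal map and breaks ties low", {
  gr <- matrix(rep(c(-80L, 120L), each = 200), 20, 20)
  t <- auto_threshold(gr)
  expect_gte(t, -80L)
  expect_lte(t, 119L)
  expect_equal(segment_canopy(gr, t)$cc, 0.5)
  # exhaustive scan oracle: recompute between-class variance for all cuts
  v <- as.integer(gr)
  n <- length(v)
  bcv <- vapply(-255:254, function(t) {
    w0 <- mean(v <= t)
    if (w0 == 0 || w0 == 1) return(-Inf)
    (mean(v[v <= t]) - mean(v[v > t]))^2 * w0 * (1 - w0)
  }, 0)
  best <- (-255:254)[bcv >= max(bcv) - 1e-9]
  expect_true(t %in% best)
  expect_equal(t, min(best))  # tie toward the lower threshold

  alt <- matrix(rep(c(-1L, 1L), 50), 10, 10)
  t2 <- auto_threshold(alt)
  expect_true(t2 %in% c(-1L, 0L))
  expect_equal(segment_canopy(alt, t2)$cc, 0.5)

  expect_error(auto_threshold(matrix(7L, 5, 5)), "no bimodality")
})

test_that("canopy cover from files matches the generator's ground truth", {
  # fully green scene
  full <- write_scene_png(1, seed = 5, color_noise_sd = 0)
  expect_equal(canopy_cover(full$path)$cc, 1.0)

  # noiseless scene segments to the exact mask fraction at threshold 0
  fx <- write_scene_png(0.42, seed = 6, color_noise_sd = 0)
  seg <- segment_canopy(gr_index(fx$scene$image), 0)
  expect_identical(seg$mask, fx$scene$mask)
  expect_equal(canopy_cover(fx$path)$cc, fx$scene$true_cover)

  # noisy scene stays within 0.01 of truth; auto mode agrees
  fy <- write_scene_png(0.42, seed = 7)
  expect_lt(abs(canopy_cover(fy$path)$cc - fy$scene$true_cover), 0.01)
  expect_lt(abs(canopy_cover(fy$path, "auto")$cc - fy$scene$true_cover), 0.01)

  expect_error(canopy_cover(file.path(tempdir(), "missing.png")),
               "missing.png")
})

test_that("batch table processes a directory and joins metadata", {
  dir <- file.path(tempdir(), "batch_imgs")
  unlink(dir, recursive = TRUE)
  truth <- simulate_image_batch(dir, n = 3, cover_range = c(0.2, 0.8),
                                seed = 20)
  meta <- data.frame(image_path = truth$image_path,
                     site = "Xinxiang", season = "2016-2017",
                     cultivar = "AK58", n_rate_kg_ha = 150,
                     replicate = 1:3, stage = "Feekes 5")
  tab <- canopy_cover_table(dir, meta = meta)
  expect_equal(nrow(tab), 3L)
  tab <- tab[match(basename(truth$image_path), basename(tab$image_path)), ]
  expect_true(all(abs(tab$cc - truth$true_cover) < 0.01))
  expect_true(all(c("cultivar", "stage", "n_canopy", "n_total") %in%
                    names(tab)))
})

test_that("cc is robust to integer-block downsampling of the scene", {
  # few large blobs keep the canopy boundary a small fraction of the image,
  # as in a real high-resolution nadir photo
  scn <- simulate_canopy_image(
    scene_config(width = 320, height = 240, target_cover = 0.5,
                 n_leaf_blobs = 8, seed = 9))
  cc_full <- segment_canopy(gr_index(scn$image), 0)$cc
  # 2x2 block-average each channel, then re-segment
  block <- 2L
  h2 <- 240L %/% block; w2 <- 320L %/% block
  small <- array(0, c(h2, w2, 3))
  for (ch in 1:3) {
    m <- scn$image[, , ch]
    dim(m) <- c(block, h2, block, w2)
    small[, , ch] <- apply(m, c(2, 4), mean)
  }
  expect_identical(dim(small), c(h2, w2, 3L))
  small <- round(small)
  storage.mode(small) <- "integer"
  cc_small <- segment_canopy(gr_index(small), 0)$cc
  expect_lt(abs(cc_full - cc_small), 0.02)
})
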