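test_that("chrominance maps behave as opponent axes", {
  gray <- flat_image(8, 8, c(128, 128, 128))
  amap <- chrominance_map(gray, "a")
  expect_lt(max(abs(amap)), 0.01)

  red <- flat_image(8, 8, c(200, 60, 60))
  green <- flat_image(8, 8, c(60, 200, 60))
  expect_true(all(chrominance_map(red, "a") > chrominance_map(green, "a")))
  expect_error(chrominance_map(red, "nope"), "unknown chrominance channel")

  # masked pixels are NA
  m <- matrix(TRUE, 8, 8); m[1, ] <- FALSE
  img <- tongue_image(red$pixels, m)
  cm <- chrominance_map(img, "a")
  expect_true(all(is.na(cm[1, ])))
  expect_true(all(is.finite(cm[m])))
})

test_that("default fixture has a bimodal chrominance histogram", {
  fx <- default_fixture()
  amap <- chrominance_map(fx$image, "a")
  mu_b <- mean(amap[fx$body_mask]); sd_b <- sd(amap[fx$body_mask])
  mu_c <- mean(amap[fx$coating_mask]); sd_c <- sd(amap[fx$coating_mask])
  expect_gt(abs(mu_b - mu_c), 3 * max(sd_b, sd_c))
})

test_that("division-merge returns one region for a uniform tongue", {
  img <- flat_image(16, 16, c(150, 100, 100))
  dm <- division_merge(img)
  expect_equal(nrow(dm$regions), 1)
  expect_equal(sum(dm$regions$n), 256)
})

test_that("division-merge recovers two flat regions exactly", {
  fx <- flat_fixture()
  # flat regions have zero within-region spread, so a tight homogeneity
  # tolerance forces the partition down to the exact boundary
  dm <- division_merge(fx$image, segmentation_config(homogeneity_tol = 2))
  expect_equal(nrow(dm$regions), 2)
  # regions tile the tongue mask
  expect_identical(!is.na(dm$labels), fx$image$tongue_mask)
  # each region matches one ground-truth mask
  r1 <- !is.na(dm$labels) & dm$labels == 1
  r2 <- !is.na(dm$labels) & dm$labels == 2
  ious <- c(max(mask_iou(r1, fx$body_mask), mask_iou(r1, fx$coating_mask)),
            max(mask_iou(r2, fx$body_mask), mask_iou(r2, fx$coating_mask)))
  expect_equal(ious, c(1, 1))
})

test_that("division-merge regions cluster to ground truth under texture", {
  fx <- make_tongue_image(synthetic_spec(texture_amplitude = 8, noise_sigma = 3))
  dm <- division_merge(fx$image)
  thr <- otsu_threshold(dm$regions$mean, dm$regions$n)
  hi <- dm$regions$mean > thr
  hi_mask <- !is.na(dm$labels) & matrix(hi[dm$labels], nrow(dm$labels))
  lo_mask <- !is.na(dm$labels) & !hi_mask
  iou_body <- max(mask_iou(hi_mask, fx$body_mask), mask_iou(lo_mask, fx$body_mask))
  expect_gte(iou_body, 0.90)
})

test_that("body/coating separation is near-exact on default fixtures", {
  for (seed in 1:3) {
    fx <- default_fixture(seed = seed)
    seg <- segment_body_coating(fx$image)
    expect_gte(mask_iou(seg$body_mask, fx$body_mask), 0.95)
    expect_gte(mask_iou(seg$coating_mask, fx$coating_mask), 0.95)
    expect_false(any(seg$body_mask & seg$coating_mask))
    expect_identical(seg$body_mask | seg$coating_mask, fx$image$tongue_mask)
  }
})

test_that("segmentation is exact with zero texture and zero noise", {
  fx <- flat_fixture()
  seg <- segment_body_coating(fx$image)
  expect_equal(mask_iou(seg$body_mask, fx$body_mask), 1)
  expect_equal(mask_iou(seg$coating_mask, fx$coating_mask), 1)
})

test_that("a coating-free tongue is labeled entirely body, with a warning", {
  fx <- make_tongue_image(synthetic_spec(coating_fraction = 0))
  expect_warning(seg <- segment_body_coating(fx$image), "single-mode")
  expect_equal(sum(seg$coating_mask), 0)
  expect_identical(seg$body_mask, fx$image$tongue_mask)
})

test_that("swapping body and coating colors swaps the masks", {
  sw <- make_tongue_image(synthetic_spec(body_color = c(210, 200, 170),
                                         coating_color = c(180, 120, 120)))
  seg <- segment_body_coating(sw$image)
  # the red blob is now the true coating; the segmenter must call it body
  expect_gte(mask_iou(seg$body_mask, sw$coating_mask), 0.95)
  expect_gte(mask_iou(seg$coating_mask, sw$body_mask), 0.95)
})

test_that("segmentation IoU does not improve on average as noise grows", {
  mean_iou <- vapply(c(0, 8, 25), function(ns) {
    mean(vapply(1:3, function(s) {
      fx <- make_tongue_image(synthetic_spec(noise_sigma = ns, seed = s))
      seg <- suppressWarnings(segment_body_coating(fx$image))
      mask_iou(seg$body_mask, fx$body_mask)
    }, 1))
  }, 1)
  expect_true(all(diff(mean_iou) <= 1e-9))
})

test_that("the partition invariant holds on fuzzed random inputs", {
  for (seed in 1:6) {
    img <- random_image(20, 20, seed = 100 + seed, mask_frac = 0.7)
    seg <- suppressWarnings(segment_body_coating(img))
    expect_false(any(seg$body_mask & seg$coating_mask))
    expect_identical(seg$body_mask | seg$coating_mask, img$tongue_mask)
  }
})

test_that("configuration is validated and fixed thresholds are honored", {
  expect_error(segmentation_config(min_block_size = 1), "min_block_size")
  expect_error(segmentation_config(homogeneity_tol = 0), "homogeneity_tol")
  expect_error(segmentation_config(threshold_mode = "fixed"), "fixed_threshold")
  fx <- flat_fixture()
  cfg <- segmentation_config(threshold_mode = "fixed", fixed_threshold = 11)
  seg <- segment_body_coating(fx$image, cfg)
  expect_equal(seg$method_trace$threshold, 11)
  expect_equal(mask_iou(seg$body_mask, fx$body_mask), 1)
})
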