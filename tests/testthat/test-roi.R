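# a tiny hand-built dynamic image: 5x5x1 voxels, 3 frames
tiny_image <- function(frame_vals) {
  sched <- frame_schedule(c(0, 1, 2), c(1, 2, 3))
  arr <- array(0, c(5, 5, 1, 3))
  for (k in 1:3) arr[, , 1, k] <- frame_vals[[k]]
  dynamic_image(arr, sched, voxel_size_mm = 1)
}

test_that("fractional-maximum screen keeps voxels at or above the cut", {
  vals <- matrix(0, 5, 5)
  vals[1:2, 1:5] <- matrix(1:10, 2, 5)  # seed values 1..10
  img <- tiny_image(list(vals, vals, vals))
  seed <- voi_mask(array(vals > 0, c(5, 5, 1)))
  kept <- threshold_mask(img, seed, fraction = 0.3, frame = 3)
  expect_equal(sum(kept$mask), 8L)              # values >= 0.3*10 = 3
  expect_true(all(img$data[, , , 3][kept$mask] >= 3))
  # uniform region: everything survives
  uni <- tiny_image(list(vals * 0 + 2, vals * 0 + 2, vals * 0 + 2))
  expect_equal(sum(threshold_mask(uni, seed, 0.3)$mask), sum(seed$mask))
  # fraction 0 returns the seed unchanged
  expect_equal(threshold_mask(img, seed, 0)$mask, seed$mask)
})

test_that("core/rim sphere screens down to the core", {
  spec <- small_phantom_spec(20L)
  ph <- build_phantom(spec, fx_input, fx_sched, noise_spec(0))
  img <- ph$image
  # paint a two-intensity sphere into the last frame: core 10, rim 2
  ctr <- c(10, 10, 10)
  core <- sphere_mask(dim(ph$labels), ctr, 2)$mask
  rim <- sphere_mask(dim(ph$labels), ctr, 4)$mask
  last <- array(0, dim(ph$labels))
  last[rim] <- 2; last[core] <- 10
  img$data[, , , 30] <- last
  kept <- threshold_mask(img, voi_mask(rim), fraction = 0.3)
  expect_equal(sum(kept$mask), sum(core))
  expect_error(threshold_mask(img, voi_mask(rim & !rim)),
               "no voxels|empty|max")
})

test_that("TAC extraction is the masked mean and is linear", {
  v1 <- matrix(stats::runif(25), 5); v2 <- v1 + 1; v3 <- v1 * 2
  img <- tiny_image(list(v1, v2, v3))
  m1 <- array(FALSE, c(5, 5, 1)); m1[2, 3, 1] <- TRUE
  expect_equal(extract_tac(img, voi_mask(m1))$value,
               c(v1[2, 3], v2[2, 3], v3[2, 3]))
  m2 <- m1; m2[4, 4, 1] <- TRUE
  expect_equal(extract_tac(img, voi_mask(m2))$value,
               c(mean(c(v1[2, 3], v1[4, 4])), mean(c(v2[2, 3], v2[4, 4])),
                 mean(c(v3[2, 3], v3[4, 4]))))
  # linearity: mean of a*img1 + img2 = a*mean1 + mean2
  a <- 2.5
  img_lin <- tiny_image(list(a * v1 + v2, a * v2 + v3, a * v3 + v1))
  expect_equal(extract_tac(img_lin, voi_mask(m2))$value,
               a * extract_tac(img, voi_mask(m2))$value +
                 c(mean(c(v2[2, 3], v2[4, 4])), mean(c(v3[2, 3], v3[4, 4])),
                   mean(c(v1[2, 3], v1[4, 4]))))
})

test_that("%ID/g conversion follows activity / dose * 100 / density", {
  sched <- frame_schedule(0, 1)
  x <- tac(sched, 37, "kBq/ml")
  out <- to_percent_id_per_g(x, dose_info(dose_mbq = 3.7))
  expect_equal(out$value, 1.0)   # 37 kBq/ml over 3.7 MBq
  expect_equal(out$units, "%ID/g")
  expect_equal(to_percent_id_per_g(tac(sched, 0), dose_info(3.7))$value, 0)
  # doubling the dose halves %ID/g
  expect_equal(to_percent_id_per_g(x, dose_info(7.4))$value, 0.5)
  expect_error(dose_info(0), "> 0")
  expect_error(to_percent_id_per_g(out, dose_info(3.7)), "kBq/ml")
})

test_that("image-derived input reproduces the plasma curve on a clean phantom", {
  spec <- small_phantom_spec(20L)
  ph <- build_phantom(spec, fx_input, fx_sched, noise_spec(0))
  masks <- dynpet:::region_masks(spec)
  idif <- image_derived_input(ph$image, voi_mask(masks$lv_blood))
  expected <- simulate_input_tac(fx_input, fx_sched)
  expect_equal(idif$tac$value, expected$value, tolerance = 1e-6)
})

test_that("the frozen LV mask depends on the delineation frame", {
  # a blood pool whose rim dims over time: late-frame delineation shrinks
  sched <- frame_schedule(c(0, 1, 2), c(1, 2, 3))
  arr <- array(0, c(7, 7, 1, 3))
  pool <- sphere_mask(c(7, 7, 1), c(4, 4, 1), 2.2)$mask
  core <- sphere_mask(c(7, 7, 1), c(4, 4, 1), 1)$mask
  for (k in 1:3) {
    f <- array(0, c(7, 7, 1))
    f[pool] <- 10 / 4^(k - 1)  # rim fades below the 30% cut by frame 3
    f[core] <- 10              # core stays hot
    arr[, , , k] <- f
  }
  img <- dynamic_image(arr, sched, 1)
  early <- image_derived_input(img, voi_mask(pool), frame = 1)
  late <- image_derived_input(img, voi_mask(pool), frame = 3)
  expect_gt(sum(early$mask$mask), sum(late$mask$mask))
})

test_that("last-frame uptake equals the final %ID/g TAC entry", {
  spec <- small_phantom_spec(20L)
  ph <- build_phantom(spec, fx_input, fx_sched, noise_spec(0))
  masks <- dynpet:::region_masks(spec)
  dose <- dose_info(3.7)
  mask <- voi_mask(masks$tumor)
  up <- last_frame_uptake(ph$image, mask, dose)
  full <- to_percent_id_per_g(extract_tac(ph$image, mask), dose)
  expect_equal(up, full$value[30])
  # inversion of the conversion: constant 3.45% of the dose per 100 ml
  const_img <- ph$image
  const_img$data[] <- 0.0345 * 3700
  expect_equal(last_frame_uptake(const_img, mask, dose), 3.45)
  zero_img <- ph$image
  zero_img$data[] <- 0
  expect_equal(last_frame_uptake(zero_img, mask, dose), 0)
})
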