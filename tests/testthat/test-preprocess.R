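test_that("crop_resize honors its contract", {
  img <- rand_rgb(12, 10, seed = 1)
  # full-extent no-op
  expect_equal(crop_resize(img, NULL, 12, 10), img * 1)
  # requested output dimensions always win
  out <- crop_resize(img, c(2, 2, 8, 8), 9, 5)
  expect_equal(dim(out), c(9L, 5L, 3L))
  # constant stays constant under any box/resize/method
  const <- array(77, c(10, 10, 3))
  for (m in c("bilinear", "nearest"))
    expect_true(all(crop_resize(const, c(2, 3, 6, 5), 8, 12,
                                method = m) == 77))
  # out-of-bounds box rejected
  expect_error(crop_resize(img, c(5, 5, 20, 3)), "outside")
  expect_error(crop_resize(img, c(0, 1, 5, 5)), "outside")
})

test_that("complement inverts per channel and is an involution", {
  px <- array(c(0, 200, 100, 50, 0, 0), c(1, 1, 3))
  img <- rand_rgb(6, 6, seed = 2)
  expect_equal(img_complement(array(c(200, 100, 50), c(1, 1, 3)))[1, 1, ],
               c(55, 155, 205))
  expect_true(all(img_complement(array(0, c(3, 3, 3))) == 255))
  expect_equal(img_complement(img_complement(img)), img * 1)
  expect_equal(dim(img_complement(img)), dim(img))
})

test_that("dark_channel matches the nested-loop oracle and its bounds", {
  expect_true(all(dark_channel(array(255, c(5, 5, 3)), 3) == 255))
  one_zero <- rand_rgb(6, 6, seed = 5); one_zero[, , 2] <- 0
  expect_true(all(dark_channel(one_zero, 3) == 0))
  for (seed in 1:5) {
    img <- rand_rgb(5, 5, seed)
    expect_equal(dark_channel(img, 3), oracle_dark_channel(img, 3L))
    expect_equal(dark_channel(img, 5), oracle_dark_channel(img, 5L))
    # pointwise <= per-pixel channel minimum
    expect_true(all(dark_channel(img, 3) <=
                      pmin(img[, , 1], img[, , 2], img[, , 3])))
  }
  expect_error(dark_channel(rand_rgb(5, 5, 1), 4), "odd")
})

test_that("dark_channel is monotone under pixel brightening", {
  for (seed in 1:5) {
    img <- rand_rgb(8, 8, seed)
    brighter <- img
    idx <- withr::with_seed(seed, sample(length(img), 20))
    brighter[idx] <- pmin(brighter[idx] + 40, 255)
    expect_true(all(dark_channel(brighter, 3) >= dark_channel(img, 3)))
  }
})

test_that("transmission_map matches its definition and limits", {
  a <- c(200, 210, 220)
  flat <- array(rep(a, each = 25), c(5, 5, 3))
  expect_true(all(transmission_map(flat, a, 3) == 0))
  img <- rand_rgb(6, 6, seed = 7); img[3, 3, 1] <- 0
  tm <- transmission_map(img, a, 3)
  expect_true(all(tm[2:4, 2:4] == 1))          # dark-pixel limit
  expect_true(all(tm >= 0 & tm <= 1))
  # matches brute-force evaluation
  norm <- img
  for (c in 1:3) norm[, , c] <- img[, , c] / a[c]
  expect_equal(tm, pmin(pmax(1 - oracle_dark_channel(norm, 3L), 0), 1))
  expect_error(transmission_map(img, c(0, 1, 1), 3), "> 0")
})

test_that("dehaze inverts the known forward model on dark-channel scenes", {
  # forward model then invert: spatially constant t, known atmospheric light
  for (seed in 1:3) {
    clean <- clip8(dcp_zero_rgb(40, 50, seed, patch = 15L))
    hazed <- add_haze(clean, 0.6, c(220, 220, 220))
    out <- dehaze(hazed, dehaze_params(atmos = c(220, 220, 220)))
    expect_lt(mean(abs(out - clean)), 5)
  }
})

test_that("dehaze round trip holds across transmissions t >= 0.3", {
  clean <- clip8(dcp_zero_rgb(40, 40, seed = 11, patch = 15L))
  for (t in c(0.3, 0.45, 0.6, 0.8, 1)) {
    hazed <- add_haze(clean, t, c(220, 220, 220))
    out <- dehaze(hazed, dehaze_params(atmos = c(220, 220, 220)))
    expect_lt(mean(abs(out - clean)), 5)
  }
})

test_that("dehaze of a haze-free dark-channel scene is the identity", {
  clean <- clip8(dcp_zero_rgb(40, 40, seed = 13, patch = 15L))
  out <- dehaze(add_haze(clean, 1, c(220, 220, 220)),
                dehaze_params(atmos = c(220, 220, 220)))
  expect_lte(max(abs(out - clean)), 1)
})

test_that("dehaze handles degenerate input and estimates atmos when blind", {
  const <- array(128, c(20, 20, 3))
  expect_warning(out <- dehaze(const), "degenerate")
  expect_equal(out, const)
  # blind estimation restores toward the clean image even when imperfect
  g <- generate_wbc_image(synth_params(seed = 3, height = 120, width = 160,
                                       cell_radius_range = c(25, 30)))
  hazed <- add_haze(g$clean, 0.6)
  blind <- dehaze(hazed)
  expect_equal(dim(blind), dim(g$clean))
  a <- estimate_atmos(hazed)
  expect_length(a, 3)
  expect_true(all(a >= 1 & a <= 255))
})

test_that("to_grayscale uses BT.601 weights and fixes achromatic images", {
  white <- array(255, c(3, 3, 3))
  expect_true(all(to_grayscale(white) == 255))
  for (v in c(0, 1, 77, 128, 254, 255)) {
    achro <- array(v, c(3, 3, 3))
    expect_true(all(to_grayscale(achro) == v))
  }
  red <- array(0, c(3, 3, 3)); red[, , 1] <- 255
  expect_true(all(to_grayscale(red) == 76))   # round(0.299 * 255)
})

test_that("preprocess_smear composes the chain and returns a gray image", {
  g <- generate_wbc_image(synth_params(seed = 8, height = 80, width = 100,
                                       cell_radius_range = c(15, 20)))
  gray <- preprocess_smear(g$clean, out_h = 60, out_w = 80)
  expect_true(is.matrix(gray))
  expect_equal(dim(gray), c(60L, 80L))
  expect_true(max(gray) <= 255 && min(gray) >= 0)
  # without dehazing the chain is just crop + grayscale
  expect_equal(preprocess_smear(g$clean, run_dehaze = FALSE),
               to_grayscale(g$clean))
})
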