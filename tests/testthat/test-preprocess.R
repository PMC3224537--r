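test_that("histogram equalization matches the direct CDF-mapping oracle", {
  # degenerate CDF: constant image returned unchanged
  const <- roi_image(matrix(7, 4, 4))
  expect_identical(equalize_histogram(const)$pixels, const$pixels)

  # two-level 2x2 image against the brute-force oracle
  two <- matrix(c(0, 255, 0, 255), 2, 2)
  expect_equal(equalize_histogram(roi_image(two))$pixels,
               matrix(oracle_equalize(two), 2, 2))

  # a 16x16 ramp already occupying all 256 levels is (up to rounding) fixed
  ramp <- matrix(0:255, 16, 16, byrow = TRUE)
  out <- equalize_histogram(roi_image(ramp))$pixels
  expect_true(max(abs(out - ramp)) <= 1)

  # random images against the oracle
  set.seed(1)
  for (i in 1:5) {
    px <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_equal(equalize_histogram(roi_image(px))$pixels,
                 matrix(oracle_equalize(px), 8, 8))
  }
})

test_that("equalization is idempotent up to one intensity level", {
  set.seed(2)
  for (i in 1:5) {
    px <- matrix(sample(0:200, 256, replace = TRUE), 16, 16)
    once <- equalize_histogram(roi_image(px))
    twice <- equalize_histogram(once)
    expect_lte(max(abs(twice$pixels - once$pixels)), 1)
  }
})

test_that("bilinear resize matches the half-pixel-centered oracle", {
  # identity when sizes agree
  img <- roi_image(matrix(sample(0:255, 1024, replace = TRUE), 32, 32))
  expect_identical(resize_roi(img, 32)$pixels, img$pixels)

  # constants are preserved at any size
  expect_true(all(resize_roi(roi_image(matrix(10, 64, 64)), 32)$pixels == 10))

  # 4x4 checkerboard upsampled to 32x32, within 1 level of the pixel-loop oracle
  cb <- 255 * outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  got <- resize_roi(roi_image(cb), 32)$pixels
  want <- oracle_resize(cb, 32)
  expect_lte(max(abs(got - want)), 1)

  # downsampling a random image, same oracle
  set.seed(3)
  px <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  expect_lte(max(abs(resize_roi(roi_image(px), 16)$pixels - oracle_resize(px, 16))), 1)

  # range containment
  rr <- resize_roi(roi_image(px), 24)$pixels
  expect_gte(min(rr), min(px)); expect_lte(max(rr), max(px))

  expect_error(resize_roi(img, 1), "at least 2")
})

test_that("vectorization concatenates rows and inverts by reshape", {
  expect_equal(vectorize_roi(roi_image(matrix(1:4, 2, 2, byrow = TRUE))),
               c(1, 2, 3, 4))
  expect_equal(vectorize_roi(roi_image(matrix(c(5, 9, 11), 1, 3))), c(5, 9, 11))
  img <- roi_image(matrix(sample(0:255, 1024, replace = TRUE), 32, 32))
  v <- vectorize_roi(img)
  expect_length(v, 1024L)
  expect_identical(matrix(v, 32, 32, byrow = TRUE), img$pixels)
})

test_that("build_dataset applies equalize -> resize -> vectorize per column", {
  set.seed(4)
  imgs <- lapply(1:5, function(i) {
    roi_image(matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40),
              sprintf("img-%d", i))
  })
  labs <- c("mass", "mass", "non-mass", "non-mass", "mass")
  d <- build_dataset(imgs, labs, side = 32)
  expect_equal(dim(d$data), c(1024L, 5L))
  expect_identical(d$labels, labs)
  for (i in seq_along(imgs)) {
    expect_equal(d$data[, i],
                 vectorize_roi(resize_roi(equalize_histogram(imgs[[i]]), 32)))
  }
  expect_error(build_dataset(list(), character(0)), "at least one")
  expect_error(build_dataset(imgs, labs[1:3]), "equal length")
})

test_that("a dataset round-trips through PNG + manifest bit-exactly", {
  d <- generate_dataset(c(mass = 50, `non-mass` = 50), synth_params(seed = 8))
  dir <- withr::local_tempdir()
  write_roi_dataset(d, dir)
  back <- read_roi_dataset(dir)
  expect_identical(back$data, d$data)
  expect_identical(back$labels, d$labels)
  expect_identical(back$ids, d$ids)
})

test_that("image containers reject malformed input", {
  expect_error(roi_image(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(roi_image(matrix(-3, 2, 2)), "\\[0, 255\\]")
  expect_error(roi_image(matrix(300, 2, 2)), "\\[0, 255\\]")
  expect_error(roi_dataset(matrix(1, 4, 2), labels = "a"), "one entry per")
})
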