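write_test_manifest <- function(dir, n_bands = 7, value = 128 / 255,
                                H = 10, W = 10) {
  nms <- bee_bands()[seq_len(n_bands)]
  bands <- lapply(seq_along(nms), function(i) {
    f <- sprintf("band_%d.png", nms[i])
    png::writePNG(matrix(value, H, W), file.path(dir, f))
    list(file = f, nm = nms[i])
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(bands = bands, gray_ref = list(0, 0, W, 2)),
                   manifest)
  manifest
}

test_that("read_stack loads PNG bands and maps integers to [0,1]", {
  dir <- withr::local_tempdir()
  manifest <- write_test_manifest(dir)
  stack <- read_stack(manifest)
  expect_equal(dim(stack$bands), c(10, 10, 7))
  expect_true(all(stack$bands == 128 / 255))
  expect_false(stack$balanced)
  expect_equal(stack$band_nm, bee_bands())
})

test_that("read_stack reads 16-bit TIFF at full depth", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "b.tiff")
  tiff::writeTIFF(matrix(c(1, 0.5, 0, 0.25), 2, 2), f,
                  bits.per.sample = 16L)
  img <- tiff::readTIFF(f)
  expect_equal(img[1, 1], 1.0)
  bands <- lapply(1:2, function(i) list(file = "b.tiff", nm = c(340, 400)[i]))
  manifest <- file.path(dir, "m.yaml")
  yaml::write_yaml(list(bands = bands, gray_ref = list(0, 0, 2, 2)),
                   manifest)
  stack <- read_stack(manifest)
  expect_equal(max(stack$bands), 1.0)
})

test_that("read_stack rejects missing bands and mismatched dimensions", {
  dir <- withr::local_tempdir()
  manifest <- write_test_manifest(dir)
  m <- yaml::read_yaml(manifest)
  m$bands[[7]]$file <- "absent.png"
  yaml::write_yaml(m, manifest)
  expect_error(read_stack(manifest), "absent.png")

  dir2 <- withr::local_tempdir()
  manifest2 <- write_test_manifest(dir2)
  png::writePNG(matrix(0.5, 4, 4), file.path(dir2, "band_700.png"))
  expect_error(read_stack(manifest2), "mismatched dimensions")
})

test_that("white balance maps the gray-reference extremes to 0 and 1", {
  H <- 10; W <- 10
  cube <- array(0.45, c(H, W, 2))
  cube[1, 1, ] <- 0.2   # darkest reference pixel
  cube[1, 2, ] <- 0.7   # lightest reference pixel
  stack <- msstack(cube, c(340, 400), c(0, 0, W, 2))
  wb <- white_balance(stack)
  expect_identical(wb$bands[1, 1, 1], 0)
  expect_identical(wb$bands[1, 2, 1], 1)
  expect_equal(wb$bands[5, 5, 1], 0.5)
  expect_true(wb$balanced)

  flat <- msstack(array(0.3, c(H, W, 2)), c(340, 400), c(0, 0, W, 2))
  expect_error(white_balance(flat), "degenerate gray reference")
})

test_that("white balance is idempotent once the reference spans [0,1]", {
  p <- scene_params(max_band_shift = 0L, seed = 3)
  sc <- generate_scene(p)
  wb1 <- white_balance(sc$stack)
  wb2 <- white_balance(wb1)
  expect_equal(wb2$bands, wb1$bands, tolerance = 1e-12)
})

test_that("white balance inverts the generator's gain/offset distortion", {
  p <- scene_params(max_band_shift = 0L, seed = 8)
  sc <- generate_scene(p)
  wb <- white_balance(sc$stack)
  for (b in 1:7) {
    expect_lt(max(abs(wb$bands[, , b] - sc$truth$reflectance_cube[, , b])),
              1 / 255)
  }
})

test_that("alignment recovers injected integer shifts exactly", {
  p <- scene_params(max_band_shift = 8L, seed = 21)
  sc <- generate_scene(p)
  st <- align_bands(white_balance(sc$stack), max_shift = 10L)
  expect_identical(st$shifts, sc$truth$shifts)
  expect_true(st$aligned)

  # translation-only: alignment moves pixels, never alters their values
  wb <- white_balance(sc$stack)
  for (b in 1:7) {
    vals <- st$bands[, , b][st$valid]
    expect_true(all(vals %in% as.vector(wb$bands[, , b])))
  }
})

test_that("already-aligned stacks get identity shifts", {
  p <- scene_params(max_band_shift = 0L, seed = 4)
  sc <- generate_scene(p)
  st <- align_bands(white_balance(sc$stack), max_shift = 4L)
  expect_true(all(st$shifts == 0L))
})

test_that("shifts beyond the search window clamp with a warning", {
  p <- scene_params(max_band_shift = 0L, seed = 5)
  sc <- generate_scene(p)
  wb <- white_balance(sc$stack)
  wb$bands[, , 1] <- shift_image(wb$bands[, , 1], 6L, 0L,
                                 fill = "replicate")
  expect_warning(st <- align_bands(wb, max_shift = 4L),
                 "search boundary")
  expect_equal(unname(st$shifts[1, "dx"]), 4L)
})

test_that("constant bands skip alignment with a warning", {
  cube <- array(runif(10 * 10 * 2), c(10, 10, 2))
  cube[, , 1] <- 0.5
  stack <- msstack(cube, c(340, 520), c(0, 0, 10, 2), balanced = TRUE)
  expect_warning(st <- align_bands(stack, max_shift = 2L),
                 "constant band")
  expect_true(all(st$shifts == 0L))
})

test_that("region sampling is exhaustive, reproducible and value-faithful", {
  stack <- uniform_stack(rep(0.3, 7), H = 40, W = 50)
  mask <- matrix(FALSE, 40, 50)
  mask[1:20, 1:50] <- TRUE  # exactly 1000 pixels
  s1 <- sample_region(stack, mask, n = 1000, seed = 5)
  s2 <- sample_region(stack, mask, n = 1000, seed = 5)
  expect_identical(s1$coords, s2$coords)
  idx <- (s1$coords[, "col"] - 1L) * 40L + s1$coords[, "row"]
  expect_setequal(idx, which(mask))
  expect_equal(mean(s1$values[, 1]), 0.3)
  expect_equal(pop_sd(s1$values[, 1]), 0)

  empty <- matrix(FALSE, 40, 50)
  expect_error(sample_region(stack, empty, n = 10, seed = 1), "empty")

  small <- matrix(FALSE, 40, 50); small[1, 1:5] <- TRUE
  expect_message(s3 <- sample_region(stack, small, n = 50, seed = 1),
                 "with replacement")
  expect_true(s3$replace)
})

test_that("false color maps bands to the documented channels", {
  mk <- function(hot_nm) {
    vals <- as.numeric(bee_bands() == hot_nm) * 0.8
    uniform_stack(vals, H = 4, W = 4)
  }
  uv <- false_color(mk(340), mode = "bee")
  expect_true(all(uv[, , 3] > 0) && all(uv[, , 1] == 0) &&
                all(uv[, , 2] == 0))
  yellow <- false_color(mk(580), mode = "bee")
  expect_true(all(yellow[, , 1] > 0) && all(yellow[, , 2] == 0) &&
                all(yellow[, , 3] == 0))
  gray <- false_color(uniform_stack(rep(0.5, 7), H = 4, W = 4), "human")
  expect_true(all(gray[, , 1] == gray[, , 2]) &&
                all(gray[, , 2] == gray[, , 3]))
  short <- uniform_stack(c(0.5, 0.5, 0.5), H = 4, W = 4,
                         band_nm = c(340, 400, 460))
  expect_error(false_color(short, "human"), "640")
})

test_that("heat maps scale E linearly onto 8 bits", {
  m <- matrix(c(0, 0.25, 0.5, 0.999), 2, 2)
  maps <- structure(list(maps = list(L = m), band_nm = bee_bands(),
                         valid = NULL, receptors = "L"),
                    class = "response_maps")
  hm <- heat_map(maps, "L")
  expect_identical(hm, matrix(c(0L, 64L, 128L, 255L), 2, 2))
  expect_error(heat_map(maps, "Q"), "unknown receptor")
  # pure rendering: the source maps are untouched
  expect_identical(maps$maps$L, m)
})

test_that("ommatidial downsampling averages blocks correctly", {
  set.seed(13)
  img <- matrix(runif(24 * 36), 24, 36)
  expect_identical(downsample_ommatidia(img, 24 * 36), img)
  expect_equal(downsample_ommatidia(img, 1),
               matrix(mean(img), 24, 36))

  out <- downsample_ommatidia(img, 24)
  # oracle: direct loop over the 4x6 aspect-preserving block grid
  rb <- floor(seq(0, 24, length.out = 5))
  cb <- floor(seq(0, 36, length.out = 7))
  for (i in 1:4) for (j in 1:6) {
    rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
    expect_equal(unique(as.vector(out[rows, cols])),
                 mean(img[rows, cols]), tolerance = 1e-12)
  }
  expect_warning(big <- downsample_ommatidia(img, 24 * 36 + 1),
                 "exceeds")
  expect_identical(big, img)
})
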