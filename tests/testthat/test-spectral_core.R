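test_that("resample interpolates linearly and preserves the role tag", {
  s <- spectrum(c(300, 500, 700), c(0.5, 0.5, 0.5), role = "illuminant")
  r <- resample(s, bee_bands())
  expect_equal(r$value, rep(0.5, 7))
  expect_identical(r$role, "illuminant")

  seg <- spectrum(c(400, 500), c(0, 1))
  expect_equal(resample(seg, c(425, 450))$value, c(0.25, 0.5))
})

test_that("resample is exact when the target is a subset of the source", {
  set.seed(42)
  src <- spectrum(seq(300, 700, by = 20), runif(21))
  sub <- c(340, 400, 460, 520, 580, 640, 700)
  r <- resample(src, sub)
  expect_identical(r$value, src$value[match(sub, src$wavelength)])
})

test_that("resample refuses to extrapolate", {
  s <- spectrum(c(400, 500), c(0, 1))
  expect_error(resample(s, c(350, 450)), "outside source range")
  expect_error(resample(s, c(450, 550)), "outside source range")
})

test_that("coarse 60-nm sampling reproduces fine-grid responses within 5%", {
  # resolution-robustness: the oracle is the 1-nm quadrature pipeline.
  # The test stimulus is a broad Gaussian varying as gently as smooth
  # floral reflectance does; steep spectra (scale of variation well below
  # the 60-nm spacing) are outside what the coarse grid can represent.
  fine <- seq(300, 700, by = 1)
  stim_f <- spectrum(fine, 0.8 * exp(-(fine - 550)^2 / (2 * 120^2)))
  rec_f <- bee_receptors(grid = fine)
  ad_f <- adaptation_state(green_leaf_background(fine),
                           d65_illuminant(fine), rec_f)
  E_fine <- respond_spectrum(stim_f, ad_f)

  coarse <- bee_bands()
  stim_c <- resample(stim_f, coarse)
  sens_c <- lapply(rec_f$receptors, resample, target = coarse)
  rec_c <- receptor_set(sens_c, rec_f$peak_nm, rec_f$total_weight)
  ad_c <- adaptation_state(resample(ad_f$background, coarse),
                           resample(ad_f$illuminant, coarse), rec_c)
  E_coarse <- respond_spectrum(stim_c, ad_c)

  expect_true(all(abs(E_coarse - E_fine) / E_fine < 0.05))
})

test_that("pigment template peaks where asked and broadens with peak shift", {
  tl <- template_sensitivity(544, bee_bands(), beta_fraction = 0)
  expect_equal(bee_bands()[which.max(tl$value)], 520)  # nearest grid point

  fine <- seq(300, 700, by = 1)
  fwhm <- function(peak) {
    v <- template_sensitivity(peak, fine, beta_fraction = 0)$value
    sum(v >= max(v) / 2)  # direct width measurement on the 1-nm grid
  }
  expect_gt(fwhm(544), fwhm(344))
})

test_that("pigment template is nonnegative and alpha band is unimodal", {
  fine <- seq(300, 700, by = 1)
  for (peak in c(344, 436, 544, 620)) {
    v <- template_sensitivity(peak, fine, beta_fraction = 0)$value
    expect_true(all(v >= 0))
    sign_changes <- sum(diff(sign(diff(v))) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("beta band adds UV sensitivity and is gated by its amplitude", {
  fine <- seq(300, 700, by = 1)
  v0 <- template_sensitivity(544, fine, beta_fraction = 0)$value
  v3 <- template_sensitivity(544, fine, beta_fraction = 0.3)$value
  expect_gt(v3[fine == 340], v0[fine == 340])
  expect_error(template_sensitivity(250, fine), "within")
})

test_that("normalize_total fixes relative total sensitivities", {
  rs <- bee_receptors()
  sums <- vapply(rs$receptors, function(s) sum(s$value), numeric(1))
  expect_equal(unname(sums), rep(1, 3))  # default weights 1:1:1

  rs2 <- normalize_total(rs, c(S = 1, M = 2, L = 1))
  sums2 <- vapply(rs2$receptors, function(s) sum(s$value), numeric(1))
  expect_equal(unname(sums2["M"] / sums2["S"]), 2)

  rs3 <- normalize_total(rs2, c(S = 1, M = 2, L = 1))
  expect_identical(rs3$receptors$M$value, rs2$receptors$M$value)

  # shape unchanged: within-receptor value ratios preserved exactly
  ratio_before <- rs$receptors$L$value / rs$receptors$L$value[4]
  ratio_after <- rs2$receptors$L$value / rs2$receptors$L$value[4]
  expect_equal(ratio_after, ratio_before)
})

test_that("degenerate zero-total sensitivities are rejected", {
  z <- spectrum(bee_bands(), rep(0, 7), role = "sensitivity")
  expect_error(receptor_set(list(Z = z), c(Z = 400)), "degenerate")
})

test_that("flat_spectrum builds constant spectra and rejects negatives", {
  f <- flat_spectrum(bee_bands(), 1)
  expect_identical(f$value, rep(1, 7))
  expect_equal(sum(f$value), length(bee_bands()))
  expect_identical(flat_spectrum(bee_bands(), 0)$value, rep(0, 7))
  expect_error(flat_spectrum(bee_bands(), -0.1), "nonnegative")
})

test_that("wavelength grids are validated", {
  expect_error(wavelength_grid(400), "at least 2")
  expect_error(wavelength_grid(c(400, 400)), "strictly increasing")
  expect_error(wavelength_grid(c(250, 400)), "within")
})

test_that("spectrum CSV round-trips and packaged constants load", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  s <- spectrum(bee_bands(), c(0, 0.1, 0.25, 0.4, 0.55, 0.7, 0.9))
  write_spectrum_csv(s, tmp)
  r <- read_spectrum_csv(tmp)
  expect_equal(r$value, s$value)
  expect_equal(r$wavelength, s$wavelength)

  d65 <- d65_illuminant()
  expect_length(d65$value, 7)
  expect_true(all(d65$value > 0))
  leaf <- green_leaf_background()
  expect_lt(leaf$value[1], leaf$value[7])  # UV-dark, red-edge bright

  rcsv <- withr::local_tempfile(fileext = ".csv")
  rs <- bee_receptors()
  utils::write.csv(data.frame(
    wavelength_nm = bee_bands(),
    S = rs$receptors$S$value, M = rs$receptors$M$value,
    L = rs$receptors$L$value), rcsv, row.names = FALSE)
  rs2 <- read_receptor_csv(rcsv)
  expect_equal(rs2$receptors$L$value, rs$receptors$L$value)
  expect_equal(unname(rs2$peak_nm["S"]), 340)  # grid point nearest 344
})
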