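test_that("region mean spectrum reports per-band mean and population SD", {
  s <- make_sample(matrix(0.3, 50, 7))
  rm <- region_mean_spectrum(s)
  expect_equal(rm$mean$value, rep(0.3, 7))
  expect_equal(rm$sd, rep(0, 7))

  two <- make_sample(matrix(c(0, 1), 2, 7))
  rm2 <- region_mean_spectrum(two)
  expect_equal(rm2$mean$value[1], 0.5)
  expect_equal(rm2$sd[1], 0.5)  # population convention

  set.seed(31)
  vals <- matrix(runif(1000 * 7), 1000, 7)
  rm3 <- region_mean_spectrum(make_sample(vals))
  # oracle: direct summation
  for (b in 1:7) {
    expect_equal(rm3$mean$value[b], sum(vals[, b]) / 1000)
    expect_equal(rm3$sd[b],
                 sqrt(sum((vals[, b] - mean(vals[, b]))^2) / 1000))
  }
})

test_that("mean-color responses anchor at the background and at zero", {
  ad <- default_adaptation()
  expect_true(all(mean_color_response(ad$background, ad) == 0.5))
  zero <- flat_spectrum(bee_bands(), 0)
  expect_true(all(mean_color_response(zero, ad) == 0))

  # for a zero-variance region the mean-spectrum and per-pixel paths agree
  vals <- matrix(rep(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8), each = 20),
                 20, 7)
  s <- make_sample(vals)
  E_mean <- mean_color_response(region_mean_spectrum(s)$mean, ad)
  stats <- region_snr(s, ad)
  expect_equal(unname(E_mean[stats$receptor]), stats$mean_E)
})

test_that("region SNR matches an independent scalar recomputation", {
  ad <- default_adaptation()
  vals <- draw_region_pixels("petal", 200, seed = 6)
  s <- make_sample(vals)
  stats <- region_snr(s, ad, species = "sp1", region_class = "petal")

  rec <- ad$receptors
  for (r in c("S", "M", "L")) {
    E <- vapply(seq_len(nrow(vals)), function(i) {
      P <- quantum_catch(spectrum(bee_bands(), vals[i, ]),
                         rec$receptors[[r]], ad$illuminant, ad$R[[r]])
      response(P)
    }, numeric(1))
    row <- stats[stats$receptor == r, ]
    expect_equal(row$mean_E, mean(E), tolerance = 1e-12)
    expect_equal(row$sd_E, pop_sd(E), tolerance = 1e-12)
    expect_equal(row$snr, mean(E) / pop_sd(E), tolerance = 1e-12)
  }
})

test_that("zero-variance regions flag an infinite SNR without erroring", {
  ad <- default_adaptation()
  s <- make_sample(matrix(0.4, 30, 7))
  stats <- region_snr(s, ad)
  expect_true(all(is.infinite(stats$snr)))
  expect_true(all(stats$sd_E == 0))
})

test_that("noisier regions have strictly lower SNR in every channel", {
  ad <- default_adaptation()
  p1 <- scene_params()
  p2 <- p1
  p2$noise_sd <- lapply(p1$noise_sd, function(x) 2 * x)
  s1 <- region_snr(make_sample(draw_region_pixels("petal", 1000, p1,
                                                  seed = 9)), ad)
  s2 <- region_snr(make_sample(draw_region_pixels("petal", 1000, p2,
                                                  seed = 9)), ad)
  expect_true(all(s2$snr < s1$snr))
})

test_that("SNR is invariant to illuminant scale through the full path", {
  grid <- bee_bands()
  rec <- bee_receptors(grid)
  leaf <- green_leaf_background(grid)
  vals <- draw_region_pixels("leaf", 300, seed = 12)
  s <- make_sample(vals)
  d65 <- d65_illuminant(grid)
  bright <- spectrum(grid, 5 * d65$value, role = "illuminant")
  st1 <- region_snr(s, adaptation_state(leaf, d65, rec))
  st2 <- region_snr(s, adaptation_state(leaf, bright, rec))
  expect_equal(st1$snr, st2$snr, tolerance = 1e-12)
})

test_that("aggregation is order-invariant and excludes infinite SNRs", {
  one <- snr_rows("a", "leaf", S = 2, M = 3, L = 4)
  ag1 <- aggregate_stats(one)
  expect_equal(ag1$snr_mean[ag1$receptor == "L"], 4)
  expect_equal(ag1$snr_sd[ag1$receptor == "L"], 0)

  two <- snr_rows(c("a", "b"), "leaf", S = c(4, 6), M = c(4, 6),
                  L = c(4, 6))
  ag2 <- aggregate_stats(two)
  expect_equal(ag2$snr_mean, rep(5, 3))
  expect_equal(ag2$snr_sd, rep(1, 3))  # population SD

  shuffled <- two[sample(nrow(two)), ]
  expect_equal(aggregate_stats(shuffled), ag2)

  withinf <- snr_rows(c("a", "b", "c"), "petal",
                      S = c(4, 6, Inf), M = c(1, 2, 3), L = c(7, 8, 9))
  ag3 <- aggregate_stats(withinf)
  sc <- ag3[ag3$receptor == "S", ]
  expect_equal(sc$snr_mean, 5)
  expect_equal(sc$n_infinite, 1)
  expect_equal(sc$n_species, 2)
  expect_error(aggregate_stats(NULL), "no statistics")
})

test_that("channel comparison runs Kruskal-Wallis plus paired Wilcoxon", {
  snr <- c(1.3, 2.9, 0.8, 4.1, 2.2, 3.3, 1.9)
  same <- snr_rows(paste0("s", 1:7), "leaf", S = snr, M = snr, L = snr)
  rep0 <- compare_channels(same, "leaf")
  expect_equal(rep0$kruskal$statistic, 0, tolerance = 1e-12)
  expect_equal(rep0$kruskal$p, 1)

  # paired signed-rank depends only on within-species differences
  set.seed(44)
  S <- runif(12, 1, 4); M <- S + rnorm(12); L <- S + runif(12, 0.5, 2)
  offset <- rnorm(12, 0, 10)
  a <- snr_rows(paste0("s", 1:12), "leaf", S = S, M = M, L = L)
  b <- snr_rows(paste0("s", 1:12), "leaf", S = S + offset, M = M,
                L = L + offset)
  pa <- compare_channels(a, "leaf")$pairwise
  pb <- compare_channels(b, "leaf")$pairwise
  sl <- grepl("S", pa$pair) & grepl("L", pa$pair)
  expect_equal(pa$p[sl], pb$p[sl])
  expect_equal(pa$V[sl], pb$V[sl])

  few <- snr_rows(paste0("s", 1:4), "leaf", S = 1:4, M = 2:5, L = 3:6)
  expect_error(compare_channels(few, "leaf"), "at least 5")

  holm <- compare_channels(a, "leaf", adjust = "holm")
  expect_true(all(holm$pairwise$p >= pa$p))
})
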