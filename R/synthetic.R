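#' Parameters of the synthetic multispectral scene generator
#'
#' Defines the statistical structure of generated flower scenes, chosen to
#' emulate the reflectance regularities of real floral image sets:
#' every region's mean reflectance increases with wavelength; petals are
#' brighter than leaves and centers at every band (centers and leaves
#' darkest in the UV/blue); per-band pixel noise never decreases with
#' wavelength, and petals are the most homogeneous region. Each scene is a
#' schematic flower — a petal annulus around a center disc on a leaf
#' background — plus an in-frame gray-reference strip of flat-reflectance
#' patches spanning dark to light identically in every band.
#'
#' Mean curves are linear in wavelength: `base + slope * t + uv * (1 - t)`
#' with `t` the position within the grid range, clipped to `[0, 1]`; the
#' `uv` term carries species-level short-wavelength variability.
#'
#' @param width,height image size in pixels.
#' @param band_nm band peak wavelengths.
#' @param curves per-region mean-curve parameters (`base`, `slope`, `uv`).
#' @param noise_sd per-region pixel-noise SD at the first and last band
#'   (linearly interpolated between, hence nondecreasing).
#' @param r_center,r_petal_out center-disc and petal-annulus radii (px).
#' @param guard unassigned ring (px) between regions.
#' @param n_gray,gray_min,gray_max,strip_h gray-reference strip: patch
#'   count, level span, and strip height (rows at the image bottom).
#' @param distort whether to apply per-band affine gain/offset distortion.
#' @param gain_range,offset_range uniform ranges of the distortion.
#' @param max_band_shift maximum absolute integer misalignment per band
#'   (the alignment-reference band is never shifted).
#' @param ref_nm wavelength of the alignment-reference band.
#' @param seed integer RNG seed.
#' @return A `"scene_params"` list.
#' @export
scene_params <- function(width = 96L, height = 96L,
                         band_nm = bee_bands(),
                         curves = list(
                           petal  = list(base = 0.15, slope = 0.65, uv = 0),
                           center = list(base = 0.05, slope = 0.38, uv = 0),
                           leaf   = list(base = 0.07, slope = 0.40, uv = 0)),
                         noise_sd = list(
                           petal  = c(0.025, 0.035),
                           center = c(0.050, 0.100),
                           leaf   = c(0.040, 0.090)),
                         r_center = 10, r_petal_out = 26, guard = 3,
                         n_gray = 6L, gray_min = 0, gray_max = 1,
                         strip_h = 20L,
                         distort = TRUE,
                         gain_range = c(0.75, 0.92),
                         offset_range = c(0.02, 0.08),
                         max_band_shift = 3L, ref_nm = 520,
                         seed = 1L) {
  for (cls in names(curves)) {
    cv <- curves[[cls]]
    lo <- min(cv$base, cv$base + cv$slope)
    hi <- max(cv$base + cv$slope + max(0, cv$uv), cv$base + max(0, cv$uv))
    if (cv$base < 0 || cv$base > 1) {
      stop("mean-curve base for ", cls, " outside [0, 1]")
    }
    if (lo < -0.25 || hi > 1.25) {
      stop("mean-curve parameters for ", cls, " far outside [0, 1]")
    }
    if (any(noise_sd[[cls]] < 0)) stop("noise SD must be nonnegative")
    if (diff(noise_sd[[cls]]) < 0) {
      stop("noise SD must be nondecreasing with wavelength")
    }
  }
  if (n_gray < 5L) stop("gray strip needs at least 5 patches")
  structure(list(width = as.integer(width), height = as.integer(height),
                 band_nm = wavelength_grid(band_nm), curves = curves,
                 noise_sd = noise_sd, r_center = r_center,
                 r_petal_out = r_petal_out, guard = guard,
                 n_gray = as.integer(n_gray), gray_min = gray_min,
                 gray_max = gray_max, strip_h = as.integer(strip_h),
                 distort = distort, gain_range = gain_range,
                 offset_range = offset_range,
                 max_band_shift = as.integer(max_band_shift),
                 ref_nm = ref_nm, seed = as.integer(seed)),
            class = "scene_params")
}

# evaluate a region mean curve on the band grid, clipped to [0, 1]
region_curve_values <- function(cv, band_nm) {
  t <- (band_nm - min(band_nm)) / diff(range(band_nm))
  clamp01(cv$base + cv$slope * t + (cv$uv %||% 0) * (1 - t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean reflectance spectrum of a synthetic region
#'
#' The configured mean reflectance curve of one region class, evaluated
#' on the band grid. With default parameters the curve is nondecreasing
#' in wavelength, petals sit above leaves and centers at every band, and
#' leaves/centers are darkest in the UV/blue bands.
#'
#' @param region_class `"petal"`, `"center"` or `"leaf"`.
#' @param params a `"scene_params"`.
#' @return A reflectance `"spectrum"`.
#' @export
generate_region_spectrum <- function(region_class, params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  cv <- params$curves[[region_class]]
  if (is.null(cv)) stop("unknown region class: ", region_class)
  spectrum(params$band_nm, region_curve_values(cv, params$band_nm),
           role = "reflectance")
}

# per-band noise SD of a region: linear between the configured endpoints
region_noise_sd <- function(region_class, params) {
  ns <- params$noise_sd[[region_class]]
  B <- length(params$band_nm)
  ns[1] + (ns[2] - ns[1]) * (seq_len(B) - 1) / (B - 1)
}

#' Draw noisy pixel spectra from a synthetic region
#'
#' Simulates `n` individual pixels of one region: the region's mean curve
#' plus independent Gaussian per-band noise, truncated to `[0, 1]`.
#'
#' @param region_class region class.
#' @param n number of pixels.
#' @param params a `"scene_params"`.
#' @param seed integer RNG seed.
#' @return n x B matrix of reflectance values.
#' @export
draw_region_pixels <- function(region_class, n, params = scene_params(),
                               seed = 1L) {
  mu <- generate_region_spectrum(region_class, params)$value
  sd_b <- region_noise_sd(region_class, params)
  B <- length(mu)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n * B), n, B) *
      rep(sd_b, each = n)
    clamp01(matrix(mu, n, B, byrow = TRUE) + noise)
  })
}

# species-level jitter of the mean-curve parameters; petal variability is
# largest at short wavelengths (the uv term), emulating how flower colors
# spread out in the bee's visual space
jitter_curves <- function(curves) {
  curves$petal$base <- curves$petal$base + stats::rnorm(1, 0, 0.04)
  curves$petal$slope <- curves$petal$slope + stats::rnorm(1, 0, 0.03)
  curves$petal$uv <- (curves$petal$uv %||% 0) + stats::rnorm(1, 0, 0.10)
  for (cls in c("center", "leaf")) {
    curves[[cls]]$base <- curves[[cls]]$base + stats::rnorm(1, 0, 0.02)
    curves[[cls]]$slope <- curves[[cls]]$slope + stats::rnorm(1, 0, 0.03)
  }
  for (cls in names(curves)) {
    curves[[cls]]$base <- min(max(curves[[cls]]$base, 0), 1)
  }
  curves
}

#' Synthetic per-species petal reflectance spectra
#'
#' Draws `n` petal mean spectra with species-level jitter of the petal
#' curve parameters — the synthetic stand-in for the per-species mean
#' petal spectra of a real image database, used as the "petals"
#' reflectance source of the null-model sweep.
#'
#' @param n number of spectra.
#' @param grid wavelength grid.
#' @param params a `"scene_params"` providing the petal curve defaults.
#' @param seed integer RNG seed.
#' @return n x B matrix, one spectrum per row.
#' @export
synthetic_petal_spectra <- function(n, grid = bee_bands(),
                                    params = scene_params(), seed = 1L) {
  grid <- wavelength_grid(grid)
  cv <- params$curves$petal
  t <- (grid - min(grid)) / diff(range(grid))
  with_seed(seed, {
    base <- cv$base + stats::rnorm(n, 0, 0.04)
    slope <- cv$slope + stats::rnorm(n, 0, 0.03)
    uv <- (cv$uv %||% 0) + stats::rnorm(n, 0, 0.10)
    clamp01(outer(base, rep(1, length(grid))) +
              outer(slope, t) + outer(uv, 1 - t))
  })
}

#' Generate one synthetic multispectral scene with ground truth
#'
#' Lays out a schematic flower (petal annulus, center disc, leaf
#' background) and a gray-reference strip of flat-reflectance patches
#' spanning `gray_min`–`gray_max` identically in every band; adds
#' per-pixel Gaussian band noise (the strip is noise-free, as a
#' calibration target), then per-band affine gain/offset distortion and
#' integer band shifts (edge-replicated), recording all ground truth.
#' Deterministic under the params' seed.
#'
#' @param params a `"scene_params"`.
#' @return A list: `stack` (the emitted `"msstack"`), `masks` (logical
#'   matrices per region class), `truth` (list: `mean_cube`,
#'   `reflectance_cube` — post-noise, pre-distortion —, `shifts`,
#'   `gains`, `offsets`, `region_means`).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  H <- params$height; W <- params$width
  B <- length(params$band_nm)
  usable_h <- H - params$strip_h
  cy <- usable_h / 2; cx <- W / 2
  if (params$r_petal_out + params$guard >= min(cy, cx)) {
    stop("flower geometry exceeds the image bounds")
  }
  d <- sqrt(outer((seq_len(H) - 0.5 - cy)^2,
                  (seq_len(W) - 0.5 - cx)^2, `+`))
  in_scene <- row(d) <= usable_h
  masks <- list(
    petal = in_scene & d > params$r_center & d <= params$r_petal_out,
    center = in_scene & d <= params$r_center,
    leaf = in_scene & d > params$r_petal_out + params$guard &
      row(d) <= usable_h - params$guard)
  # gray strip: patches span dark to light identically in every band, in a
  # scrambled order. A monotone staircase is nearly a ramp, whose
  # x-autocorrelation is too flat to pin down band alignment; scrambling
  # gives the strip sharp, high-amplitude edges in every band. The extreme
  # patches sit away from the strip ends so band shifts never push the
  # darkest/lightest reference values out of the gray_ref rectangle.
  levels <- seq(params$gray_min, params$gray_max,
                length.out = params$n_gray)
  ng <- params$n_gray
  patch_order <- c(ng - 1L, 1L, ng, 2:(ng - 2L))
  patch_of_col <- pmin(ng, 1L + (seq_len(W) - 1L) %/% ceiling(W / ng))
  strip_row <- matrix(levels[patch_order][patch_of_col],
                      nrow = params$strip_h, ncol = W, byrow = TRUE)

  mean_cube <- array(0, c(H, W, B))
  region_means <- list()
  for (cls in c("leaf", "petal", "center")) {
    region_means[[cls]] <- generate_region_spectrum(cls, params)
  }
  for (b in seq_len(B)) {
    img <- matrix(region_means$leaf$value[b], H, W)
    img[masks$petal] <- region_means$petal$value[b]
    img[masks$center] <- region_means$center$value[b]
    img[(usable_h + 1):H, ] <- strip_row
    mean_cube[, , b] <- img
  }

  seed <- params$seed
  refl_cube <- with_seed(seed, {
    out <- mean_cube
    for (b in seq_len(B)) {
      noise <- matrix(stats::rnorm(H * W), H, W)
      sdmap <- matrix(0, H, W)
      for (cls in names(masks)) {
        sdmap[masks[[cls]]] <- region_noise_sd(cls, params)[b]
      }
      # the guard ring gets leaf-level noise; the strip stays noise-free
      ring <- in_scene & !masks$petal & !masks$center & !masks$leaf
      sdmap[ring] <- region_noise_sd("leaf", params)[b]
      out[, , b] <- clamp01(out[, , b] + noise * sdmap)
    }
    out
  })

  ref_b <- which.min(abs(params$band_nm - params$ref_nm))
  dist <- with_seed(child_seed(seed, 1L), list(
    gains = if (params$distort) {
      stats::runif(B, params$gain_range[1], params$gain_range[2])
    } else rep(1, B),
    offsets = if (params$distort) {
      stats::runif(B, params$offset_range[1], params$offset_range[2])
    } else rep(0, B),
    shifts = {
      s <- matrix(0L, B, 2, dimnames = list(NULL, c("dx", "dy")))
      if (params$max_band_shift > 0) {
        s[, 1] <- as.integer(sample(
          -params$max_band_shift:params$max_band_shift, B, replace = TRUE))
        s[, 2] <- as.integer(sample(
          -params$max_band_shift:params$max_band_shift, B, replace = TRUE))
        s[ref_b, ] <- 0L  # the alignment reference is never misaligned
      }
      s
    }))

  emitted <- array(0, c(H, W, B))
  for (b in seq_len(B)) {
    img <- dist$offsets[b] + dist$gains[b] * refl_cube[, , b]
    emitted[, , b] <- shift_image(img, dist$shifts[b, 1],
                                  dist$shifts[b, 2], fill = "replicate")
  }
  # gray_ref: full width, inset below the strip top by the worst-case shift
  inset <- max(2L, params$max_band_shift)
  gray_ref <- c(0, usable_h + inset, W, H)
  stack <- msstack(emitted, params$band_nm, gray_ref,
                   balanced = !params$distort,
                   aligned = all(dist$shifts == 0L))
  list(stack = stack, masks = masks,
       truth = list(mean_cube = mean_cube,
                    reflectance_cube = refl_cube,
                    shifts = dist$shifts, gains = dist$gains,
                    offsets = dist$offsets,
                    region_means = region_means,
                    params = params))
}

#' Generate a set of synthetic species scenes
#'
#' `k` scenes with species-level jitter of the mean-curve parameters,
#' larger at short wavelengths for petals, so the across-species spread
#' of petal reflectance is widest in the UV/blue. Per-scene seeds are
#' derived from the master seed; the same master seed reproduces the
#' identical set.
#'
#' @param k number of species.
#' @param params base `"scene_params"`.
#' @param seed master RNG seed.
#' @return A list of `k` elements, each `list(species, scene)` where
#'   `scene` is a [generate_scene()] result.
#' @export
generate_species_set <- function(k, params = scene_params(), seed = 1L) {
  if (k < 1) stop("k must be at least 1")
  lapply(seq_len(k), function(i) {
    sp_seed <- child_seed(seed, i)
    p <- params
    p$curves <- with_seed(sp_seed, jitter_curves(params$curves))
    p$seed <- child_seed(sp_seed, 7L)
    list(species = sprintf("species_%03d", i), scene = generate_scene(p))
  })
}

#' Write a synthetic scene to disk
#'
#' Emits 8-bit grayscale band PNGs, binary mask PNGs named
#' `<name>_<class>.png`, a YAML manifest readable by [read_stack()], and a
#' ground-truth JSON (shifts, gains, offsets, region mean spectra). The
#' 8-bit quantization on write exercises the realistic I/O path.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @param name scene name used as the file prefix.
#' @return The manifest path, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stack <- scene$stack
  B <- dim(stack$bands)[3]
  bands <- list()
  for (b in seq_len(B)) {
    f <- sprintf("%s_band_%03d.png", name, stack$band_nm[b])
    png::writePNG(stack$bands[, , b], file.path(dir, f))
    bands[[b]] <- list(file = f, nm = stack$band_nm[b])
  }
  mask_entries <- list()
  for (cls in names(scene$masks)) {
    f <- sprintf("%s_%s.png", name, cls)
    png::writePNG(scene$masks[[cls]] * 1, file.path(dir, f))
    mask_entries[[length(mask_entries) + 1L]] <-
      list(file = f, class = cls)
  }
  manifest <- file.path(dir, paste0(name, "_manifest.yaml"))
  yaml::write_yaml(list(bands = bands,
                        gray_ref = as.list(stack$gray_ref),
                        masks = mask_entries), manifest)
  truth <- scene$truth
  jsonlite::write_json(
    list(shifts = truth$shifts, gains = truth$gains,
         offsets = truth$offsets,
         region_means = lapply(truth$region_means, function(s) {
           list(wavelength_nm = s$wavelength, value = s$value)
         })),
    file.path(dir, paste0(name, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
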