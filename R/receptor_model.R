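#' Von Kries sensitivity factor
#'
#' The adaptation scalar R of a receptor viewing a background under an
#' illuminant: the reciprocal of the background quantum-catch integral
#' `sum(I_B * S * D)` over the shared grid. It expresses von Kries
#' adaptation — each receptor rescales its gain to the prevailing
#' background in its own spectral domain, so the background itself always
#' yields a quantum catch of 1.
#'
#' @param background background reflectance `"spectrum"` I_B.
#' @param sensitivity receptor sensitivity `"spectrum"` S.
#' @param illuminant illuminant `"spectrum"` D.
#' @return Positive scalar R.
#' @export
sensitivity_factor <- function(background, sensitivity, illuminant) {
  s <- catch_integral(background, sensitivity, illuminant)
  if (s <= 0) {
    stop("degenerate adaptation: background, sensitivity and illuminant ",
         "have no spectral overlap")
  }
  1 / s
}

# the discrete quantum-catch integral sum(I * S * D); grid spacing omitted
# because it cancels between the stimulus and background integrals
catch_integral <- function(stimulus, sensitivity, illuminant) {
  check_same_grid(stimulus, sensitivity, illuminant)
  sum(stimulus$value * sensitivity$value * illuminant$value)
}

# Row-wise quantum-catch accumulation with a fixed left-to-right band
# order. Used for both pixel matrices and the background vector so that a
# pixel bitwise-equal to the background yields exactly the same catch
# (BLAS matrix products may sum in a shape-dependent order; this must not).
catch_rows <- function(mat, w) {
  acc <- mat[, 1] * w[1]
  for (b in seq_along(w)[-1]) acc <- acc + mat[, b] * w[b]
  acc
}

check_same_grid <- function(...) {
  specs <- list(...)
  g <- specs[[1]]$wavelength
  for (s in specs[-1]) {
    if (!identical(s$wavelength, g)) {
      stop("all spectra must share one wavelength grid")
    }
  }
  invisible(TRUE)
}

#' Quantum catch of a receptor
#'
#' The relative amount of light absorbed by a receptor viewing a stimulus:
#' `P = R * sum(I_s * S * D)` over the shared wavelength grid, where R is
#' the von Kries sensitivity factor of the adapting background. P is
#' linear in the stimulus and equals 1 when the stimulus is the background
#' used to form R.
#'
#' @param stimulus stimulus reflectance `"spectrum"` I_s.
#' @param sensitivity receptor sensitivity `"spectrum"` S.
#' @param illuminant illuminant `"spectrum"` D.
#' @param R von Kries sensitivity factor (see [sensitivity_factor()]).
#' @return Nonnegative scalar P.
#' @export
quantum_catch <- function(stimulus, sensitivity, illuminant, R) {
  if (!is.finite(R) || R <= 0) stop("R must be positive and finite")
  R * catch_integral(stimulus, sensitivity, illuminant)
}

#' Naka-Rushton normalized receptor response
#'
#' The dimensionless receptor response `E = P / (P + 1)`, ranging from 0
#' (baseline) toward 1 (saturation) and exactly 0.5 at the adaptation
#' background (P = 1). The hyperbolic form gives near-logarithmic coding:
#' differences in E approximate ratios of quantum catches.
#'
#' @param P nonnegative quantum catch (vectorized).
#' @return E in `[0, 1)`.
#' @export
response <- function(P) {
  if (any(!is.finite(P)) || any(P < 0)) stop("P must be nonnegative")
  P / (P + 1)
}

#' Adaptation state of a receptor set
#'
#' Precomputes, for every receptor, the background quantum-catch integral
#' and its reciprocal R under a given background and illuminant. Response
#' computations divide stimulus catches by the stored background integral,
#' so a stimulus numerically identical to the background yields P = 1 and
#' E = 0.5 exactly.
#'
#' @param background background reflectance `"spectrum"`.
#' @param illuminant illuminant `"spectrum"`.
#' @param receptors a `"receptor_set"` on the same grid.
#' @return An object of class `"adaptation_state"` with elements
#'   `catch_bg` (named background integrals), `R` (named factors),
#'   `background`, `illuminant`, `receptors`.
#' @export
adaptation_state <- function(background, illuminant, receptors) {
  stopifnot(inherits(receptors, "receptor_set"))
  catch_bg <- vapply(receptors$receptors, function(s) {
    catch_integral(background, s, illuminant)
  }, numeric(1))
  if (any(catch_bg <= 0)) {
    stop("degenerate adaptation: zero background catch for receptor(s) ",
         paste(names(catch_bg)[catch_bg <= 0], collapse = ", "))
  }
  structure(list(catch_bg = catch_bg, R = 1 / catch_bg,
                 background = background, illuminant = illuminant,
                 receptors = receptors),
            class = "adaptation_state")
}

#' @export
print.adaptation_state <- function(x, ...) {
  cat("<adaptation_state>\n")
  print(data.frame(catch_bg = x$catch_bg, R = x$R))
  invisible(x)
}

#' Receptor responses to a single stimulus spectrum
#'
#' Applies the quantum-catch, von Kries and Naka-Rushton steps to one
#' stimulus under a precomputed adaptation state.
#'
#' @param stimulus stimulus reflectance `"spectrum"`.
#' @param adaptation an `"adaptation_state"`.
#' @return Named vector of responses E, one per receptor.
#' @export
respond_spectrum <- function(stimulus, adaptation) {
  stopifnot(inherits(adaptation, "adaptation_state"))
  P <- vapply(names(adaptation$catch_bg), function(r) {
    catch_integral(stimulus, adaptation$receptors$receptors[[r]],
                   adaptation$illuminant) / adaptation$catch_bg[[r]]
  }, numeric(1))
  response(P)
}

#' Receptor response maps for a whole multispectral stack
#'
#' Treats each pixel's band vector as a stimulus reflectance spectrum on
#' the stack's band grid and computes the per-receptor response E at every
#' pixel. The stack must be white-balanced (pixel values are treated as
#' linear reflectance) and its band wavelengths must equal the receptor
#' grid.
#'
#' @param stack a balanced `"msstack"` (see [read_stack()]).
#' @param receptors a `"receptor_set"` on the stack's band grid.
#' @param adaptation an `"adaptation_state"` built from `receptors`.
#' @return An object of class `"response_maps"`: a named list `maps` of
#'   H x W matrices of E values plus provenance fields.
#' @export
respond_stack <- function(stack, receptors, adaptation) {
  stopifnot(inherits(stack, "msstack"),
            inherits(receptors, "receptor_set"),
            inherits(adaptation, "adaptation_state"))
  if (!isTRUE(stack$balanced)) {
    stop("stack must be white-balanced before computing responses ",
         "(run white_balance())")
  }
  if (!isTRUE(all.equal(stack$band_nm, receptors$grid))) {
    stop("stack band wavelengths must equal the receptor grid")
  }
  H <- dim(stack$bands)[1]; W <- dim(stack$bands)[2]
  B <- dim(stack$bands)[3]
  pix <- matrix(stack$bands, nrow = H * W, ncol = B)
  D <- adaptation$illuminant$value
  maps <- lapply(names(receptors$receptors), function(r) {
    w <- receptors$receptors[[r]]$value * D
    # background catch through the same accumulation as the pixels, so a
    # pixel spectrally identical to the background yields P = 1 exactly
    denom <- catch_rows(matrix(adaptation$background$value, 1L, B), w)
    P <- catch_rows(pix, w) / denom
    matrix(response(P), nrow = H, ncol = W)
  })
  names(maps) <- names(receptors$receptors)
  structure(list(maps = maps, band_nm = stack$band_nm,
                 valid = stack$valid,
                 receptors = names(receptors$receptors)),
            class = "response_maps")
}

#' Write response maps as 16-bit grayscale TIFFs with a JSON sidecar
#'
#' Each receptor's E map is quantized to 16 bits (E scaled by 65535) and
#' written as `<prefix>_<receptor>.tiff`; a sidecar
#' `<prefix>_responses.json` records the receptor names, band grid and
#' scaling.
#'
#' @param maps a `"response_maps"`.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_response_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "response_maps"))
  files <- character(0)
  for (r in names(maps$maps)) {
    f <- paste0(prefix, "_", r, ".tiff")
    tiff::writeTIFF(maps$maps[[r]], f, bits.per.sample = 16L)
    files <- c(files, f)
  }
  side <- paste0(prefix, "_responses.json")
  jsonlite::write_json(
    list(receptors = names(maps$maps), band_nm = maps$band_nm,
         scale = 65535, encoding = "E * 65535, 16-bit grayscale PNG"),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(files, side))
}
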