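#' The seven-band wavelength grid of the multispectral camera filters
#'
#' Peak transmission wavelengths of the broadband filters used for the
#' floral image stacks: 340, 400, 460, 520, 580, 640 and 700 nm — one data
#' point every 60 nm across the visual range of bees. All spectra in a
#' computation live on one shared grid of this kind, so the discrete
#' integrals of the receptor model reduce to plain sums (the grid-spacing
#' factor cancels between the stimulus and background integrals).
#'
#' @param wavelengths numeric vector of wavelengths in nm; strictly
#'   increasing, all within 300–700 nm, at least two points.
#' @return The validated numeric vector.
#' @export
wavelength_grid <- function(wavelengths = bee_bands()) {
  w <- as.numeric(wavelengths)
  if (length(w) < 2L) stop("a wavelength grid needs at least 2 points")
  if (any(!is.finite(w))) stop("wavelengths must be finite")
  if (any(diff(w) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(w < 300 | w > 700)) {
    stop("wavelengths must lie within [300, 700] nm")
  }
  w
}

#' @rdname wavelength_grid
#' @export
bee_bands <- function() c(340, 400, 460, 520, 580, 640, 700)

#' Construct a spectrum on a wavelength grid
#'
#' A spectrum is a vector of nonnegative intensities on a shared wavelength
#' grid, tagged with the role it plays in the receptor model: the stimulus
#' reflectance I_s, the background reflectance I_B, the illuminant D, or a
#' receptor sensitivity S.
#'
#' @param wavelengths wavelength grid in nm (see [wavelength_grid()]).
#' @param values nonnegative intensities, one per grid point.
#' @param role one of `"reflectance"`, `"illuminant"`, `"sensitivity"`,
#'   `"background"`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths, values,
                     role = c("reflectance", "illuminant", "sensitivity",
                              "background")) {
  role <- match.arg(role)
  w <- wavelength_grid(wavelengths)
  v <- as.numeric(values)
  if (length(v) != length(w)) {
    stop("values must have one entry per grid point")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("spectrum values must be finite and nonnegative")
  }
  structure(list(wavelength = w, value = v, role = role),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d bands %g-%g nm>\n", x$role,
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  print(stats::setNames(x$value, x$wavelength))
  invisible(x)
}

#' Spectrally flat spectrum
#'
#' Constant spectrum at a given level; the building block of the null
#' model's unit background and unit illumination.
#'
#' @param grid wavelength grid in nm.
#' @param value constant nonnegative level.
#' @param role role tag, as in [spectrum()].
#' @return A `"spectrum"`.
#' @export
flat_spectrum <- function(grid, value = 1, role = "reflectance") {
  if (!is.finite(value) || value < 0) stop("value must be nonnegative")
  grid <- wavelength_grid(grid)
  spectrum(grid, rep(value, length(grid)), role = role)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation at the target wavelengths. Extrapolation is
#' forbidden: the source grid must cover the target range. When the target
#' grid is a subset of the source grid the source values are returned
#' unchanged at those points (interpolation is exact there).
#'
#' @param spec a `"spectrum"`.
#' @param target target wavelength grid in nm.
#' @return A `"spectrum"` on `target` with the role tag preserved.
#' @export
resample <- function(spec, target) {
  stopifnot(inherits(spec, "spectrum"))
  target <- wavelength_grid(target)
  if (min(target) < min(spec$wavelength) ||
      max(target) > max(spec$wavelength)) {
    stop(sprintf(
      "target grid [%g, %g] nm outside source range [%g, %g] nm",
      min(target), max(target), min(spec$wavelength), max(spec$wavelength)))
  }
  v <- stats::approx(spec$wavelength, spec$value, xout = target,
                     method = "linear", ties = "ordered")$y
  spectrum(target, v, role = spec$role)
}

#' Read and write single-spectrum CSV files
#'
#' The on-disk format is a two-column CSV `wavelength_nm,value` with a
#' header, one file per spectrum.
#'
#' @param path file path.
#' @param role role tag assigned to the spectrum read (see [spectrum()]).
#' @return `read_spectrum_csv` returns a `"spectrum"`;
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, role = "reflectance") {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    stop("spectrum CSV needs columns wavelength_nm,value: ", path)
  }
  spectrum(d$wavelength_nm, d$value, role = role)
}

#' @rdname read_spectrum_csv
#' @param spec spectrum to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = spec$wavelength, value = spec$value),
    path, row.names = FALSE)
  invisible(path)
}

#' Packaged standard daylight illuminant (D65)
#'
#' The CIE D65 relative spectral power distribution, tabulated at 10-nm
#' steps over 300–700 nm and resampled onto the requested grid on load.
#' The absolute scale is irrelevant to the receptor model (von Kries
#' adaptation cancels it); only the spectral shape matters.
#'
#' @param grid wavelength grid to resample onto.
#' @return A `"spectrum"` with role `"illuminant"`.
#' @export
d65_illuminant <- function(grid = bee_bands()) {
  path <- system.file("extdata", "d65_300_700nm.csv", package = "beefield")
  resample(read_spectrum_csv(path, role = "illuminant"), grid)
}

#' Packaged synthetic green-leaf reflectance
#'
#' A synthetic stand-in for the average green foliage background: low
#' reflectance in the UV/blue, a modest green bump near 550 nm, a
#' chlorophyll absorption dip in the red, and the start of the near-infrared
#' red edge at 700 nm. Used as the default adaptation background when no
#' leaf regions are available to average over.
#'
#' @param grid wavelength grid to resample onto.
#' @return A `"spectrum"` with role `"background"`.
#' @export
green_leaf_background <- function(grid = bee_bands()) {
  path <- system.file("extdata", "synthetic_green_leaf.csv",
                      package = "beefield")
  resample(read_spectrum_csv(path, role = "background"), grid)
}
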