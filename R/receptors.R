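#' Visual-pigment template sensitivity
#'
#' Builds a receptor spectral sensitivity from the A1 visual-pigment
#' alpha-band template of Govardovskii et al. (2000), optionally adding a
#' Gaussian UV beta band. The template's alpha band peaks at 1 before any
#' normalization and broadens (in nm) as the peak shifts toward longer
#' wavelengths, which is the property that matters for the receptor-noise
#' analysis: broader sensitivities average reflectance over more bands.
#'
#' The beta band is a Gaussian centered at `beta_center` with amplitude
#' `beta_fraction` relative to the alpha peak. Bee long-wavelength
#' receptors show a secondary UV peak that grows with the main peak's
#' wavelength; [default_beta_fraction()] encodes that schedule and is used
#' by [bee_receptors()].
#'
#' @param peak_nm alpha-band peak wavelength, within 300–700 nm.
#' @param grid wavelength grid to evaluate on.
#' @param beta_fraction nonnegative amplitude of the UV beta band relative
#'   to the alpha peak.
#' @param beta_center,beta_sd center and width (nm) of the Gaussian beta
#'   band.
#' @return A `"spectrum"` with role `"sensitivity"`.
#' @export
template_sensitivity <- function(peak_nm, grid = bee_bands(),
                                 beta_fraction = 0,
                                 beta_center = 340, beta_sd = 25) {
  if (!is.finite(peak_nm) || peak_nm < 300 || peak_nm > 700) {
    stop("peak_nm must lie within [300, 700] nm")
  }
  if (beta_fraction < 0) stop("beta_fraction must be nonnegative")
  grid <- wavelength_grid(grid)
  alpha <- govardovskii_alpha(grid, peak_nm)
  beta <- beta_fraction * exp(-(grid - beta_center)^2 / (2 * beta_sd^2))
  spectrum(grid, alpha + beta, role = "sensitivity")
}

# Govardovskii et al. (2000) A1 alpha-band template; x = lambda_max / lambda
govardovskii_alpha <- function(wl, peak_nm) {
  x <- peak_nm / wl
  a <- 0.8795 + 0.0459 * exp(-(peak_nm - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

# default UV beta-band amplitude schedule: zero for the UV receptor,
# growing linearly with peak wavelength (0.1 near 436 nm, 0.25 at 544 nm)
#' @rdname template_sensitivity
#' @export
default_beta_fraction <- function(peak_nm) {
  pmax(0, 0.25 * (peak_nm - 344) / 200)
}

#' Construct a set of named receptor sensitivities
#'
#' A receptor set is an ordered collection of sensitivity spectra on one
#' grid, with their peak wavelengths and relative total-sensitivity
#' weights. The total sensitivity of each receptor (its summed sensitivity
#' across all wavelengths) is held constant relative to the others: after
#' construction, `sum(sensitivity) == total_weight` for every receptor.
#'
#' @param sensitivities named list of `"spectrum"` objects (sensitivity
#'   role) on a common grid.
#' @param peak_nm named numeric vector of peak wavelengths.
#' @param total_weight named positive weights; defaults to 1 for each.
#' @return An object of class `"receptor_set"`.
#' @export
receptor_set <- function(sensitivities, peak_nm,
                         total_weight = NULL) {
  if (is.null(names(sensitivities)) || any(names(sensitivities) == "")) {
    stop("sensitivities must be a named list")
  }
  nm <- names(sensitivities)
  grids <- lapply(sensitivities, `[[`, "wavelength")
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("all sensitivities must share one wavelength grid")
  }
  if (is.null(total_weight)) total_weight <- stats::setNames(rep(1, length(nm)), nm)
  rs <- structure(list(receptors = sensitivities,
                       peak_nm = peak_nm[nm],
                       total_weight = total_weight[nm],
                       grid = grids[[1]]),
                  class = "receptor_set")
  normalize_total(rs, total_weight[nm])
}

#' @export
print.receptor_set <- function(x, ...) {
  cat(sprintf("<receptor_set: %s on %d bands>\n",
              paste(names(x$receptors), collapse = "/"),
              length(x$grid)))
  print(data.frame(peak_nm = x$peak_nm,
                   total_weight = x$total_weight,
                   row.names = names(x$receptors)))
  invisible(x)
}

#' Rescale receptor sensitivities to fixed relative total sensitivity
#'
#' Rescales each sensitivity so its sum over the grid equals its weight
#' (shape unchanged), keeping the total sensitivities of the receptors
#' constant relative to each other. Applying the operation twice with the
#' same weights is a no-op.
#'
#' @param receptors a `"receptor_set"`.
#' @param weights named positive weights, one per receptor.
#' @return The rescaled `"receptor_set"`.
#' @export
normalize_total <- function(receptors, weights) {
  stopifnot(inherits(receptors, "receptor_set"))
  nm <- names(receptors$receptors)
  weights <- weights[nm]
  if (any(is.na(weights)) || any(weights <= 0)) {
    stop("weights must be positive and cover every receptor")
  }
  for (r in nm) {
    s <- sum(receptors$receptors[[r]]$value)
    if (s <= 0) {
      stop("degenerate sensitivity (zero total) for receptor ", r)
    }
    receptors$receptors[[r]]$value <-
      receptors$receptors[[r]]$value * (weights[[r]] / s)
  }
  receptors$total_weight <- weights
  receptors
}

#' Default honeybee receptor set
#'
#' Template-based sensitivities for the bee's short- (S, 344 nm), medium-
#' (M, 436 nm) and long-wavelength (L, 544 nm) photoreceptors on the
#' seven-band grid, with UV beta-band amplitudes following
#' [default_beta_fraction()] and equal total-sensitivity weights. All
#' components are user-overridable (see [read_receptor_csv()]).
#'
#' @param grid wavelength grid.
#' @param peak_nm named receptor peaks.
#' @param beta_fraction named beta-band amplitudes; defaults to the
#'   peak-dependent schedule.
#' @param total_weight named relative total sensitivities.
#' @return A `"receptor_set"`.
#' @export
bee_receptors <- function(grid = bee_bands(),
                          peak_nm = c(S = 344, M = 436, L = 544),
                          beta_fraction = default_beta_fraction(peak_nm),
                          total_weight = c(S = 1, M = 1, L = 1)) {
  names(beta_fraction) <- names(peak_nm)
  sens <- lapply(names(peak_nm), function(r) {
    template_sensitivity(peak_nm[[r]], grid,
                         beta_fraction = beta_fraction[[r]])
  })
  names(sens) <- names(peak_nm)
  receptor_set(sens, peak_nm, total_weight)
}

#' Read a receptor set from CSV
#'
#' One file with columns `wavelength_nm,S,M,L` (or any receptor names
#' after the wavelength column). Peaks are taken as the wavelength of each
#' column's maximum; totals are normalized to the supplied weights.
#'
#' @param path CSV file path.
#' @param total_weight named weights; defaults to equal.
#' @return A `"receptor_set"`.
#' @export
read_receptor_csv <- function(path, total_weight = NULL) {
  d <- utils::read.csv(path)
  if (names(d)[1] != "wavelength_nm" || ncol(d) < 2L) {
    stop("receptor CSV needs wavelength_nm plus one column per receptor")
  }
  nm <- names(d)[-1]
  sens <- lapply(nm, function(r) {
    spectrum(d$wavelength_nm, d[[r]], role = "sensitivity")
  })
  names(sens) <- nm
  peaks <- vapply(nm, function(r) d$wavelength_nm[which.max(d[[r]])],
                  numeric(1))
  if (is.null(total_weight)) {
    total_weight <- stats::setNames(rep(1, length(nm)), nm)
  }
  receptor_set(sens, peaks, total_weight)
}
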