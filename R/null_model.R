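#' Random reflectance spectra
#'
#' Draws `n` reflectance spectra with independent Uniform(0, 1) intensity
#' at every grid point (configurable to Beta(a, b) for robustness checks).
#' Reproducible under `seed`.
#'
#' @param n number of spectra.
#' @param grid wavelength grid.
#' @param seed integer RNG seed.
#' @param shape1,shape2 optional Beta parameters; both `NULL` (default)
#'   means Uniform(0, 1).
#' @return An n x B numeric matrix, one spectrum per row, with the grid
#'   as attribute `"band_nm"`.
#' @export
random_spectra <- function(n, grid = bee_bands(), seed = 1L,
                           shape1 = NULL, shape2 = NULL) {
  if (n < 1) stop("n must be at least 1")
  grid <- wavelength_grid(grid)
  B <- length(grid)
  vals <- with_seed(seed, {
    if (is.null(shape1)) {
      stats::runif(n * B)
    } else {
      stats::rbeta(n * B, shape1, shape2)
    }
  })
  m <- matrix(vals, nrow = n, ncol = B)
  attr(m, "band_nm") <- grid
  m
}

#' Factor configuration for the null-model sweep
#'
#' Each factor of the receptor model can be switched between its "unit"
#' null setting and its realistic setting: illumination (unit vs D65),
#' background reflectance (unit vs average leaf), receptor sensitivity
#' shape (unit — a one-hot indicator at the peak band — vs the pigment
#' template), and the reflectance source (random spectra vs petal
#' spectra). All-unit with random reflectance is the null model;
#' all-realistic is the bee model.
#'
#' @param illumination `"unit"` or `"D65"`.
#' @param background `"unit"` or `"average_leaf"`.
#' @param sensitivity `"unit"` or `"template"`.
#' @param reflectance_source `"random"` or `"petals"`.
#' @param n_spectra number of spectra to run (default 10000).
#' @param seed integer RNG seed.
#' @return A `"factor_config"` list.
#' @export
factor_config <- function(illumination = c("unit", "D65"),
                          background = c("unit", "average_leaf"),
                          sensitivity = c("unit", "template"),
                          reflectance_source = c("random", "petals"),
                          n_spectra = 10000L, seed = 1L) {
  if (n_spectra < 1) stop("n_spectra must be at least 1")
  structure(list(illumination = match.arg(illumination),
                 background = match.arg(background),
                 sensitivity = match.arg(sensitivity),
                 reflectance_source = match.arg(reflectance_source),
                 n_spectra = as.integer(n_spectra),
                 seed = as.integer(seed)),
            class = "factor_config")
}

# build the sweep sensitivity for one peak under a config: one-hot
# indicator at the peak band, or the pigment template normalized to unit
# total sensitivity (so totals stay constant across peaks in both modes)
sweep_sensitivity <- function(peak_nm, grid, mode) {
  if (mode == "unit") {
    v <- as.numeric(grid == peak_nm)
    spectrum(grid, v, role = "sensitivity")
  } else {
    s <- template_sensitivity(peak_nm, grid,
                              beta_fraction = default_beta_fraction(peak_nm))
    spectrum(grid, s$value / sum(s$value), role = "sensitivity")
  }
}

sweep_illuminant <- function(grid, mode) {
  if (mode == "unit") flat_spectrum(grid, 1, role = "illuminant")
  else d65_illuminant(grid)
}

sweep_background <- function(grid, mode) {
  if (mode == "unit") flat_spectrum(grid, 1, role = "background")
  else green_leaf_background(grid)
}

# input spectra for a config: a matrix per reflectance_source
sweep_spectra <- function(config, grid, spectra = NULL) {
  if (!is.null(spectra)) return(spectra)
  if (config$reflectance_source == "random") {
    random_spectra(config$n_spectra, grid, seed = config$seed)
  } else {
    synthetic_petal_spectra(config$n_spectra, grid = grid,
                            seed = config$seed)
  }
}

#' Sweep receptor peak wavelength under one factor configuration
#'
#' For each band wavelength in the grid, builds a receptor with that peak
#' (one-hot or template per the config), adapts it to the configured
#' background and illuminant, computes the quantum catch P and response E
#' for every input spectrum, and returns per-peak moments. This is the
#' machinery of the factor-decomposition experiment that explains which
#' ingredients — sensitivity shape, flower reflectance, response
#' nonlinearity — produce the long-wavelength channel's advantage.
#'
#' @param config a `"factor_config"`.
#' @param spectra optional n x B matrix of reflectance spectra (rows);
#'   when `NULL`, generated per the config's `reflectance_source` and
#'   `seed`.
#' @param grid wavelength grid of candidate peaks (default: bee bands).
#' @return A `data.frame` with one row per peak: `peak_nm`, `mean_P`,
#'   `sd_P`, `mean_E`, `sd_E`, `n` (SDs population).
#' @export
run_sweep <- function(config, spectra = NULL, grid = bee_bands()) {
  stopifnot(inherits(config, "factor_config"))
  grid <- wavelength_grid(grid)
  spectra <- sweep_spectra(config, grid, spectra)
  if (ncol(spectra) != length(grid)) {
    stop("spectra must have one column per grid wavelength")
  }
  D <- sweep_illuminant(grid, config$illumination)
  BG <- sweep_background(grid, config$background)
  out <- lapply(grid, function(pk) {
    S <- sweep_sensitivity(pk, grid, config$sensitivity)
    denom <- catch_integral(BG, S, D)
    if (denom <= 0) {
      stop(sprintf("degenerate adaptation at peak %g nm", pk))
    }
    P <- as.vector(spectra %*% (S$value * D$value)) / denom
    E <- response(P)
    data.frame(peak_nm = pk, mean_P = mean(P), sd_P = pop_sd(P),
               mean_E = mean(E), sd_E = pop_sd(E), n = nrow(spectra))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full factor table over all 16 configurations
#'
#' Runs [run_sweep()] for every combination of the four binary factors
#' and concatenates the results in long format with the configuration
#' columns. Deterministic under `seed`: every configuration with the same
#' reflectance source reuses the identical input spectra.
#'
#' @param n number of spectra per configuration.
#' @param seed master RNG seed.
#' @param grid wavelength grid.
#' @return A `data.frame` of 16 x length(grid) rows with columns
#'   `illumination`, `background`, `sensitivity`, `source`, `peak_nm`,
#'   `mean_P`, `sd_P`, `mean_E`, `sd_E`, `n`, `seed`.
#' @export
factor_table <- function(n = 10000L, seed = 1L, grid = bee_bands()) {
  grid <- wavelength_grid(grid)
  sources <- list(
    random = random_spectra(n, grid, seed = seed),
    petals = synthetic_petal_spectra(n, grid = grid, seed = seed))
  combos <- expand.grid(illumination = c("unit", "D65"),
                        background = c("unit", "average_leaf"),
                        sensitivity = c("unit", "template"),
                        source = c("random", "petals"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- factor_config(combos$illumination[i], combos$background[i],
                         combos$sensitivity[i], combos$source[i],
                         n_spectra = n, seed = seed)
    sw <- run_sweep(cfg, spectra = sources[[combos$source[i]]],
                    grid = grid)
    cbind(combos[rep(i, nrow(sw)), , drop = FALSE], sw,
          seed = seed, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
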