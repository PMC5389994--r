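#' Mean reflectance spectrum of a sampled region
#'
#' Per-band mean and standard deviation of the sampled pixels' reflectance
#' values; the mean describes the average spectral reflectance function
#' (practically, the color) of the region. SDs use the population
#' convention (divisor n; see [pop_sd()]).
#'
#' @param sample a `"pixel_sample"` from [sample_region()].
#' @return List with `mean` (a reflectance `"spectrum"`), `sd` (per-band
#'   numeric), and `n`.
#' @export
region_mean_spectrum <- function(sample) {
  stopifnot(inherits(sample, "pixel_sample"))
  m <- colMeans(sample$values)
  s <- apply(sample$values, 2, pop_sd)
  list(mean = spectrum(sample$band_nm, m, role = "reflectance"),
       sd = s, n = nrow(sample$values))
}

#' Receptor responses to a region's mean color
#'
#' Applies the receptor model to the region's average reflectance
#' spectrum. Note this is the response to the mean spectrum, not the mean
#' of per-pixel responses — the two differ under the Naka-Rushton
#' nonlinearity whenever the region has variance (Jensen's inequality);
#' the per-pixel path is [region_snr()].
#'
#' @param mean_spectrum a reflectance `"spectrum"` on the receptor grid.
#' @param adaptation an `"adaptation_state"`.
#' @return Named per-receptor response vector E.
#' @export
mean_color_response <- function(mean_spectrum, adaptation) {
  respond_spectrum(mean_spectrum, adaptation)
}

#' Per-region receptor-response statistics and SNR
#'
#' Computes the receptor response E for every sampled pixel, then the
#' mean, population SD and signal-to-noise ratio (SNR = mean / SD) per
#' receptor. This SNR is a within-region homogeneity measure: high values
#' mean the region elicits consistent responses that are easy to group
#' into one object. A zero-variance region gives an infinite SNR, which
#' is flagged (not an error) and excluded downstream by [aggregate_stats()].
#'
#' @param sample a `"pixel_sample"`.
#' @param adaptation an `"adaptation_state"`.
#' @param species species/image identifier.
#' @param region_class `"petal"`, `"center"` or `"leaf"`.
#' @return A `data.frame` with one row per receptor: `species`,
#'   `region_class`, `receptor`, `mean_E`, `sd_E`, `snr`, `n`, `seed`
#'   (SD convention: population).
#' @export
region_snr <- function(sample, adaptation, species = NA_character_,
                       region_class = NA_character_) {
  stopifnot(inherits(sample, "pixel_sample"),
            inherits(adaptation, "adaptation_state"))
  rec <- adaptation$receptors
  if (!isTRUE(all.equal(sample$band_nm, rec$grid))) {
    stop("sample band wavelengths must equal the receptor grid")
  }
  D <- adaptation$illuminant$value
  out <- lapply(names(rec$receptors), function(r) {
    w <- rec$receptors[[r]]$value * D
    P <- as.vector(sample$values %*% w) / adaptation$catch_bg[[r]]
    E <- response(P)
    m <- mean(E); s <- pop_sd(E)
    data.frame(species = species, region_class = region_class,
               receptor = r, mean_E = m, sd_E = s,
               snr = if (s == 0) Inf else m / s,
               n = nrow(sample$values), seed = sample$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate per-region statistics across species
#'
#' Cross-species mean and population SD of each statistic per region
#' class x receptor cell. Infinite SNRs (zero-variance regions) are
#' excluded from the SNR aggregation and counted in `n_infinite`.
#' The result is invariant to the input row order.
#'
#' @param stats a `data.frame` of [region_snr()] rows (possibly many
#'   species bound together).
#' @return A `data.frame` with one row per region class x receptor:
#'   `mean_E`, `sd_E_across` (SD of per-species mean_E), `snr_mean`,
#'   `snr_sd`, `n_species`, `n_infinite`.
#' @export
aggregate_stats <- function(stats) {
  if (is.null(stats) || nrow(stats) == 0L) stop("no statistics to aggregate")
  cells <- unique(stats[, c("region_class", "receptor")])
  cells <- cells[order(cells$region_class, cells$receptor), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- stats[stats$region_class == cells$region_class[i] &
                   stats$receptor == cells$receptor[i], ]
    fin <- is.finite(sub$snr)
    data.frame(region_class = cells$region_class[i],
               receptor = cells$receptor[i],
               mean_E = mean(sub$mean_E),
               sd_E_across = pop_sd(sub$mean_E),
               snr_mean = mean(sub$snr[fin]),
               snr_sd = pop_sd(sub$snr[fin]),
               n_species = sum(fin),
               n_infinite = sum(!fin),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare receptor channels' SNRs within one region class
#'
#' Kruskal-Wallis test across the receptors' per-species SNR samples,
#' followed by pairwise Wilcoxon signed-rank tests (paired by species)
#' for every receptor pair. No multiplicity correction is applied by
#' default; `adjust = "holm"` enables it. Species with an infinite SNR in
#' any channel are dropped (counted in the report). Requires at least 5
#' species.
#'
#' @param stats a `data.frame` of [region_snr()] rows.
#' @param region_class region class to test.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return List with `kruskal` (statistic, df, p), `pairwise`
#'   (data.frame: pair, V, p), `n_species`, `n_dropped`, `adjust`.
#' @export
compare_channels <- function(stats, region_class,
                             adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  sub <- stats[stats$region_class == region_class, ]
  if (nrow(sub) == 0L) stop("no rows for region class ", region_class)
  wide <- stats::reshape(
    sub[, c("species", "receptor", "snr")],
    idvar = "species", timevar = "receptor", direction = "wide")
  names(wide) <- sub("^snr\\.", "", names(wide))
  rec <- setdiff(names(wide), "species")
  keep <- stats::complete.cases(wide) &
    apply(is.finite(as.matrix(wide[, rec])), 1, all)
  n_dropped <- sum(!keep)
  wide <- wide[keep, ]
  if (nrow(wide) < 5L) {
    stop("need at least 5 species with finite SNRs in all channels; have ",
         nrow(wide))
  }
  kw <- stats::kruskal.test(lapply(rec, function(r) wide[[r]]))
  pairs <- utils::combn(rec, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    wt <- tryCatch(
      suppressWarnings(
        stats::wilcox.test(wide[[p[1]]], wide[[p[2]]], paired = TRUE)),
      error = function(e) NULL)  # e.g. all paired differences zero
    data.frame(pair = paste(p, collapse = "-"),
               V = if (is.null(wt)) NA_real_ else unname(wt$statistic),
               p = if (is.null(wt)) NA_real_ else wt$p.value,
               stringsAsFactors = FALSE)
  }))
  if (adjust == "holm") pw$p <- stats::p.adjust(pw$p, method = "holm")
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw, n_species = nrow(wide), n_dropped = n_dropped,
       adjust = adjust, region_class = region_class)
}

#' Write per-region statistics as tidy CSV
#'
#' @param stats a `data.frame` of [region_snr()] rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
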