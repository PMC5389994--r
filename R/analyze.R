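#' Run the full receptor-response analysis on a set of scenes
#'
#' The complete pipeline behind the per-region statistics: each scene is
#' white-balanced and band-aligned, each region mask is sampled, leaf mean
#' spectra are averaged into the shared adaptation background (the
#' "average leaf"; a packaged synthetic green-leaf curve is substituted
#' and messaged when no scene has a leaf region), and per-region receptor
#' statistics and SNRs are computed under a single adaptation state
#' shared across all scenes. Set `adapt_per_scene = TRUE` to re-derive
#' the background from each scene's own leaves instead.
#'
#' @param scenes list of `list(species, scene)` entries as produced by
#'   [generate_species_set()], or of `list(species, stack, masks)` with a
#'   read stack.
#' @param receptors a `"receptor_set"`.
#' @param illuminant illuminant `"spectrum"` (default D65 on the
#'   receptor grid).
#' @param n pixels sampled per region (default 1000).
#' @param seed master sampling seed.
#' @param max_shift alignment search radius in pixels.
#' @param adapt_per_scene re-derive the adaptation background per scene.
#' @return List: `stats` (per species x region x receptor
#'   [region_snr()] rows), `mean_responses` (per species x region
#'   responses to the mean spectrum), `summary` ([aggregate_stats()]
#'   table), `background` (the adaptation background used), `adaptation`.
#' @export
analyze_scenes <- function(scenes, receptors = bee_receptors(),
                           illuminant = d65_illuminant(receptors$grid),
                           n = 1000L, seed = 1L, max_shift = 5L,
                           adapt_per_scene = FALSE) {
  prepped <- lapply(seq_along(scenes), function(i) {
    entry <- scenes[[i]]
    stack <- if (!is.null(entry$scene)) entry$scene$stack else entry$stack
    masks <- if (!is.null(entry$scene)) entry$scene$masks else entry$masks
    if (!isTRUE(stack$balanced)) stack <- white_balance(stack)
    if (!isTRUE(stack$aligned)) stack <- align_bands(stack, max_shift)
    samples <- list()
    for (cls in names(masks)) {
      samples[[cls]] <- sample_region(stack, masks[[cls]], n = n,
                                      seed = child_seed(seed, 100L * i +
                                                          match(cls, names(masks))))
    }
    list(species = entry$species %||% sprintf("species_%03d", i),
         stack = stack, samples = samples)
  })

  leaf_means <- lapply(prepped, function(p) {
    if (!is.null(p$samples$leaf)) region_mean_spectrum(p$samples$leaf)$mean
  })
  leaf_means <- Filter(Negate(is.null), leaf_means)
  background <- if (length(leaf_means) > 0) {
    vals <- rowMeans(vapply(leaf_means, `[[`, numeric(length(receptors$grid)),
                            "value"))
    spectrum(receptors$grid, vals, role = "background")
  } else {
    message("no leaf regions available: using the packaged synthetic ",
            "green-leaf background")
    green_leaf_background(receptors$grid)
  }
  adaptation <- adaptation_state(background, illuminant, receptors)

  stats_rows <- list(); mean_rows <- list()
  for (p in prepped) {
    adapt_i <- adaptation
    if (adapt_per_scene && !is.null(p$samples$leaf)) {
      bg_i <- region_mean_spectrum(p$samples$leaf)$mean
      bg_i$role <- "background"
      adapt_i <- adaptation_state(bg_i, illuminant, receptors)
    }
    for (cls in names(p$samples)) {
      stats_rows[[length(stats_rows) + 1L]] <-
        region_snr(p$samples[[cls]], adapt_i, species = p$species,
                   region_class = cls)
      ms <- region_mean_spectrum(p$samples[[cls]])$mean
      E <- mean_color_response(ms, adapt_i)
      mean_rows[[length(mean_rows) + 1L]] <-
        data.frame(species = p$species, region_class = cls,
                   receptor = names(E), mean_color_E = unname(E),
                   stringsAsFactors = FALSE)
    }
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL
  mean_responses <- do.call(rbind, mean_rows)
  rownames(mean_responses) <- NULL
  list(stats = stats, mean_responses = mean_responses,
       summary = aggregate_stats(stats), background = background,
       adaptation = adaptation)
}

#' Run the analysis from stack manifests on disk
#'
#' File-based front end to [analyze_scenes()] for an image database on
#' disk: reads each YAML manifest (band images, gray reference, region
#' masks) with [read_stack()] and runs the identical pipeline. This is
#' the entry point for analyzing a real multispectral flower database.
#'
#' @param manifests character vector of manifest paths.
#' @param species optional species identifiers (defaults to manifest
#'   file names).
#' @param ... passed to [analyze_scenes()].
#' @return See [analyze_scenes()].
#' @export
analyze_image_set <- function(manifests, species = NULL, ...) {
  if (length(manifests) == 0L) stop("no manifests supplied")
  if (is.null(species)) {
    species <- sub("_manifest\\.ya?ml$", "",
                   basename(manifests))
  }
  scenes <- lapply(seq_along(manifests), function(i) {
    stack <- read_stack(manifests[i])
    masks <- attr(stack, "masks")
    if (is.null(masks)) {
      stop("manifest has no region masks: ", manifests[i])
    }
    list(species = species[i], stack = stack, masks = masks)
  })
  analyze_scenes(scenes, ...)
}
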