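#' Construct a multispectral image stack
#'
#' A stack is a set of B co-registered grayscale images of one scene, each
#' taken through a different band-pass filter, held as an H x W x B array
#' of values in `[0, 1]` together with the band peak wavelengths, the
#' gray-reference rectangle, and processing-state flags.
#'
#' Coordinates are 0-based and row-major; rectangles are half-open
#' `[x0, x1) x [y0, y1)` with x along columns and y along rows.
#'
#' @param bands H x W x B numeric array, values in `[0, 1]`.
#' @param band_nm strictly increasing band peak wavelengths (nm).
#' @param gray_ref gray-reference rectangle `c(x0, y0, x1, y1)`.
#' @param balanced,aligned processing-state flags.
#' @param valid optional H x W logical matrix of in-frame pixels.
#' @param shifts optional B x 2 matrix of applied `(dx, dy)` corrections.
#' @return An object of class `"msstack"`.
#' @export
msstack <- function(bands, band_nm, gray_ref,
                    balanced = FALSE, aligned = FALSE,
                    valid = NULL, shifts = NULL) {
  stopifnot(is.array(bands), length(dim(bands)) == 3L)
  H <- dim(bands)[1]; W <- dim(bands)[2]; B <- dim(bands)[3]
  if (length(band_nm) != B) stop("band_nm must have one entry per band")
  if (any(diff(band_nm) <= 0)) {
    stop("band wavelengths must be strictly increasing")
  }
  gray_ref <- as.numeric(gray_ref)
  if (length(gray_ref) != 4L ||
      gray_ref[1] < 0 || gray_ref[2] < 0 ||
      gray_ref[3] > W || gray_ref[4] > H ||
      gray_ref[1] >= gray_ref[3] || gray_ref[2] >= gray_ref[4]) {
    stop("gray_ref must be a nonempty [x0,y0,x1,y1] rectangle inside ",
         "the image bounds")
  }
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  structure(list(bands = bands, band_nm = as.numeric(band_nm),
                 gray_ref = gray_ref, balanced = balanced,
                 aligned = aligned, valid = valid, shifts = shifts),
            class = "msstack")
}

#' @export
print.msstack <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf(
    "<msstack: %dx%d px, %d bands (%s nm), balanced=%s, aligned=%s>\n",
    d[1], d[2], d[3], paste(x$band_nm, collapse = ","),
    x$balanced, x$aligned))
  invisible(x)
}

# gray_ref rectangle -> 1-based row/col index lists
gray_ref_idx <- function(stack) {
  r <- stack$gray_ref
  list(rows = (r[2] + 1):r[4], cols = (r[1] + 1):r[3])
}

# read one grayscale image file; both readPNG and readTIFF map integer
# samples onto [0,1] by dividing by the type maximum
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format (need PNG or TIFF): ", path))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Read a multispectral stack from a YAML manifest
#'
#' The manifest lists the band image files with their peak wavelengths and
#' the gray-reference rectangle:
#' ```yaml
#' bands:
#'   - {file: band_340.png, nm: 340}
#'   - ...
#' gray_ref: [x0, y0, x1, y1]
#' masks:
#'   - {file: scene_petal.png, class: petal}   # optional
#' ```
#' Relative file names are resolved against the manifest's directory.
#' Integer pixel values are mapped to `[0, 1]` by dividing by the type
#' maximum (255 or 65535); the stack starts unbalanced and unaligned.
#'
#' @param manifest path to the YAML manifest.
#' @return An `"msstack"`; any masks are attached as attribute `"masks"`,
#'   a named-by-class list of logical matrices.
#' @export
read_stack <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  if (is.null(m$bands) || is.null(m$gray_ref)) {
    stop("malformed manifest (need bands and gray_ref): ", manifest)
  }
  dir <- dirname(manifest)
  resolve <- function(f) if (file.exists(f)) f else file.path(dir, f)
  imgs <- list(); nm <- numeric(0)
  for (b in m$bands) {
    f <- resolve(b$file)
    if (!file.exists(f)) stop("missing band image: ", b$file)
    imgs[[length(imgs) + 1L]] <- read_gray_image(f)
    nm <- c(nm, b$nm)
  }
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("band images have mismatched dimensions in ", manifest)
  }
  ord <- order(nm)
  cube <- array(0, c(dims[1, 1], dims[2, 1], length(imgs)))
  for (i in seq_along(ord)) cube[, , i] <- imgs[[ord[i]]]
  stack <- msstack(cube, nm[ord], unlist(m$gray_ref))
  if (!is.null(m$masks)) {
    masks <- list()
    for (mk in m$masks) {
      f <- resolve(mk$file)
      if (!file.exists(f)) stop("missing mask image: ", mk$file)
      masks[[mk$class]] <- read_gray_image(f) > 0.5
    }
    attr(stack, "masks") <- masks
  }
  stack
}

#' Gray-reference white balance
#'
#' Per band, finds the darkest value d and lightest value l inside the
#' gray-reference rectangle and applies the affine map
#' `v -> (v - d) / (l - d)`, clipped to `[0, 1]` — setting the darkest
#' reference pixel black and the lightest white. Because the reference
#' strip has flat spectral reflectance at graded levels, this removes
#' per-band exposure/gain differences; pixel values are thereafter treated
#' as linear reflectance.
#'
#' @param stack an `"msstack"` with a gray-reference rectangle.
#' @return The balanced `"msstack"` (`balanced = TRUE`).
#' @export
white_balance <- function(stack) {
  stopifnot(inherits(stack, "msstack"))
  idx <- gray_ref_idx(stack)
  for (b in seq_len(dim(stack$bands)[3])) {
    ref <- stack$bands[idx$rows, idx$cols, b]
    d <- min(ref); l <- max(ref)
    if (l - d <= .Machine$double.eps) {
      stop(sprintf(
        "degenerate gray reference in band %g nm (no dark-light span)",
        stack$band_nm[b]))
    }
    stack$bands[, , b] <- clamp01((stack$bands[, , b] - d) / (l - d))
  }
  stack$balanced <- TRUE
  stack
}

# translate an image by integer (dx, dy): out[r, c] = img[r - dy, c - dx]
shift_image <- function(img, dx, dy, fill = c("zero", "replicate")) {
  fill <- match.arg(fill)
  H <- nrow(img); W <- ncol(img)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  if (fill == "replicate") {
    img[pmin(pmax(src_r, 1L), H), pmin(pmax(src_c, 1L), W), drop = FALSE]
  } else {
    out <- matrix(0, H, W)
    ok_r <- src_r >= 1L & src_r <= H
    ok_c <- src_c >= 1L & src_c <= W
    out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
    out
  }
}

# Template-matching NCC: the band's central crop (margin m) is the fixed
# template; for a candidate shift the template is correlated against the
# reference window implied by band[r, c] == ref[r - sy, c - sx]. Keeping
# the template side fixed across candidates avoids the bias of comparing
# correlations computed over windows of different content.
shift_ncc <- function(template, ref, rows, cols, sx, sy) {
  b <- as.vector(ref[rows - sy, cols - sx])
  if (stats::sd(b) == 0) return(NA_real_)
  stats::cor(template, b)
}

#' Integer band alignment by normalized cross-correlation
#'
#' Registers every band against a reference band (default: the band
#' nearest 520 nm) by exhaustive search over integer translations within
#' `max_shift` pixels, maximizing the normalized cross-correlation
#' (Pearson correlation over the overlap). The winning shift is undone by
#' a pure translation — pixel values are never altered, only positions;
#' pixels translated in from outside the frame are zero-filled and marked
#' invalid in the stack's `valid` mask.
#'
#' Candidate shifts are scanned in order of increasing displacement, so
#' exact ties resolve to the smallest shift. A constant band has no
#' correlation structure; it is left untouched with a warning. A best
#' shift on the search-window boundary triggers a residual-misalignment
#' warning.
#'
#' @param stack a balanced `"msstack"`.
#' @param max_shift maximum absolute shift in pixels (per axis).
#' @param ref_nm wavelength whose nearest band is the alignment reference.
#' @return The aligned `"msstack"` with `shifts` recording the detected
#'   `(dx, dy)` per band.
#' @export
align_bands <- function(stack, max_shift = 10L, ref_nm = 520) {
  stopifnot(inherits(stack, "msstack"))
  if (!isTRUE(stack$balanced)) {
    stop("stack must be white-balanced before alignment")
  }
  if (max_shift < 0) stop("max_shift must be nonnegative")
  B <- dim(stack$bands)[3]
  H <- dim(stack$bands)[1]; W <- dim(stack$bands)[2]
  m <- as.integer(max_shift)
  if (2L * m + 2L >= min(H, W)) {
    stop("max_shift too large for the image size")
  }
  rows <- (m + 1L):(H - m); cols <- (m + 1L):(W - m)
  ref_b <- which.min(abs(stack$band_nm - ref_nm))
  ref <- stack$bands[, , ref_b]
  cand <- expand.grid(sx = -m:m, sy = -m:m)
  cand <- cand[order(abs(cand$sx) + abs(cand$sy), abs(cand$sy),
                     abs(cand$sx)), ]
  shifts <- matrix(0L, B, 2, dimnames = list(NULL, c("dx", "dy")))
  valid <- stack$valid
  for (b in seq_len(B)) {
    if (b == ref_b) next
    band <- stack$bands[, , b]
    template <- as.vector(band[rows, cols])
    if (stats::sd(template) == 0) {
      warning(sprintf("constant band %g nm: alignment skipped",
                      stack$band_nm[b]))
      next
    }
    best <- c(0L, 0L); best_ncc <- -Inf
    for (k in seq_len(nrow(cand))) {
      ncc <- shift_ncc(template, ref, rows, cols, cand$sx[k], cand$sy[k])
      if (!is.na(ncc) && ncc > best_ncc) {
        best_ncc <- ncc
        best <- c(cand$sx[k], cand$sy[k])
      }
    }
    if (max_shift > 0 && max(abs(best)) == max_shift) {
      warning(sprintf(
        "band %g nm: best shift (%d,%d) on the search boundary; residual misalignment likely",
        stack$band_nm[b], best[1], best[2]))
    }
    shifts[b, ] <- as.integer(best)
    stack$bands[, , b] <- shift_image(band, -best[1], -best[2])
    inframe <- shift_image(matrix(1, nrow(band), ncol(band)),
                           -best[1], -best[2]) > 0
    valid <- valid & inframe
  }
  stack$valid <- valid
  stack$shifts <- shifts
  stack$aligned <- TRUE
  stack
}

#' Randomly sample pixels from a region mask
#'
#' Draws `n` pixels uniformly from the mask (intersected with the stack's
#' valid-pixel mask) and records their per-band reflectance vectors.
#' Sampling is without replacement when the mask holds at least `n`
#' pixels, with replacement otherwise (flagged in the result and
#' messaged). Reproducible under `seed`; the caller's RNG stream is left
#' untouched.
#'
#' @param stack a balanced, aligned `"msstack"`.
#' @param mask logical H x W region mask.
#' @param n number of pixels to draw (default 1000).
#' @param seed integer RNG seed.
#' @return An object of class `"pixel_sample"`: fields `coords` (n x 2,
#'   row/col), `values` (n x B), `band_nm`, `n`, `seed`, `replace`.
#' @export
sample_region <- function(stack, mask, n = 1000L, seed = 1L) {
  stopifnot(inherits(stack, "msstack"), is.logical(mask))
  if (!isTRUE(stack$balanced) || !isTRUE(stack$aligned)) {
    stop("stack must be white-balanced and aligned before sampling")
  }
  if (!all(dim(mask) == dim(stack$bands)[1:2])) {
    stop("mask dimensions must match the stack")
  }
  pool <- which(mask & stack$valid)
  if (length(pool) == 0L) stop("empty region mask (no valid pixels)")
  replace <- length(pool) < n
  if (replace) {
    message(sprintf(
      "mask has %d pixels < n = %d: sampling with replacement",
      length(pool), n))
  }
  idx <- with_seed(seed, sample(pool, n, replace = replace))
  H <- dim(stack$bands)[1]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  B <- dim(stack$bands)[3]
  vals <- matrix(0, n, B)
  for (b in seq_len(B)) vals[, b] <- stack$bands[, , b][idx]
  structure(list(coords = cbind(row = rows, col = cols), values = vals,
                 band_nm = stack$band_nm, n = n, seed = seed,
                 replace = replace),
            class = "pixel_sample")
}

#' False-color rendering of a multispectral stack
#'
#' `mode = "human"` maps the bands nearest 640, 520 and 460 nm to R, G, B,
#' approximating the scene's appearance to a human. `mode = "bee"` shifts
#' each channel down one step — UV becomes blue, blue becomes green and
#' yellow becomes red — mapping the bands nearest 580, 460 and 340 nm to
#' R, G, B, so bee-visible contrast becomes human-visible.
#'
#' @param stack a balanced `"msstack"`.
#' @param mode `"human"` or `"bee"`.
#' @return H x W x 3 integer array of 8-bit values (0–255).
#' @export
false_color <- function(stack, mode = c("human", "bee")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "msstack"))
  if (!isTRUE(stack$balanced)) stop("stack must be white-balanced first")
  want <- if (mode == "human") c(640, 520, 460) else c(580, 460, 340)
  pick <- vapply(want, function(nm) {
    i <- which.min(abs(stack$band_nm - nm))
    if (abs(stack$band_nm[i] - nm) > 30) {
      stop(sprintf("no band near %g nm available for %s rendering",
                   nm, mode))
    }
    i
  }, integer(1))
  H <- dim(stack$bands)[1]; W <- dim(stack$bands)[2]
  out <- array(0L, c(H, W, 3))
  for (ch in 1:3) {
    out[, , ch] <- as.integer(floor(
      clamp01(stack$bands[, , pick[ch]]) * 255 + 0.5))
  }
  out
}

#' Render one receptor's response map as an 8-bit heat map
#'
#' Linearly maps E in `[0, 1]` to brightness 0–255 (round half up), so
#' response values are represented by the brightness of each pixel.
#'
#' @param maps a `"response_maps"`.
#' @param receptor receptor name.
#' @return H x W integer matrix of 8-bit values.
#' @export
heat_map <- function(maps, receptor) {
  stopifnot(inherits(maps, "response_maps"))
  if (!receptor %in% names(maps$maps)) {
    stop("unknown receptor: ", receptor)
  }
  m <- maps$maps[[receptor]]
  matrix(as.integer(floor(clamp01(m) * 255 + 0.5)), nrow(m), ncol(m))
}

#' Reduce an image to compound-eye resolution
#'
#' Partitions the image into approximately `n_facets` equal rectangular
#' blocks on an aspect-preserving grid — one block per ommatidium — and
#' replaces each block by its mean, keeping the original pixel dimensions
#' (a blocky image). The honeybee eye has about 5000 ommatidia, hence the
#' default.
#'
#' @param image numeric matrix.
#' @param n_facets target number of facets (blocks), at least 1.
#' @return Matrix of the same dimensions with blockwise-constant values.
#' @export
downsample_ommatidia <- function(image, n_facets = 5000L) {
  stopifnot(is.matrix(image))
  if (n_facets < 1) stop("n_facets must be at least 1")
  H <- nrow(image); W <- ncol(image)
  if (n_facets > H * W) {
    warning("n_facets exceeds the pixel count; returning image unchanged")
    return(image)
  }
  s <- sqrt(n_facets * H / W)
  cand_rows <- unique(pmin(pmax(c(floor(s), ceiling(s)), 1), H))
  best <- NULL; best_err <- Inf
  for (rr in cand_rows) {
    cc <- pmin(pmax(round(n_facets / rr), 1), W)
    err <- abs(rr * cc - n_facets)
    if (err < best_err) { best <- c(rr, cc); best_err <- err }
  }
  rows <- best[1]; cols <- best[2]
  rbreak <- floor(seq(0, H, length.out = rows + 1))
  cbreak <- floor(seq(0, W, length.out = cols + 1))
  rblock <- findInterval(seq_len(H) - 1L, rbreak,
                         rightmost.closed = TRUE)
  cblock <- findInterval(seq_len(W) - 1L, cbreak,
                         rightmost.closed = TRUE)
  bid <- outer(rblock, (cblock - 1L) * rows, `+`)
  sums <- rowsum(as.vector(image), as.vector(bid))
  counts <- rowsum(rep(1, length(bid)), as.vector(bid))
  means <- stats::setNames(as.vector(sums / counts), rownames(sums))
  matrix(means[as.character(as.vector(bid))], H, W)
}

#' Write an 8-bit rendering to a PNG file
#'
#' Accepts the integer outputs of [false_color()] and [heat_map()].
#'
#' @param img H x W or H x W x 3 integer array of 8-bit values.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_render_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
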