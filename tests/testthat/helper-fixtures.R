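# shared fixtures, built in code at test time

# a pixel_sample wrapper around a plain value matrix
make_sample <- function(values, band_nm = bee_bands(), seed = 1L) {
  structure(list(coords = cbind(row = seq_len(nrow(values)), col = 1L),
                 values = values, band_nm = band_nm,
                 n = nrow(values), seed = seed, replace = FALSE),
            class = "pixel_sample")
}

# a balanced, aligned stack where every pixel has the given band vector
uniform_stack <- function(values, H = 8L, W = 8L, band_nm = bee_bands()) {
  cube <- array(rep(values, each = H * W), c(H, W, length(values)))
  msstack(cube, band_nm, gray_ref = c(0, 0, W, 2),
          balanced = TRUE, aligned = TRUE)
}

default_adaptation <- function(grid = bee_bands()) {
  adaptation_state(green_leaf_background(grid), d65_illuminant(grid),
                   bee_receptors(grid))
}

# region_snr-shaped rows from bare per-species SNR vectors
snr_rows <- function(species, region_class, S, M, L) {
  do.call(rbind, lapply(seq_along(species), function(i) {
    data.frame(species = species[i], region_class = region_class,
               receptor = c("S", "M", "L"),
               mean_E = 0.5, sd_E = 0.1,
               snr = c(S[i], M[i], L[i]), n = 1000L, seed = 1L,
               stringsAsFactors = FALSE)
  }))
}
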