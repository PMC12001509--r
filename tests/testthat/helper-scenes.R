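# Shared fixtures: all scenes are generated in code at test time.

# deterministic scene with every stochastic intensity perturbation off
noise_free_spec <- function(...) {
  args <- list(...)
  defaults <- list(gaussian_noise_sd = 0, poisson_noise = FALSE,
                   cell_brightness_cv = 0)
  do.call(scene_spec, utils::modifyList(defaults, args))
}

# small fast scene for unit tests
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_height_px = 320, image_width_px = 320,
                   n_cells = 4, cell_radius_px = c(35, 45))
  do.call(scene_spec, utils::modifyList(defaults, args))
}

small_noise_free_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_height_px = 320, image_width_px = 320,
                   n_cells = 4, cell_radius_px = c(35, 45),
                   gaussian_noise_sd = 0, poisson_noise = FALSE,
                   cell_brightness_cv = 0)
  do.call(scene_spec, utils::modifyList(defaults, args))
}

# rasterized disk mask
disk_mask <- function(r, pad = 3) {
  n <- 2 * r + 2 * pad
  cy <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) sqrt((i - cy)^2 + (j - cy)^2) <= r)
}

# independent brute-force Euclidean distance transform
brute_edt <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  rr <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  out <- matrix(Inf, nr, ncol(mask))
  for (i in seq_len(nr))
    for (j in seq_len(ncol(mask)))
      if (length(idx))
        out[i, j] <- sqrt(min((rr - i)^2 + (cc - j)^2))
  out
}
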