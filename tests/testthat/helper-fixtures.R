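# Shared fixtures, built in code.

box_region_ts <- function(shape, n_t, seed = 1, label = "region",
                          data = NULL) {
  grid <- vol_grid(shape)
  mask <- region_mask(array(1L, shape), grid, label)
  if (is.null(data)) {
    set.seed(seed)
    data <- matrix(rnorm(prod(shape) * n_t), prod(shape), n_t)
  }
  structure(list(mask = mask, data = data, demeaned = FALSE),
            class = "region_ts")
}

small_phantom <- function(scheme = "topographic", seed_rng = 1, snr = 10,
                          n_t = 200, seed_shape = c(5, 5, 5),
                          map_shape = c(7, 7, 7), ...) {
  generate_phantom(phantom_spec(seed_shape = seed_shape,
                                map_shape = map_shape, scheme = scheme,
                                n_timepoints = n_t, snr = snr,
                                seed_rng = seed_rng, ...))
}

# Brute-force grid oracle for the connective field fit: exhaustive search
# over integer-voxel centers and a 0.25-step sigma grid, minimizing the
# same correlation distance. Independent of the optimizer path.
grid_fit_oracle <- function(z, coords, sigma_step = 0.25) {
  coords <- as.matrix(coords)
  rng <- apply(coords, 2, function(v) diff(range(v)))
  sigmas <- seq(sigma_step, min(rng), by = sigma_step)
  d2 <- as.matrix(dist(coords))^2
  best <- c(obj = Inf, idx = NA, sigma = NA)
  for (s in sigmas) {
    W <- exp(-d2 / (2 * s^2))
    cors <- suppressWarnings(cor(z, W))
    j <- which.max(cors)
    if (1 - cors[j] < best["obj"])
      best <- c(obj = 1 - cors[j], idx = j, sigma = s)
  }
  list(center = coords[best["idx"], ], sigma = best[["sigma"]],
       objective = best[["obj"]])
}

write_phantom_nifti <- function(dir, seed_rng = 1, n_t = 60) {
  cfg <- list(out_dir = dir, seed = seed_rng,
              phantom = list(seed_shape = c(4, 4, 4),
                             map_shape = c(6, 6, 6),
                             n_timepoints = n_t, snr = 10))
  cf_run_phantom(cfg)
  cfg
}
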