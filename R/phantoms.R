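# Separable Gaussian smoothing of a 3-D array; kernel truncated at 3 SD and
# renormalized at the edges so the field keeps unit-ish scale everywhere.
gaussian_smooth_3d <- function(a, fwhm) {
  if (fwhm < 0) stop("'fwhm' must be non-negative")
  if (fwhm == 0) return(a)
  s <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * s))
  k <- stats::dnorm(-r:r, sd = s)
  smooth_axis <- function(x, ax) {
    out <- array(0, dim(x)); wt <- array(0, dim(x))
    n <- dim(x)[ax]
    idx <- lapply(dim(x), seq_len)
    for (o in -r:r) {
      w <- k[o + r + 1L]
      src <- seq_len(n) - o
      okk <- src >= 1L & src <= n
      si <- idx; si[[ax]] <- src[okk]
      ti <- idx; ti[[ax]] <- which(okk)
      out[ti[[1]], ti[[2]], ti[[3]]] <-
        out[ti[[1]], ti[[2]], ti[[3]]] + w * x[si[[1]], si[[2]], si[[3]]]
      wt[ti[[1]], ti[[2]], ti[[3]]] <-
        wt[ti[[1]], ti[[2]], ti[[3]]] + w
    }
    out / wt
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

#' Random volume with controlled smoothness
#'
#' A standard-normal field, optionally convolved with a Gaussian kernel of
#' the stated FWHM and re-standardized to zero mean, unit variance.
#'
#' @param shape 3 integers (each >= 2).
#' @param smooth_fwhm kernel FWHM in voxels (0 = white noise).
#' @param seed optional RNG seed.
#' @return 3-D numeric array.
#' @export
generate_random_volume <- function(shape, smooth_fwhm = 0, seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop("'shape' must be 3 integers >= 2")
  if (smooth_fwhm < 0) stop("'smooth_fwhm' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  a <- array(stats::rnorm(prod(shape)), shape)
  if (smooth_fwhm > 0) a <- gaussian_smooth_3d(a, smooth_fwhm)
  (a - mean(a)) / stats::sd(a)
}

#' Specify a synthetic connectivity phantom
#'
#' Defines the ground truth for [generate_phantom()]: a box-shaped seed and
#' mapping region, the connectivity scheme linking them, the true field
#' spread, time-series length, signal-to-noise ratio and mapping-signal
#' smoothness. Defaults reproduce the package's reference study
#' conditions: 818-frame sessions, SNR 2 (the lower end of the regime in
#' which parameter recovery is expected), a 2-voxel true spread, and an
#' identity topographic map.
#'
#' @param seed_shape,map_shape region shapes (3 integers, each >= 4).
#' @param scheme `"topographic"` (affine seed-to-mapping map),
#'   `"convergent"` (all seed voxels connect to one locus) or `"null"`
#'   (random center per seed voxel).
#' @param mapping_rule for `"topographic"`: a 3 x 4 affine matrix taking a
#'   seed voxel's 0-based `(i, j, k, 1)` to a mapping-region center;
#'   default scales the seed bounding box onto the mapping bounding box
#'   (the identity when shapes match). For `"convergent"`: a length-3
#'   locus, default the mapping-region center.
#' @param sigma_true true field spread in voxels.
#' @param n_timepoints frames per run (default 818).
#' @param snr ratio of signal variance to added noise variance (> 0).
#' @param smooth_fwhm spatial smoothness of the mapping source signals.
#' @param seed_rng RNG seed; the generator is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed_shape = c(6, 6, 6), map_shape = c(9, 9, 9),
                         scheme = c("topographic", "convergent", "null"),
                         mapping_rule = NULL, sigma_true = 2,
                         n_timepoints = 818, snr = 2, smooth_fwhm = 0,
                         seed_rng = 1L) {
  scheme <- match.arg(scheme)
  seed_shape <- as.integer(seed_shape); map_shape <- as.integer(map_shape)
  if (any(seed_shape < 4L) || any(map_shape < 4L))
    stop("region shapes must be >= 4 voxels per axis")
  if (!is.numeric(snr) || snr <= 0) stop("'snr' must be positive")
  if (!is.numeric(sigma_true) || sigma_true <= 0)
    stop("'sigma_true' must be positive")
  if (smooth_fwhm < 0) stop("'smooth_fwhm' must be non-negative")
  if (scheme == "topographic" && is.null(mapping_rule)) {
    sc <- (map_shape - 1) / (seed_shape - 1)
    mapping_rule <- cbind(diag(sc), c(0, 0, 0))
  }
  if (scheme == "convergent") {
    if (is.null(mapping_rule)) mapping_rule <- (map_shape - 1) / 2
    if (length(mapping_rule) != 3L ||
        any(mapping_rule < 0) || any(mapping_rule > map_shape - 1))
      stop("convergent locus outside the mapping region")
  }
  structure(list(seed_shape = seed_shape, map_shape = map_shape,
                 scheme = scheme, mapping_rule = mapping_rule,
                 sigma_true = sigma_true,
                 n_timepoints = as.integer(n_timepoints), snr = snr,
                 smooth_fwhm = smooth_fwhm, seed_rng = as.integer(seed_rng)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s: seed %s -> map %s, sigma* %.2f, %d frames, SNR %.1f, source FWHM %.1f, seed_rng %d\n",
              x$scheme, paste(x$seed_shape, collapse = "x"),
              paste(x$map_shape, collapse = "x"), x$sigma_true,
              x$n_timepoints, x$snr, x$smooth_fwhm, x$seed_rng))
  invisible(x)
}

full_box_region <- function(shape, label) {
  grid <- vol_grid(shape)
  region_mask(array(1L, shape), grid, label)
}

#' Generate a synthetic connectivity phantom
#'
#' Mapping voxels carry independent Gaussian-noise time series (optionally
#' spatially smoothed to `smooth_fwhm`); each seed voxel's series is the
#' Gaussian-weighted sum of the mapping series under its true connective
#' field, rescaled to unit variance, plus white noise with variance
#' `1 / snr`. Deterministic given `seed_rng`.
#'
#' @param spec a [phantom_spec].
#' @return A list with `seed` and `mapping` ([region_ts] objects), `truth`
#'   (data.frame of per-seed-voxel true `x0, y0, z0, sigma`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed_rng)
  seed_region <- full_box_region(spec$seed_shape, "seed")
  map_region <- full_box_region(spec$map_shape, "mapping")
  map_coords <- map_region$voxel_indices
  M <- nrow(map_coords); T <- spec$n_timepoints

  map_data <- matrix(stats::rnorm(M * T), M, T)
  if (spec$smooth_fwhm > 0) {
    for (t in seq_len(T)) {
      v <- array(map_data[, t], spec$map_shape)
      map_data[, t] <- as.vector(gaussian_smooth_3d(v, spec$smooth_fwhm))
    }
  }

  seed_ijk <- seed_region$voxel_indices
  n <- nrow(seed_ijk)
  centers <- switch(spec$scheme,
    topographic = t(spec$mapping_rule %*% t(cbind(seed_ijk, 1))),
    convergent = matrix(spec$mapping_rule, n, 3, byrow = TRUE),
    null = cbind(stats::runif(n, 0, spec$map_shape[1] - 1),
                 stats::runif(n, 0, spec$map_shape[2] - 1),
                 stats::runif(n, 0, spec$map_shape[3] - 1)))
  if (any(centers < -1e-9) ||
      any(sweep(centers, 2L, spec$map_shape - 1, "-") > 1e-9))
    stop("truth centers fall outside the mapping region")

  seed_data <- matrix(0, n, T)
  for (v in seq_len(n)) {
    w <- gaussian_weights(map_coords, centers[v, ], spec$sigma_true)
    sig <- as.vector(crossprod(map_data, w))
    sig <- sig / stats::sd(sig)
    seed_data[v, ] <- sig + stats::rnorm(T, sd = sqrt(1 / spec$snr))
  }

  truth <- data.frame(seed_ijk, x0 = centers[, 1], y0 = centers[, 2],
                      z0 = centers[, 3], sigma = spec$sigma_true)
  list(
    seed = structure(list(mask = seed_region, data = seed_data,
                          demeaned = FALSE), class = "region_ts"),
    mapping = structure(list(mask = map_region, data = map_data,
                             demeaned = FALSE), class = "region_ts"),
    truth = truth, spec = spec)
}

#' Block-structured synthetic linearity matrix
#'
#' A directed parcel-by-parcel linearity matrix with planted network
#' structure: `within` on within-network pairs, `between` elsewhere, plus
#' truncated Gaussian noise, clipped to [0, 1]. The diagonal is `NA`.
#'
#' @param n_parcels number of parcels (>= 2).
#' @param networks parcel-to-network assignment: a vector of length
#'   `n_parcels` (factor/character), or NULL for two equal blocks.
#' @param within,between mean linearity within / between networks
#'   (`0 <= between < within <= 1`).
#' @param noise_sd additive noise SD.
#' @param seed optional RNG seed.
#' @return A `linearity_matrix` (see [pairwise_linearity()]) with a
#'   `networks` attribute.
#' @export
generate_block_linearity_matrix <- function(n_parcels, networks = NULL,
                                            within = 0.4, between = 0.05,
                                            noise_sd = 0.02, seed = NULL) {
  if (n_parcels < 2L) stop("'n_parcels' must be >= 2")
  if (!(between >= 0 && between < within && within <= 1))
    stop("need 0 <= between < within <= 1")
  if (is.null(networks))
    networks <- rep(c("A", "B"),
                    c(ceiling(n_parcels / 2), floor(n_parcels / 2)))
  if (is.list(networks)) {
    ids <- unlist(networks)
    if (anyDuplicated(ids) || !setequal(ids, seq_len(n_parcels)))
      stop("'networks' partition overlaps or does not cover all parcels")
    nv <- character(n_parcels)
    for (nm in names(networks)) nv[networks[[nm]]] <- nm
    networks <- nv
  }
  if (length(networks) != n_parcels)
    stop("'networks' must assign every parcel")
  if (!is.null(seed)) set.seed(seed)
  same <- outer(networks, networks, `==`)
  vals <- ifelse(same, within, between)
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(n_parcels^2, sd = noise_sd),
                          n_parcels, n_parcels)
  vals <- pmin(pmax(vals, 0), 1)
  diag(vals) <- NA_real_
  out <- linearity_matrix(vals, parcel_ids = seq_len(n_parcels))
  attr(out, "networks") <- networks
  out
}
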