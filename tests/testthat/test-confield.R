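test_that("Fisher z profiles match closed forms and clamp extremes", {
  t_n <- 40
  set.seed(1)
  base <- rnorm(t_n)
  # construct series with known correlations to 'base'
  noise <- rnorm(t_n)
  noise <- residuals(lm(noise ~ base))
  mk <- function(r) r * scale(base)[, 1] + sqrt(1 - r^2) * scale(noise)[, 1]
  seed <- box_region_ts(c(2, 1, 1), t_n, data = rbind(base, base))
  mapping <- box_region_ts(c(2, 2, 2), t_n,
                           data = rbind(mk(0), mk(0.5), mk(-0.5), base,
                                        mk(0.9), mk(0.2), mk(-0.9), mk(1)))
  z <- fisher_z_profiles(seed, mapping)
  expect_equal(dim(z), c(2, 8))
  expect_equal(z[1, 1], 0, tolerance = 1e-10)
  expect_equal(z[1, 2], atanh(0.5), tolerance = 1e-8)
  expect_equal(z[1, 3], atanh(-0.5), tolerance = 1e-8)
  # identical series: clamped, finite
  expect_true(is.finite(z[1, 4]))
  expect_equal(z[1, 4], atanh(1 - 1e-7))

  flat <- mapping
  flat$data[2, ] <- 0  # zero-variance voxel
  expect_warning(z2 <- fisher_z_profiles(seed, flat), "zero-variance")
  expect_equal(z2[, 2], c(0, 0), ignore_attr = TRUE)

  short <- box_region_ts(c(2, 1, 1), 2, data = matrix(rnorm(4), 2))
  expect_error(fisher_z_profiles(short, short), "3 shared timepoints")
})

test_that("gaussian_weights is the stated density", {
  coords <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  for (sg in c(0.7, 1, 2)) {
    w <- gaussian_weights(coords, c(2, 2, 2), sg)
    peak <- 1 / (sg^3 * (2 * pi)^1.5)
    expect_equal(w[which(coords[, 1] == 2 & coords[, 2] == 2 &
                           coords[, 3] == 2)], peak)
    expect_true(all(w > 0))
    expect_equal(max(w), peak)
    # isotropy: equidistant coords get equal weights
    w1 <- gaussian_weights(matrix(c(3, 2, 2), 1), c(2, 2, 2), sg)
    w2 <- gaussian_weights(matrix(c(2, 1, 2), 1), c(2, 2, 2), sg)
    expect_equal(w1, w2)
    # unit displacement at sigma 1
    if (sg == 1) expect_equal(w1, peak * exp(-0.5))
  }
  expect_error(gaussian_weights(coords, c(0, 0, 0), 0), "positive")
  expect_error(gaussian_weights(coords, c(0, 0, 0), -1), "positive")
})

test_that("noise-free Gaussian profiles are recovered exactly", {
  coords <- as.matrix(expand.grid(0:8, 0:8, 0:8))
  truth <- c(3.4, 5.1, 2.7)
  z <- 7.3 * gaussian_weights(coords, truth, 2)  # arbitrary scaling
  fit <- confield:::fit_connective_field(z, coords)
  expect_lt(max(abs(c(fit$x0, fit$y0, fit$z0) - truth)), 0.1)
  expect_lt(abs(fit$sigma - 2), 0.1)
  expect_lt(fit$objective, 1e-6)
  expect_false(fit$degenerate)
  # scale invariance of the correlation-distance objective
  fit2 <- confield:::fit_connective_field(z * 100, coords)
  expect_equal(c(fit2$x0, fit2$y0, fit2$z0, fit2$sigma),
               c(fit$x0, fit$y0, fit$z0, fit$sigma), tolerance = 1e-4)
})

test_that("degenerate z profiles fall back to the published initialization", {
  coords <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  z <- rep(1, nrow(coords))
  fit <- confield:::fit_connective_field(z, coords)
  expect_true(fit$degenerate)
  expect_equal(fit$fit_r2, 0)
  # degenerate fits sit at the published initialization: the max-z location
  # (ties broken by the first voxel) and sigma at machine epsilon
  expect_equal(unname(c(fit$x0, fit$y0, fit$z0)), coords[1, ],
               ignore_attr = TRUE)
  expect_equal(fit$sigma, .Machine$double.eps)
  z2 <- z; z2[17] <- 5  # unique maximum but otherwise constant: fits
  f2 <- confield:::fit_connective_field(z2, coords)
  expect_false(f2$degenerate)
  expect_equal(unname(c(round(f2$x0), round(f2$y0), round(f2$z0))),
               coords[17, ], ignore_attr = TRUE)
})

test_that("optimizer matches the brute-force grid oracle on noisy profiles", {
  set.seed(7)
  coords <- as.matrix(expand.grid(0:5, 0:5, 0:5))
  for (rep in 1:6) {
    truth <- runif(3, 1, 4)
    sg <- runif(1, 1, 3)
    z <- gaussian_weights(coords, truth, sg)
    z <- z / sd(z) + rnorm(nrow(coords), sd = 0.35)
    fit <- confield:::fit_connective_field(z, coords)
    oracle <- grid_fit_oracle(z, coords)
    expect_lte(max(abs(c(fit$x0, fit$y0, fit$z0) - oracle$center)), 1 + 1e-6)
    expect_lte(abs(fit$sigma - oracle$sigma), 0.25 + 1e-6)
    expect_lte(fit$objective, oracle$objective + 1e-8)
  }
})

test_that("fitted maps are translation-equivariant and respect bounds", {
  ph <- small_phantom(seed_rng = 21, n_t = 120, seed_shape = c(4, 4, 4),
                      map_shape = c(6, 6, 6))
  fit <- cf_fit(ph$seed, ph$mapping)
  expect_true(all(fit$fields$x0 >= 0 & fit$fields$x0 <= 5))
  expect_true(all(fit$fields$sigma > 0 & fit$fields$sigma <= 5))
  expect_equal((1 - fit$fields$objective)^2, fit$fields$fit_r2,
               tolerance = 1e-12)

  # translate both masks by an integer offset: centers shift, sigma fixed
  shift <- c(2L, 1L, 3L)
  shift_ts <- function(ts, off, pad) {
    grid <- vol_grid(ts$mask$grid$shape + pad)
    m <- array(0L, grid$shape)
    ijk <- sweep(ts$mask$voxel_indices, 2, off, "+")
    m[ijk + 1L] <- 1L
    structure(list(mask = region_mask(m, grid, ts$mask$label),
                   data = ts$data, demeaned = ts$demeaned),
              class = "region_ts")
  }
  fit2 <- cf_fit(shift_ts(ph$seed, shift, c(4L, 4L, 4L)),
                 shift_ts(ph$mapping, shift, c(4L, 4L, 4L)))
  expect_equal(fit2$fields$x0, fit$fields$x0 + shift[1], tolerance = 1e-3)
  expect_equal(fit2$fields$z0, fit$fields$z0 + shift[3], tolerance = 1e-3)
  expect_equal(fit2$fields$sigma, fit$fields$sigma, tolerance = 1e-3)
})

test_that("predictions reduce to closed forms in degenerate activations", {
  ph <- small_phantom(seed_rng = 5, n_t = 60, seed_shape = c(4, 4, 4),
                      map_shape = c(6, 6, 6))
  fit <- cf_fit(ph$seed, ph$mapping)
  # spatially uniform activity c(t): prediction proportional to c(t)
  ct <- rnorm(60)
  uni <- ph$mapping
  uni$data <- matrix(ct, nrow(uni$data), 60, byrow = TRUE)
  p <- predict(fit, uni)
  expect_equal(abs(cor(p[1, ], ct)), 1, tolerance = 1e-10)
  # delta activity at one voxel: prediction proportional to that series
  del <- ph$mapping
  del$data <- matrix(0, nrow(del$data), 60)
  del$data[10, ] <- rnorm(60)
  p2 <- predict(fit, del)
  expect_equal(abs(cor(p2[3, ], del$data[10, ])), 1, tolerance = 1e-10)
  # all predictions are z-scored
  p3 <- predict(fit, ph$mapping)
  expect_lt(max(abs(rowMeans(p3))), 1e-8)
  expect_equal(apply(p3, 1, sd), rep(1, nrow(p3)), tolerance = 1e-8)
})

test_that("matched predictions beat mismatched ones on phantoms", {
  ph <- small_phantom(seed_rng = 9, n_t = 150)
  fit <- cf_fit(ph$seed, ph$mapping)
  ev <- evaluate_fit(fit, ph$seed, ph$mapping)
  n <- sum(!fit$fields$degenerate)
  expect_length(ev$matched, n)
  expect_length(ev$mismatched, n * (n - 1))
  expect_gt(ev$summary$mean_matched, ev$summary$mean_mismatched)
  expect_lt(ev$summary$p_value, 0.01)

  # single seed voxel: mismatched set empty
  one <- ph$seed
  one$mask$voxel_indices <- one$mask$voxel_indices[1, , drop = FALSE]
  one$data <- one$data[1, , drop = FALSE]
  fit1 <- fit
  fit1$fields <- fit1$fields[1, , drop = FALSE]
  fit1$seed_mask <- one$mask
  expect_error(evaluate_fit(fit1, one, ph$mapping, demean = FALSE),
               ">= 2")

  # identical fields for every seed: matched and mismatched coincide
  same <- fit
  same$fields[, c("x0", "y0", "z0", "sigma")] <-
    same$fields[rep(1, nrow(same$fields)), c("x0", "y0", "z0", "sigma")]
  ev2 <- evaluate_fit(same, ph$seed, ph$mapping)
  expect_equal(mean(ev2$matched), mean(ev2$mismatched), tolerance = 0.05)
})
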