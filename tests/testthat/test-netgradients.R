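make_parcel_phantom <- function(seed_rng = 1, n_t = 150, snr = 8) {
  # three parcels in one volume; planted topography parcel 1 <-> parcel 2,
  # parcel 3 carries independent noise
  set.seed(seed_rng)
  shape <- c(14, 5, 5)
  parc <- array(0L, shape)
  parc[1:4, 1:4, 1:4] <- 1L
  parc[6:9, 1:4, 1:4] <- 2L
  parc[11:14, 1:4, 1:4] <- 3L
  grid <- vol_grid(shape)
  n_vox <- 64L
  src <- matrix(rnorm(n_vox * n_t), n_vox, n_t)   # parcel 2 sources
  coords2 <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  data4d <- array(rnorm(prod(shape) * n_t, sd = 1), c(shape, n_t))
  flat <- matrix(data4d, prod(shape), n_t)
  idx <- function(lab) which(as.vector(parc) == lab)
  flat[idx(2), ] <- src
  # parcel 1: identity-mapped Gaussian mixtures of parcel 2 + noise
  w <- sapply(seq_len(n_vox), function(v) {
    gaussian_weights(coords2, coords2[v, ], 1.5)
  })
  sig <- t(w) %*% src
  sig <- sig / apply(sig, 1, sd)
  flat[idx(1), ] <- sig + matrix(rnorm(n_vox * n_t, sd = sqrt(1 / snr)),
                                 n_vox, n_t)
  list(data4d = array(flat, c(shape, n_t)), grid = grid, parc = parc)
}

test_that("pairwise linearity finds planted topography between parcels", {
  pp <- make_parcel_phantom()
  lm <- pairwise_linearity(pp$data4d, pp$grid, pp$parc)
  expect_equal(dim(lm$values), c(3, 3))
  expect_true(all(is.na(diag(lm$values))))
  # planted pair beats the null threshold in both directions; pairs with
  # the noise parcel do not
  expect_lt(lm$p_values[1, 2], 1e-6)
  expect_lt(lm$p_values[2, 1], 1e-6)
  expect_gt(lm$p_values[1, 3], 1e-3)
  expect_gt(lm$p_values[3, 1], 1e-3)
  expect_gt(lm$values[1, 2], lm$values[1, 3])
  expect_false(any(lm$low_resel[!is.na(lm$low_resel)]))

  # subset argument controls the matrix size
  lm2 <- pairwise_linearity(pp$data4d, pp$grid, pp$parc, subset = c(1, 2))
  expect_equal(dim(lm2$values), c(2, 2))

  # a parcel below the voxel precondition is recorded, not silently dropped
  parc_bad <- pp$parc
  parc_bad[parc_bad == 3L] <- 0L
  parc_bad[11, 1, 1] <- 3L; parc_bad[11, 2, 1] <- 3L; parc_bad[11, 1, 2] <- 3L
  lm3 <- pairwise_linearity(pp$data4d, pp$grid, parc_bad)
  expect_true(all(is.na(lm3$values[3, ])))
  expect_true(any(grepl("parcel 3", attr(lm3, "errors"))))
})

test_that("pairwise linearity permutes consistently with parcel relabeling", {
  pp <- make_parcel_phantom(seed_rng = 3)
  lm <- pairwise_linearity(pp$data4d, pp$grid, pp$parc)
  relab <- pp$parc
  relab[pp$parc == 1L] <- 2L
  relab[pp$parc == 2L] <- 1L
  lm2 <- pairwise_linearity(pp$data4d, pp$grid, relab)
  perm <- c(2, 1, 3)
  expect_equal(lm2$values, lm$values[perm, perm], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("network contrast recovers a planted within-network excess", {
  labels <- data.frame(parcel_id = 1:20,
                       network = rep(c("A", "B"), each = 10))
  lms <- lapply(1:10, function(s)
    generate_block_linearity_matrix(20, networks = labels$network,
                                    within = 0.4, between = 0.05,
                                    noise_sd = 0.02, seed = 100 + s))
  nc <- network_contrast(lms, labels, c("A", "B"))
  expect_equal(nrow(nc), 2)
  expect_true(all(nc$t > 0))
  expect_true(all(nc$p_value < 0.01))
  expect_true(all(nc$mean_within > nc$mean_between))

  # within == between gives t = 0
  flat <- lapply(1:5, function(s) {
    m <- matrix(0.3, 20, 20); diag(m) <- NA
    linearity_matrix(m)
  })
  nc0 <- network_contrast(flat, labels, "A")
  expect_equal(nc0$t, 0, tolerance = 1e-10)

  # single subject: means returned, test skipped with a notice
  expect_message(nc1 <- network_contrast(lms[[1]], labels, "A"), "skipped")
  expect_true(is.na(nc1$t))
  expect_false(is.na(nc1$mean_within))
  expect_error(network_contrast(lms, labels, "C"), "not present")
})

test_that("topography graphs threshold edges and attach degrees/layout", {
  m <- matrix(0.05, 4, 4); diag(m) <- NA
  m[1, 2] <- 0.5; m[2, 1] <- 0.10  # either direction suffices
  g <- topography_graph(linearity_matrix(m), threshold = 0.20)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(g$nodes$degree, c(1, 1, 0, 0))
  expect_equal(g$edges$weight, 0.5)

  full <- matrix(0.9, 5, 5); diag(full) <- NA
  g2 <- topography_graph(linearity_matrix(full), threshold = 0.20)
  expect_equal(nrow(g2$edges), choose(5, 2))
  expect_true(all(g2$nodes$degree == 4))

  expect_warning(g3 <- topography_graph(linearity_matrix(m),
                                        threshold = 0.95), "empty")
  expect_equal(nrow(g3$edges), 0)
  expect_error(topography_graph(linearity_matrix(m), threshold = 1.2),
               "0, 1")
})

test_that("gradient decomposition recovers latent dimensionality and blocks", {
  # matrix generated from exact 2-D latent coordinates: elbow selects 2
  set.seed(5)
  lat <- cbind(runif(30), runif(30))
  D <- as.matrix(dist(lat)); D <- D / max(D) * 0.9
  linmat <- 1 - D; diag(linmat) <- NA
  g <- gradient_decomposition(linmat, max_modes = 5)
  expect_equal(g$n_modes, 2L)
  expect_true(all(abs(colMeans(g$scores)) < 1e-8))
  expect_true(all(diff(g$fit_curve) > -0.01))

  # planted two-block matrix: mode 1 separates the blocks by sign
  bm <- generate_block_linearity_matrix(20, within = 0.4, between = 0.05,
                                        noise_sd = 0.02, seed = 2)
  nets <- attr(bm, "networks")
  g2 <- gradient_decomposition(bm, max_modes = 4)
  s1 <- g2$scores[, 1]
  expect_true(prod(mean(s1[nets == "A"]), mean(s1[nets == "B"])) < 0)
  expect_true(all(s1[nets == "A"] * mean(s1[nets == "A"]) > 0))

  # invariant to parcel ordering up to sign/rotation of the embedding
  # (checked on the latent-coordinate matrix, whose embedding is unique
  # up to a rigid motion)
  perm <- sample(30)
  g4 <- gradient_decomposition(linmat[perm, perm], max_modes = 5,
                               n_modes = g$n_modes)
  dref <- as.matrix(dist(g$scores))[perm, perm]
  dperm <- as.matrix(dist(g4$scores))
  expect_gt(cor(as.vector(dref), as.vector(dperm), method = "spearman"),
            0.99)

  # degenerate inputs
  eq <- matrix(0.5, 6, 6); diag(eq) <- NA
  expect_error(gradient_decomposition(eq), "degenerate")
  nf <- linmat; nf[2, 3] <- NA; nf[3, 2] <- NA
  expect_error(gradient_decomposition(nf), "2-3")
})

test_that("task-map regression reports standardized OLS like Table-1 output", {
  set.seed(9)
  n <- 30
  G <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("g1", "g2")))
  conv <- rnorm(n)
  y <- 0.55 * scale(G[, 2])[, 1] + rnorm(n, sd = sqrt(1 - 0.55^2))
  fit <- task_map_regression(G, y, convergence = conv)
  co <- fit$coefficients
  b2 <- co[co$term == "g2", ]
  expect_lt(abs(b2$beta - 0.55), qt(0.975, n - 4) * b2$se)
  expect_equal(co$beta[co$term == "(Intercept)"], 0, tolerance = 1e-10)
  expect_gt(fit$r_squared, 0.1)

  # collinear design is refused with the offending column named
  expect_error(task_map_regression(cbind(G, g3 = G[, 1]), y), "g3")
  expect_error(task_map_regression(G, y[1:10]), "length")
})
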