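# Orthogonal Procrustes alignment (translation + rotation + global scale,
# no reflection) of Y onto X; returns the complement of the normalized SSE.
# With both point sets rank-transformed this is the rank linearity statistic.
procrustes_linearity <- function(X, Y, allow_reflection = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  nx <- sqrt(sum(Xc^2)); ny <- sqrt(sum(Yc^2))
  if (nx == 0) stop("target configuration has zero spread")
  if (ny == 0) {
    warning("all source points identical; scale degenerate, linearity 0")
    return(0)
  }
  s <- svd(crossprod(Xc / nx, Yc / ny))
  tr <- if (allow_reflection) sum(s$d)
  else sum(s$d[-length(s$d)]) + sign(det(s$u %*% t(s$v))) * s$d[length(s$d)]
  # linearity = 1 - d where d = 1 - tr^2 is the normalized Procrustes SSE
  max(0, tr)^2
}

rank_columns <- function(M) apply(as.matrix(M), 2L, rank)

#' Rank linearity: Procrustes topography score
#'
#' Quantifies how topographically a connective field map projects one
#' region onto another. The three fitted center coordinates and the three
#' seed voxel coordinates are each rank-transformed (average ranks for
#' ties), the ranked centers are aligned to the ranked seed locations by
#' the best similarity transform (translation, rotation, global scale), and
#' linearity is the complement of the normalized Procrustes SSE, in [0, 1].
#' 1 means a perfectly preserved (possibly rotated/scaled) rank ordering.
#'
#' Inference uses the smoothness-corrected chance level `1 / (V / fwhm^3)`
#' (the inverse of the number of resels) on a binomial with `V` trials; see
#' [linearity_null()]. When the region has 10 or fewer resels the binomial
#' null is unreliable and the result carries `low_resel_flag`.
#'
#' @param x a `cfmap` (from [cf_fit()]), or a numeric matrix of fitted
#'   centers for the default method.
#' @param fwhm estimated spatial smoothness of the seed region in voxels
#'   (>= 1). Use [estimate_fwhm()] on the seed time series, or leave at 1
#'   for unsmoothed data.
#' @param ... passed to methods.
#' @return An object of class `cf_linearity`: `linearity`, `n_voxels`,
#'   `fwhm`, `resels`, `expected`, `threshold`, `p_value`, `significant`,
#'   `low_resel_flag`.
#' @export
rank_linearity <- function(x, ...) UseMethod("rank_linearity")

#' @rdname rank_linearity
#' @export
rank_linearity.cfmap <- function(x, fwhm = 1, ...) {
  ok <- !x$fields$degenerate
  centers <- as.matrix(x$fields[ok, c("x0", "y0", "z0")])
  seeds <- region_coords(x$seed_mask, x$coord_space)[ok, , drop = FALSE]
  rank_linearity.default(centers, seeds, fwhm = fwhm, ...)
}

#' @rdname rank_linearity
#' @param seed_coords n x 3 matrix of seed voxel coordinates (default
#'   method only).
#' @param alpha significance level for the binomial test.
#' @export
rank_linearity.default <- function(x, seed_coords, fwhm = 1, alpha = 0.05,
                                   ...) {
  centers <- as.matrix(x)
  seed_coords <- as.matrix(seed_coords)
  if (nrow(centers) != nrow(seed_coords))
    stop("'x' and 'seed_coords' must have the same number of rows")
  if (nrow(centers) < 4L)
    stop("rank linearity needs >= 4 non-degenerate seed fields")
  lin <- procrustes_linearity(rank_columns(seed_coords),
                              rank_columns(centers))
  null <- linearity_null(nrow(centers), fwhm)
  structure(list(
    linearity = lin, n_voxels = nrow(centers), fwhm = fwhm,
    resels = null$resels, expected = null$expected,
    threshold = null$threshold, p_value = null$p_value(lin),
    significant = null$p_value(lin) < alpha,
    low_resel_flag = null$low_resel_flag), class = "cf_linearity")
}

#' @export
print.cf_linearity <- function(x, ...) {
  cat(sprintf("Rank linearity: %.2f%% (chance %.2f%% at FWHM %.2f, %d voxels, %.1f resels)\n",
              100 * x$linearity, 100 * x$expected, x$fwhm, x$n_voxels,
              x$resels))
  cat(sprintf("  binomial p = %.3g%s%s\n", x$p_value,
              if (x$significant) " (significant at 0.05)" else "",
              if (x$low_resel_flag) " [FLAG: <= 10 resels, null unreliable]"
              else ""))
  invisible(x)
}

#' Binomial null model for rank linearity
#'
#' Under no topographic organization, the probability that a voxel's data
#' rank matches its spatial rank is `1/V`, so the expected rank linearity
#' of a volume of `V` voxels is `1/V`; spatial smoothness reduces the
#' number of independent observations to the resel count `V / fwhm^3`, and
#' the smoothness-corrected expectation is `1 / (V / fwhm^3)` (capped at 1).
#' Inference treats `round(L * V)` as a binomial count with `V` trials and
#' success probability equal to the expectation.
#'
#' @param V number of seed voxels (>= 2).
#' @param fwhm spatial smoothness in voxels (>= 1).
#' @return A list: `expected`, `resels`, `threshold` (upper bound of the
#'   central binomial 95% interval as a proportion), `p_value` (function of
#'   an observed linearity, upper-tail binomial probability at count
#'   `round(L*V)`), and `low_resel_flag` (`TRUE` when resels <= 10).
#' @export
linearity_null <- function(V, fwhm) {
  if (!is.numeric(V) || V < 2) stop("'V' must be >= 2")
  if (!is.numeric(fwhm) || fwhm < 1) stop("'fwhm' must be >= 1")
  resels <- V / fwhm^3
  expected <- min(1, 1 / resels)
  list(
    expected = expected,
    resels = resels,
    threshold = stats::qbinom(0.975, V, expected) / V,
    p_value = function(L)
      stats::pbinom(round(L * V) - 1, V, expected, lower.tail = FALSE),
    low_resel_flag = resels <= 10)
}

#' Estimate spatial smoothness (FWHM) of a region's data
#'
#' Random-field-theory style estimator: each volume (timepoint) is
#' standardized, spatial first differences are taken along each axis over
#' in-mask neighbor pairs, and the per-axis FWHM is
#' `sqrt(4 * log(2) / var(diff))`; the returned value is the geometric mean
#' across usable axes. Independent white noise yields about 1.18 voxels
#' (the intrinsic lattice smoothness); Gaussian-smoothed noise recovers the
#' kernel width to within a few percent.
#'
#' @param x a [region_ts] (>= 10 timepoints), or a 3-D array for the
#'   default method (a single volume on a full grid).
#' @param ... passed to methods.
#' @return positive FWHM in voxels.
#' @export
estimate_fwhm <- function(x, ...) UseMethod("estimate_fwhm")

#' @rdname estimate_fwhm
#' @export
estimate_fwhm.region_ts <- function(x, ...) {
  if (ncol(x$data) < 10L)
    stop("FWHM estimation needs >= 10 timepoints")
  ijk <- x$mask$voxel_indices
  key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
  row_of <- seq_len(nrow(ijk))
  names(row_of) <- key(ijk)
  dat <- x$data
  sds <- apply(dat, 2L, stats::sd)
  if (all(!is.finite(sds) | sds == 0))
    stop("constant image: spatial variance undefined")
  use <- which(is.finite(sds) & sds > 0)
  std <- sweep(sweep(dat[, use, drop = FALSE], 2L,
                     colMeans(dat[, use, drop = FALSE]), "-"),
               2L, sds[use], "/")
  fwhms <- rep(NA_real_, 3L)
  for (ax in 1:3) {
    nb <- ijk
    nb[, ax] <- nb[, ax] + 1L
    j <- row_of[key(nb)]
    has <- !is.na(j)
    if (sum(has) < nrow(ijk) / 4 || sum(has) < 2L) next
    d <- std[which(has), , drop = FALSE] - std[j[has], , drop = FALSE]
    v <- mean(d^2, na.rm = TRUE)
    if (is.finite(v) && v > 0) fwhms[ax] <- sqrt(4 * log(2) / v)
  }
  if (all(is.na(fwhms)))
    stop("mask too thin along every axis; cannot estimate FWHM")
  if (any(is.na(fwhms)))
    warning("axis with too few neighbor pairs excluded from FWHM estimate")
  exp(mean(log(fwhms), na.rm = TRUE))
}

#' @rdname estimate_fwhm
#' @export
estimate_fwhm.default <- function(x, ...) {
  a <- as.array(x)
  if (length(dim(a)) != 3L) stop("expected a 3-D array or a region_ts")
  if (any(dim(a) < 2L)) stop("each axis needs >= 2 voxels")
  s <- stats::sd(a)
  if (!is.finite(s) || s == 0) stop("constant image: variance undefined")
  a <- (a - mean(a)) / s
  f <- numeric(3L)
  d <- dim(a)
  f[1] <- sqrt(4 * log(2) / mean((a[-1, , ] - a[-d[1], , ])^2))
  f[2] <- sqrt(4 * log(2) / mean((a[, -1, ] - a[, -d[2], ])^2))
  f[3] <- sqrt(4 * log(2) / mean((a[, , -1] - a[, , -d[3]])^2))
  exp(mean(log(f)))
}

#' 3-D Kolmogorov-Smirnov deviance from a reference voxel set
#'
#' Peacock-style multidimensional KS statistic: the maximum, over the eight
#' orthant orderings and all sample anchor points, of the absolute
#' difference between the empirical cumulative fraction of the sample and
#' that of the reference point set. Used by [convergence()] with the
#' mapping region's voxels as the reference.
#'
#' @param points n x 3 matrix of sample points (fitted centers).
#' @param ref m x 3 matrix of reference points (the uniform model).
#' @return the KS deviance (non-negative scalar).
#' @export
ks3d_deviance <- function(points, ref) ks3d_stat(points, ref)

ks3d_stat <- function(points, ref) {
  points <- as.matrix(points); ref <- as.matrix(ref)
  n <- nrow(points)
  cmp <- function(A, anchors, ge) {
    # result[i, j]: does A[j, ax] fall on the anchor i's side, per axis
    out <- NULL
    for (ax in 1:3) {
      m <- if (ge[ax]) outer(anchors[, ax], A[, ax], `<=`)
      else outer(anchors[, ax], A[, ax], `>=`)
      out <- if (is.null(out)) m else out & m
    }
    out
  }
  dmax <- 0
  for (b in 0:7) {
    ge <- c(bitwAnd(b, 1L) > 0, bitwAnd(b, 2L) > 0, bitwAnd(b, 4L) > 0)
    fe <- rowMeans(cmp(points, points, ge))
    fr <- rowMeans(cmp(ref, points, ge))
    dmax <- max(dmax, max(abs(fe - fr)))
  }
  dmax
}

#' Convergence of a connective field map
#'
#' Measures how strongly the fitted field centers pile up, as the deviance
#' of the centers from a uniform distribution over the mapping region's
#' voxels, using a 3-D generalization of the Kolmogorov-Smirnov statistic
#' (maximum empirical-minus-reference cumulative difference over the eight
#' orthant orderings, anchored at the sample points). To make values
#' comparable across regions of different size and shape, the statistic is
#' divided by its Monte Carlo critical value at the 5% alpha level
#' (the 95th percentile over `n_null` equal-size uniform draws from the
#' mapping voxels), so `corrected > 1` exactly when the deviance exceeds
#' its 5% critical value.
#'
#' @param cfm a `cfmap` with >= 4 non-degenerate fields.
#' @param n_null number of null draws for the critical value (>= 199).
#' @param seed optional RNG seed for the null draws.
#' @return An object of class `cf_convergence`: `ks_stat`,
#'   `ks_critical_05`, `corrected`, `n`.
#' @export
convergence <- function(cfm, n_null = 499, seed = NULL) {
  stopifnot(inherits(cfm, "cfmap"))
  if (n_null < 199) stop("'n_null' must be >= 199")
  ok <- !cfm$fields$degenerate
  centers <- as.matrix(cfm$fields[ok, c("x0", "y0", "z0")])
  if (nrow(centers) < 4L)
    stop("convergence needs >= 4 non-degenerate fields")
  ref <- region_coords(cfm$map_mask, cfm$coord_space)
  if (nrow(ref) < nrow(centers))
    stop("mapping region smaller than the sample of fitted centers")
  ks <- ks3d_stat(centers, ref)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(centers)
  null_stats <- vapply(seq_len(n_null), function(i)
    ks3d_stat(ref[sample.int(nrow(ref), n, replace = TRUE), , drop = FALSE],
              ref), numeric(1))
  crit <- unname(stats::quantile(null_stats, 0.95))
  structure(list(ks_stat = ks, ks_critical_05 = crit,
                 corrected = ks / crit, n = n),
            class = "cf_convergence")
}

#' @export
print.cf_convergence <- function(x, ...) {
  cat(sprintf("Convergence: KS = %.3f, 5%% critical = %.3f, corrected = %.2f%s\n",
              x$ks_stat, x$ks_critical_05, x$corrected,
              if (x$corrected > 1) " (significantly convergent)" else ""))
  invisible(x)
}

#' Vector field of preferred connectivity locations
#'
#' For each non-degenerate seed voxel, the vector from the mapping region's
#' center of mass to the fitted center `(x0, y0, z0)`; drawn at the seed
#' voxel's location, these vectors visualize the spatial organization of
#' the connectivity between the two regions.
#'
#' @param cfm a `cfmap` with >= 1 non-degenerate field.
#' @return A data.frame of class `cf_vectorfield`: seed origins
#'   (`i, j, k`), vector components (`vx, vy, vz`) and Euclidean `norm`.
#' @export
vector_field <- function(cfm) {
  stopifnot(inherits(cfm, "cfmap"))
  ok <- !cfm$fields$degenerate
  if (!any(ok)) stop("no non-degenerate fields")
  f <- cfm$fields[ok, , drop = FALSE]
  centroid <- colMeans(region_coords(cfm$map_mask, cfm$coord_space))
  v <- cbind(vx = f$x0 - centroid[1L], vy = f$y0 - centroid[2L],
             vz = f$z0 - centroid[3L])
  out <- data.frame(f[c("i", "j", "k")], v, norm = sqrt(rowSums(v^2)))
  class(out) <- c("cf_vectorfield", "data.frame")
  out
}

#' @export
plot.cf_vectorfield <- function(x, axes = c(1, 2), scale = 0.3, ...) {
  org <- as.matrix(x[, c("i", "j", "k")[axes], drop = FALSE])
  vec <- as.matrix(x[, c("vx", "vy", "vz")[axes], drop = FALSE])
  cols <- grDevices::hcl.colors(64, "viridis")
  ci <- cut(x$norm, 64, labels = FALSE)
  graphics::plot(org[, 1], org[, 2], pch = 16, cex = 0.4,
                 xlab = c("x", "y", "z")[axes[1]],
                 ylab = c("x", "y", "z")[axes[2]], asp = 1, ...)
  nz <- x$norm > 0
  graphics::arrows(org[nz, 1], org[nz, 2],
                   org[nz, 1] + scale * vec[nz, 1],
                   org[nz, 2] + scale * vec[nz, 2],
                   length = 0.04, col = cols[ci[nz]])
  invisible(x)
}

#' Monte Carlo null calibration for rank linearity
#'
#' Emulates a connective field map with no topographic structure on a full
#' box region: three independent random volumes (optionally spatially
#' smoothed) supply the pseudo fitted-center coordinates, and the rank
#' linearity against the voxel coordinates is computed for each replicate.
#' With `fwhm <= 1` the pseudo-parameter volumes are plain white noise and
#' the replicate is equivalent to assigning centers to seed voxels by
#' independent random permutation of each coordinate's ranks.
#'
#' @param shape region shape (3 integers).
#' @param fwhm target field smoothness in voxels; values above 1 apply a
#'   Gaussian smoothing kernel of that FWHM.
#' @param n_rep number of replicates.
#' @param seed optional RNG seed.
#' @param estimate also estimate each replicate's realized smoothness with
#'   [estimate_fwhm()] (returned as attribute `"fwhm_est"`).
#' @return numeric vector of `n_rep` linearity values.
#' @export
linearity_null_simulation <- function(shape, fwhm = 1, n_rep = 1000,
                                      seed = NULL, estimate = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  shape <- as.integer(shape)
  coords <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2]),
                                  seq_len(shape[3])))
  Xr <- rank_columns(coords)
  kern_fwhm <- if (fwhm > 1) fwhm else 0
  fest <- if (estimate) numeric(n_rep) else NULL
  lin <- vapply(seq_len(n_rep), function(r) {
    vols <- lapply(1:3, function(j)
      generate_random_volume(shape, smooth_fwhm = kern_fwhm))
    if (estimate)
      fest[r] <<- exp(mean(log(vapply(vols, estimate_fwhm, numeric(1)))))
    Y <- vapply(vols, as.vector, numeric(prod(shape)))
    procrustes_linearity(Xr, rank_columns(Y))
  }, numeric(1))
  if (estimate) attr(lin, "fwhm_est") <- fest
  lin
}

#' Write per-pair topography metrics to TSV
#'
#' @param metrics data.frame of per-pair metrics (as produced by the
#'   pipeline: seed_label, map_label, linearity, expected, p_value, resels,
#'   low_resel_flag, and optionally KS columns).
#' @param path output TSV path.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
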