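#' Fisher z connectivity profiles
#'
#' Correlates every seed voxel's time course with every mapping voxel's time
#' course and applies the variance-stabilizing Fisher z transform
#' (`atanh(r)`). Correlations are Pearson, pairwise-complete over frames, so
#' censored (NaN) frames are dropped per voxel pair. `|r|` is clamped at
#' `1 - 1e-7` before the transform so perfectly correlated pairs stay finite.
#'
#' @param seed,mapping [region_ts] objects with a common number of
#'   timepoints (at least 3 shared non-missing frames per pair).
#' @return An `n_seed x n_map` matrix of Fisher z values, with the mapping
#'   voxel coordinates attached as attribute `"map_coords"`.
#' @export
fisher_z_profiles <- function(seed, mapping) {
  stopifnot(inherits(seed, "region_ts"), inherits(mapping, "region_ts"))
  if (ncol(seed$data) != ncol(mapping$data))
    stop("seed and mapping regions have different numbers of timepoints")
  ok <- colSums(is.na(seed$data)) == 0 & colSums(is.na(mapping$data)) == 0
  if (sum(ok) < 3L)
    stop("fewer than 3 shared timepoints after NaN-frame removal")
  r <- suppressWarnings(stats::cor(t(seed$data), t(mapping$data),
                                   use = "pairwise.complete.obs"))
  bad <- !is.finite(r)
  if (any(bad)) {
    warning(sum(bad), " correlation(s) undefined (zero-variance series); ",
            "set to 0")
    r[bad] <- 0
  }
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  attr(z, "map_coords") <- mapping$mask$voxel_indices
  z
}

#' Isotropic 3-D Gaussian connective field weights
#'
#' Evaluates the connective field density
#' \deqn{g(x,y,z) = \frac{1}{\sigma^3 (2\pi)^{3/2}}
#'   \exp\left(-\frac{(x-x_0)^2+(y-y_0)^2+(z-z_0)^2}{2\sigma^2}\right)}
#' at a set of voxel coordinates. The peak value at the center is
#' `1 / (sigma^3 (2*pi)^(3/2))` and the weights are spherically symmetric
#' about the center.
#'
#' @param coords n x 3 matrix of voxel coordinates.
#' @param center numeric length-3 center `(x0, y0, z0)`.
#' @param sigma positive spread (voxels).
#' @return numeric vector of n strictly positive weights.
#' @export
gaussian_weights <- function(coords, center, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a positive number")
  coords <- as.matrix(coords)
  d2 <- (coords[, 1L] - center[1L])^2 + (coords[, 2L] - center[2L])^2 +
    (coords[, 3L] - center[3L])^2
  exp(-d2 / (2 * sigma^2)) / (sigma^3 * (2 * pi)^1.5)
}

# correlation-distance objective: 1 - Pearson(z, gaussian weights)
cf_objective <- function(par, z, coords) {
  w <- exp(-((coords[, 1L] - par[1L])^2 + (coords[, 2L] - par[2L])^2 +
               (coords[, 3L] - par[3L])^2) / (2 * par[4L]^2))
  s <- stats::sd(w)
  if (!is.finite(s) || s == 0) return(1)
  v <- suppressWarnings(stats::cor(z, w))
  if (!is.finite(v)) return(1)
  1 - v
}

# Fit one seed voxel's connective field to its Fisher z profile.
# Box-constrained local optimization (L-BFGS-B) from the published
# initialization (max-z location, sigma = machine epsilon) plus a coarse
# multi-start over sigma to guard against local minima.
fit_connective_field <- function(z, coords,
                                 sigma_starts = c(0.5, 1, 2, 4),
                                 include_eps_start = TRUE) {
  coords <- as.matrix(coords)
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  rng <- hi - lo
  if (any(rng == 0))
    stop("mapping region is degenerate: an axis has a single distinct ",
         "coordinate")
  sig_hi <- min(rng)
  eps <- .Machine$double.eps
  init_loc <- coords[which.max(z), ]

  if (stats::sd(z) == 0) {
    return(list(x0 = init_loc[1L], y0 = init_loc[2L], z0 = init_loc[3L],
                sigma = eps, objective = NA_real_, fit_r2 = 0,
                degenerate = TRUE))
  }

  starts <- sigma_starts[sigma_starts > eps & sigma_starts <= sig_hi]
  if (include_eps_start) starts <- c(eps, starts)
  if (length(starts) == 0L) starts <- sig_hi / 2

  best <- NULL
  for (s0 in starts) {
    p0 <- c(init_loc, s0)
    f0 <- cf_objective(p0, z, coords)
    res <- tryCatch(
      stats::optim(p0, cf_objective, z = z, coords = coords,
                   method = "L-BFGS-B",
                   lower = c(lo, eps), upper = c(hi, sig_hi),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    cand <- if (!is.null(res) && is.finite(res$value) && res$value <= f0)
      list(par = res$par, value = res$value)
    else list(par = p0, value = f0)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  obj <- best$value
  list(x0 = best$par[1L], y0 = best$par[2L], z0 = best$par[3L],
       sigma = best$par[4L], objective = obj, fit_r2 = (1 - obj)^2,
       degenerate = FALSE)
}

#' Fit 3-D connective fields for every seed voxel
#'
#' The central model fit. Each seed voxel's Fisher z connectivity profile
#' over the mapping region is fitted with an isotropic 3-D Gaussian by
#' minimizing the correlation distance between the z profile and the
#' Gaussian density ([gaussian_weights]), under box constraints: the center
#' is bounded by the mapping region's coordinate extremes and sigma by
#' machine epsilon below and the smallest axis range above. Optimization is
#' initialized at the location of the maximum z value with sigma at machine
#' epsilon, plus a coarse multi-start over `sigma_starts`; the best objective
#' is kept and never exceeds its value at initialization.
#'
#' Because the objective is a correlation distance it is invariant to
#' positive rescaling of the z profile, and fitted centers are equivariant
#' to integer translations of both masks.
#'
#' @param seed,mapping [region_ts] objects sharing a timepoint axis.
#' @param demean remove each region's mean time course first (default TRUE;
#'   skipped for a region already demeaned).
#' @param coord_space `"voxel"` (default) fits in 0-based voxel-index space;
#'   `"world"` converts coordinates through the grid affine first.
#' @param sigma_starts coarse multi-start values for sigma, in voxels.
#' @return An object of class `cfmap`: a list with `fields` (one row per
#'   seed voxel: `i, j, k, x0, y0, z0, sigma, fit_r2, objective,
#'   degenerate`), `seed_mask`, `map_mask`, `coord_space`.
#' @seealso [rank_linearity()], [convergence()], [vector_field()],
#'   [evaluate_fit()], [predict.cfmap()]
#' @export
cf_fit <- function(seed, mapping, demean = TRUE,
                   coord_space = c("voxel", "world"),
                   sigma_starts = c(0.5, 1, 2, 4)) {
  stopifnot(inherits(seed, "region_ts"), inherits(mapping, "region_ts"))
  coord_space <- match.arg(coord_space)
  if (demean) {
    if (!isTRUE(seed$demeaned)) seed <- remove_region_mean(seed)
    if (!isTRUE(mapping$demeaned)) mapping <- remove_region_mean(mapping)
  }
  coords <- region_coords(mapping$mask, coord_space)
  if (nrow(coords) < 8L)
    stop("mapping region must have >= 8 voxels")
  if (any(apply(coords, 2L, function(v) length(unique(v))) < 2L))
    stop("mapping region is degenerate: an axis has a single distinct ",
         "coordinate")
  z <- fisher_z_profiles(seed, mapping)
  fits <- lapply(seq_len(nrow(z)), function(i)
    fit_connective_field(z[i, ], coords, sigma_starts = sigma_starts))
  fields <- cbind(
    as.data.frame(seed$mask$voxel_indices),
    do.call(rbind, lapply(fits, function(f)
      data.frame(x0 = f$x0, y0 = f$y0, z0 = f$z0, sigma = f$sigma,
                 fit_r2 = f$fit_r2, objective = f$objective,
                 degenerate = f$degenerate))))
  rownames(fields) <- NULL
  structure(list(fields = fields, seed_mask = seed$mask,
                 map_mask = mapping$mask, coord_space = coord_space,
                 call = match.call()),
            class = "cfmap")
}

region_coords <- function(mask, coord_space = "voxel") {
  ijk <- mask$voxel_indices
  if (coord_space == "voxel") return(ijk)
  xyz1 <- cbind(ijk, 1) %*% t(mask$grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' @export
print.cfmap <- function(x, ...) {
  f <- x$fields
  cat(sprintf("3-D connective field map: %d seed voxel(s) ('%s') -> %d mapping voxel(s) ('%s')\n",
              nrow(f), x$seed_mask$label, n_voxels(x$map_mask),
              x$map_mask$label))
  ok <- !f$degenerate
  if (any(ok))
    cat(sprintf("  median sigma %.2f voxels, mean fit R^2 %.3f, %d degenerate fit(s)\n",
                stats::median(f$sigma[ok]), mean(f$fit_r2[ok]), sum(!ok)))
  invisible(x)
}

#' @export
summary.cfmap <- function(object, ...) {
  f <- object$fields[!object$fields$degenerate, , drop = FALSE]
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75))
  out <- list(
    n_seed = nrow(object$fields),
    n_map = n_voxels(object$map_mask),
    n_degenerate = sum(object$fields$degenerate),
    center_quartiles = sapply(f[c("x0", "y0", "z0")], qs),
    sigma_quartiles = qs(f$sigma),
    fit_r2_quartiles = qs(f$fit_r2))
  class(out) <- "summary.cfmap"
  out
}

#' @export
print.summary.cfmap <- function(x, ...) {
  cat(sprintf("Connective field map: %d seed voxels (%d degenerate), %d mapping voxels\n",
              x$n_seed, x$n_degenerate, x$n_map))
  cat("sigma quartiles (voxels): ",
      paste(signif(x$sigma_quartiles, 3), collapse = " / "), "\n")
  cat("fit R^2 quartiles:        ",
      paste(signif(x$fit_r2_quartiles, 3), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.cfmap <- function(object, ...) {
  as.matrix(object$fields[c("x0", "y0", "z0", "sigma")])
}

#' Predict seed time series from mapping-region activity
#'
#' For each fitted field the predicted series is the Gaussian-weighted sum
#' of the mapping region's activity at each time point,
#' `p(t) = sum_xyz A(x,y,z,t) g(x,y,z)`, z-scored over valid timepoints.
#'
#' @param object a `cfmap`.
#' @param mapping the mapping-region [region_ts] the fields were fitted on.
#' @param ... unused.
#' @return n_seed x n_timepoints matrix of z-scored predictions. Rows for
#'   degenerate fits or zero-variance predictions are `NA` and flagged in
#'   attribute `"failed"`.
#' @export
predict.cfmap <- function(object, mapping, ...) {
  stopifnot(inherits(mapping, "region_ts"))
  if (!grids_match(object$map_mask$grid, mapping$mask$grid) ||
      !identical(object$map_mask$voxel_indices, mapping$mask$voxel_indices))
    stop("'mapping' does not match the mask the fields were fitted on")
  coords <- region_coords(mapping$mask, object$coord_space)
  f <- object$fields
  pred <- matrix(NA_real_, nrow(f), ncol(mapping$data))
  failed <- f$degenerate
  for (i in which(!f$degenerate)) {
    w <- gaussian_weights(coords, c(f$x0[i], f$y0[i], f$z0[i]), f$sigma[i])
    p <- as.vector(crossprod(mapping$data, w))
    s <- stats::sd(p, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      failed[i] <- TRUE
      next
    }
    pred[i, ] <- (p - mean(p, na.rm = TRUE)) / s
  }
  attr(pred, "failed") <- failed
  pred
}

#' Matched versus mismatched prediction correlations
#'
#' Evaluates model fit the way an encoding model is validated: the
#' distribution of correlations between each seed voxel's predicted and
#' actual time series ("matched") is compared with the correlations between
#' each voxel's actual series and every *other* voxel's prediction
#' ("mismatched"). Degenerate fits are excluded (their count is reported).
#'
#' @param cfm a `cfmap`.
#' @param seed,mapping the [region_ts] pair the map was fitted on. The seed
#'   region is demeaned first when `demean` is TRUE (matching the fit).
#' @param demean apply ROI-mean removal to the seed series before z-scoring.
#' @return An object of class `cf_fiteval` with `matched` (n valid seeds),
#'   `mismatched` (n*(n-1) values), `n_excluded`, and `summary` (means,
#'   quartiles and a one-sided Welch test of matched > mismatched).
#' @export
evaluate_fit <- function(cfm, seed, mapping, demean = TRUE) {
  stopifnot(inherits(cfm, "cfmap"))
  if (demean && !isTRUE(seed$demeaned)) seed <- remove_region_mean(seed)
  pred <- predict(cfm, if (demean && !isTRUE(mapping$demeaned))
    remove_region_mean(mapping) else mapping)
  keep <- !attr(pred, "failed")
  n_excluded <- sum(!keep)
  if (sum(keep) < 2L)
    stop("matched/mismatched evaluation needs >= 2 non-degenerate seed ",
         "voxels (mismatched set would be empty)")
  cc <- suppressWarnings(stats::cor(t(pred[keep, , drop = FALSE]),
                                    t(seed$data[keep, , drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  matched <- diag(cc)
  mismatched <- cc[row(cc) != col(cc)]
  tt <- stats::t.test(matched, mismatched, alternative = "greater")
  out <- list(
    matched = matched, mismatched = mismatched, n_excluded = n_excluded,
    summary = list(
      mean_matched = mean(matched, na.rm = TRUE),
      mean_mismatched = mean(mismatched, na.rm = TRUE),
      q_matched = stats::quantile(matched, c(0.05, 0.5, 0.95), na.rm = TRUE),
      q_mismatched = stats::quantile(mismatched, c(0.05, 0.5, 0.95),
                                     na.rm = TRUE),
      t = unname(tt$statistic), p_value = tt$p.value))
  class(out) <- "cf_fiteval"
  out
}

#' @export
print.cf_fiteval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Prediction validity: mean r matched %.3f vs mismatched %.3f\n",
              s$mean_matched, s$mean_mismatched))
  cat(sprintf("  one-sided Welch test (matched > mismatched): t = %.2f, p = %.3g\n",
              s$t, s$p_value))
  if (x$n_excluded > 0)
    cat(sprintf("  %d degenerate fit(s) excluded\n", x$n_excluded))
  invisible(x)
}

#' Plot a connective field map as a vector field
#'
#' Draws each (non-degenerate) seed voxel's displacement vector from its
#' seed location toward its fitted center relative to the mapping region's
#' center of mass, projected onto two axes.
#'
#' @param x a `cfmap`.
#' @param axes which two coordinate axes to display (default x and y).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cfmap <- function(x, axes = c(1, 2), ...) {
  vf <- vector_field(x)
  plot(vf, axes = axes, ...)
}

#' Serialize fitted fields to TSV
#'
#' @param cfm a `cfmap`.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_fields_tsv <- function(cfm, path) {
  stopifnot(inherits(cfm, "cfmap"))
  utils::write.table(cfm$fields, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
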