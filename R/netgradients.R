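#' Directed parcel-pair linearity matrix container
#'
#' @param values square numeric matrix of directed (seed -> mapping)
#'   linearity values in [0, 1]; the diagonal is `NA`.
#' @param parcel_ids parcel identifiers in matrix order.
#' @param p_values,resels,low_resel optional companion matrices.
#' @param convergence optional matrix of corrected KS values per pair.
#' @return An object of class `linearity_matrix`.
#' @export
linearity_matrix <- function(values, parcel_ids = NULL, p_values = NULL,
                             resels = NULL, low_resel = NULL,
                             convergence = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("'values' must be square")
  off <- values[row(values) != col(values)]
  if (any(off < -1e-9 | off > 1 + 1e-9, na.rm = TRUE))
    stop("off-diagonal linearity values must lie in [0, 1]")
  if (is.null(parcel_ids)) parcel_ids <- seq_len(nrow(values))
  dimnames(values) <- list(parcel_ids, parcel_ids)
  structure(list(values = values, parcel_ids = parcel_ids,
                 p_values = p_values, resels = resels,
                 low_resel = low_resel, convergence = convergence),
            class = "linearity_matrix")
}

#' @export
print.linearity_matrix <- function(x, ...) {
  off <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("<linearity_matrix> %d parcels; off-diagonal linearity median %.3f (range %.3f-%.3f)\n",
              length(x$parcel_ids), stats::median(off, na.rm = TRUE),
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

symmetrized_values <- function(lm) {
  v <- lm$values
  (v + t(v)) / 2
}

#' All-pairs parcel linearity
#'
#' Runs connective field fitting and rank linearity for every ordered pair
#' of parcels in a labeled parcellation volume. The matrix is directed:
#' `[i, j]` fits parcel `i` as seed and parcel `j` as mapping region.
#' Parcels that fail a precondition (too few voxels, a degenerate axis)
#' keep `NA` entries and are listed in the `errors` attribute rather than
#' dropped silently; pairs with 10 or fewer resels are flagged.
#'
#' @param data4d 4-D data array.
#' @param grid its [vol_grid].
#' @param parcellation 3-D integer-labeled array (0 = background).
#' @param subset optional vector of parcel ids to analyze.
#' @param fwhm smoothness passed to [rank_linearity()]; `"estimate"`
#'   estimates it per seed parcel with [estimate_fwhm()].
#' @param demean apply ROI-mean removal (default TRUE).
#' @param compute_convergence also compute the corrected KS per pair
#'   (slower; default FALSE).
#' @param n_null null draws for the convergence critical value.
#' @param ... passed to [cf_fit()].
#' @return A [linearity_matrix] with `p_values`, `resels`, `low_resel`
#'   (and `convergence` if requested) filled in.
#' @export
pairwise_linearity <- function(data4d, grid, parcellation, subset = NULL,
                               fwhm = 1, demean = TRUE,
                               compute_convergence = FALSE, n_null = 499,
                               ...) {
  labs <- sort(unique(as.vector(parcellation)))
  labs <- labs[labs != 0 & !is.na(labs)]
  if (!is.null(subset)) {
    missing <- setdiff(subset, labs)
    if (length(missing))
      stop("parcel id(s) not in parcellation: ",
           paste(missing, collapse = ", "))
    labs <- labs[labs %in% subset]
  }
  k <- length(labs)
  if (k < 2L) stop("need >= 2 parcels")

  regions <- vector("list", k)
  errors <- character(0)
  for (a in seq_len(k)) {
    reg <- tryCatch({
      m <- region_mask(parcellation == labs[a], grid,
                       label = as.character(labs[a]))
      if (n_voxels(m) < 4L) stop("parcel has fewer than 4 voxels")
      ts <- extract_region(data4d, grid, m)
      if (demean) ts <- remove_region_mean(ts)
      ts
    }, error = function(e) {
      errors <<- c(errors, sprintf("parcel %s: %s", labs[a],
                                   conditionMessage(e)))
      NULL
    })
    regions[a] <- list(reg)
  }

  mk <- function() matrix(NA_real_, k, k, dimnames = list(labs, labs))
  vals <- mk(); pvs <- mk(); res <- mk(); conv <- mk()
  lowr <- matrix(NA, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k)) {
    if (is.null(regions[[a]])) next
    fw <- if (identical(fwhm, "estimate"))
      max(1, estimate_fwhm(regions[[a]])) else fwhm
    for (b in seq_len(k)) {
      if (a == b || is.null(regions[[b]])) next
      fit <- tryCatch(cf_fit(regions[[a]], regions[[b]], demean = FALSE,
                             ...),
                      error = function(e) {
                        errors <<- c(errors,
                                     sprintf("pair %s->%s: %s", labs[a],
                                             labs[b], conditionMessage(e)))
                        NULL
                      })
      if (is.null(fit)) next
      lin <- tryCatch(rank_linearity(fit, fwhm = fw),
                      error = function(e) NULL)
      if (is.null(lin)) next
      vals[a, b] <- lin$linearity
      pvs[a, b] <- lin$p_value
      res[a, b] <- lin$resels
      lowr[a, b] <- lin$low_resel_flag
      if (compute_convergence)
        conv[a, b] <- tryCatch(
          convergence(fit, n_null = n_null)$corrected,
          error = function(e) NA_real_)
    }
  }
  out <- linearity_matrix(vals, parcel_ids = labs, p_values = pvs,
                          resels = res, low_resel = lowr,
                          convergence = if (compute_convergence) conv)
  attr(out, "errors") <- errors
  out
}

#' Within- versus between-network linearity
#'
#' For each subject and each requested network, the mean off-diagonal
#' linearity among parcels of that network ("within") and the mean
#' linearity between the network's parcels and all other parcels
#' ("between"), with a paired t test across subjects per network.
#'
#' @param lms a [linearity_matrix] or a list of them (one per subject).
#' @param labels data.frame with columns `parcel_id` and `network` (see
#'   [read_network_table()]).
#' @param networks character vector of network names to test (each must
#'   have >= 2 parcels).
#' @return data.frame of class `cf_netcontrast`: one row per network with
#'   mean within, mean between, and (if more than one subject) the paired
#'   t statistic, df and p value.
#' @export
network_contrast <- function(lms, labels, networks) {
  if (inherits(lms, "linearity_matrix")) lms <- list(lms)
  S <- length(lms)
  rows <- lapply(networks, function(net) {
    in_net_ids <- labels$parcel_id[labels$network == net]
    if (length(in_net_ids) == 0L)
      stop("network '", net, "' not present in labels")
    per <- vapply(lms, function(lm) {
      idx <- match(in_net_ids, lm$parcel_ids)
      idx <- idx[!is.na(idx)]
      if (length(idx) < 2L)
        stop("network '", net, "' needs >= 2 parcels in the matrix")
      v <- lm$values
      win <- v[idx, idx]
      w_mean <- mean(win[row(win) != col(win)], na.rm = TRUE)
      b_mean <- mean(c(v[idx, -idx], v[-idx, idx]), na.rm = TRUE)
      c(w_mean, b_mean)
    }, numeric(2))
    within <- per[1, ]; between <- per[2, ]
    if (S > 1L) {
      diffs <- within - between
      if (stats::sd(diffs) < 1e-14) {
        # no variability in the paired differences: no evidence either way
        tt <- list(statistic = 0, parameter = S - 1L,
                   p.value = if (all(abs(diffs) < 1e-14)) 1 else 0)
      } else tt <- stats::t.test(within, between, paired = TRUE)
      data.frame(network = net, n_subjects = S,
                 mean_within = mean(within), mean_between = mean(between),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
    } else {
      message("single subject: paired test skipped for network '", net, "'")
      data.frame(network = net, n_subjects = 1L,
                 mean_within = mean(within), mean_between = mean(between),
                 t = NA_real_, df = NA_real_, p_value = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cf_netcontrast", "data.frame")
  out
}

#' Thresholded topography graph
#'
#' Builds an undirected graph over parcels: an edge is drawn when either
#' directed linearity of a pair exceeds the threshold (default 20%). Node
#' positions come from classical multidimensional scaling of the
#' symmetrized `1 - linearity` distances, and node weight is the degree in
#' the thresholded graph.
#'
#' @param lm a [linearity_matrix].
#' @param threshold edge threshold in (0, 1); default 0.20.
#' @return A list of class `cf_graph`: `nodes` (id, degree, mds_x, mds_y)
#'   and `edges` (source, target, weight = max directed linearity).
#' @export
topography_graph <- function(lm, threshold = 0.20) {
  stopifnot(inherits(lm, "linearity_matrix"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)")
  v <- lm$values
  k <- nrow(v)
  sym <- symmetrized_values(lm)
  strength <- pmax(v, t(v), na.rm = TRUE)
  diag(strength) <- NA
  edges <- which(upper.tri(strength) & strength > threshold, arr.ind = TRUE)
  ed <- data.frame(source = lm$parcel_ids[edges[, 1]],
                   target = lm$parcel_ids[edges[, 2]],
                   weight = strength[edges])
  if (nrow(ed) == 0L)
    warning("no pair exceeds the linearity threshold; empty graph")
  deg <- integer(k)
  for (r in seq_len(nrow(ed))) {
    i <- match(ed$source[r], lm$parcel_ids)
    j <- match(ed$target[r], lm$parcel_ids)
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }
  d <- 1 - sym
  diag(d) <- 0
  xy <- tryCatch(stats::cmdscale(stats::as.dist(d), k = 2),
                 error = function(e) matrix(0, k, 2))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  nodes <- data.frame(id = lm$parcel_ids, degree = deg,
                      mds_x = xy[, 1], mds_y = xy[, 2])
  structure(list(nodes = nodes, edges = ed, threshold = threshold),
            class = "cf_graph")
}

#' @export
print.cf_graph <- function(x, ...) {
  cat(sprintf("<cf_graph> %d nodes, %d edges at linearity threshold %.0f%%\n",
              nrow(x$nodes), nrow(x$edges), 100 * x$threshold))
  invisible(x)
}

#' @export
plot.cf_graph <- function(x, ...) {
  n <- x$nodes
  graphics::plot(n$mds_x, n$mds_y, type = "n", xlab = "MDS 1",
                 ylab = "MDS 2", ...)
  for (r in seq_len(nrow(x$edges))) {
    i <- match(x$edges$source[r], n$id)
    j <- match(x$edges$target[r], n$id)
    graphics::segments(n$mds_x[i], n$mds_y[i], n$mds_x[j], n$mds_y[j],
                       col = "grey70")
  }
  graphics::points(n$mds_x, n$mds_y, pch = 21, bg = "steelblue",
                   cex = 0.8 + 1.5 * n$degree / max(1, max(n$degree)))
  graphics::text(n$mds_x, n$mds_y, n$id, pos = 3, cex = 0.7)
  invisible(x)
}

#' Gradient decomposition of a linearity matrix
#'
#' Embeds parcels in a low-dimensional space by nonmetric multidimensional
#' scaling of the symmetrized `1 - linearity` distances (Kruskal stress
#' minimization with monotone regression, multiple random restarts keeping
#' the best stress). The fit curve is the Spearman correlation between the
#' embedded and observed distances for each candidate mode count; the mode
#' count is selected at the elbow of that curve (the largest drop in its
#' discrete second difference), overridable via `n_modes`.
#'
#' @param lm a [linearity_matrix] (or a bare square matrix) over >= 5
#'   parcels.
#' @param max_modes largest candidate mode count.
#' @param n_restarts random restarts per mode count (>= 1; the classical
#'   metric solution and the previous mode's warm start are always
#'   included).
#' @param seed RNG seed for the restarts.
#' @param n_modes optional manual override of the selected mode count.
#' @return An object of class `cf_gradients`: `scores` (parcels x modes,
#'   zero-mean columns), `n_modes`, `fit_curve`, `stress`, `parcel_ids`.
#' @export
gradient_decomposition <- function(lm, max_modes = 6, n_restarts = 8,
                                   seed = 1, n_modes = NULL) {
  if (inherits(lm, "linearity_matrix")) {
    sym <- symmetrized_values(lm)
    ids <- lm$parcel_ids
  } else {
    sym <- (as.matrix(lm) + t(as.matrix(lm))) / 2
    ids <- seq_len(nrow(sym))
  }
  k <- nrow(sym)
  if (k < 5L) stop("gradient decomposition needs >= 5 parcels")
  d <- 1 - sym
  diag(d) <- 0
  offd <- d[row(d) != col(d)]
  if (any(!is.finite(offd))) {
    bad <- which(!is.finite(d) & row(d) != col(d), arr.ind = TRUE)
    stop("non-finite distances for pairs: ",
         paste(apply(bad, 1, function(r)
           paste0(ids[r[1]], "-", ids[r[2]])), collapse = ", "))
  }
  if (stats::sd(offd) < 1e-12)
    stop("all pairwise distances equal; stress-degenerate configuration")
  d[d <= 0 & row(d) != col(d)] <- 1e-8
  dd <- stats::as.dist(d)
  max_modes <- min(max_modes, k - 1L)
  set.seed(seed)

  fit_curve <- numeric(max_modes)
  stress <- numeric(max_modes)
  sols <- vector("list", max_modes)
  prev <- NULL
  for (m in seq_len(max_modes)) {
    inits <- list(classical_init(dd, m))
    if (!is.null(prev)) inits <- c(inits, list(cbind(prev, 0)))
    for (r in seq_len(max(0L, n_restarts - length(inits))))
      inits <- c(inits, list(matrix(stats::rnorm(k * m), k, m)))
    best <- NULL
    for (y0 in inits) {
      fit <- tryCatch(
        suppressWarnings(MASS::isoMDS(dd, y = y0, k = m, trace = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$stress < best$stress))
        best <- fit
    }
    if (is.null(best)) stop("nonmetric MDS failed for ", m, " mode(s)")
    sols[[m]] <- best$points
    stress[m] <- best$stress
    fit_curve[m] <- stats::cor(as.vector(stats::dist(best$points)),
                               as.vector(dd), method = "spearman")
    prev <- best$points
  }

  if (is.null(n_modes)) n_modes <- elbow_select(fit_curve)
  n_modes <- max(1L, min(as.integer(n_modes), max_modes))
  scores <- sols[[n_modes]]
  scores <- sweep(scores, 2L, colMeans(scores), "-")
  colnames(scores) <- paste0("mode_", seq_len(n_modes))
  rownames(scores) <- ids
  structure(list(scores = scores, n_modes = n_modes,
                 fit_curve = fit_curve, stress = stress,
                 parcel_ids = ids), class = "cf_gradients")
}

classical_init <- function(dd, m) {
  y <- stats::cmdscale(dd, k = m)
  if (ncol(y) < m) y <- cbind(y, matrix(stats::rnorm(nrow(y) * (m - ncol(y)),
                                                     sd = 1e-4),
                                        nrow(y)))
  y
}

# elbow: mode count with the largest drop in curvature of the fit curve
# (most negative discrete second difference); 1 if the curve has no bend.
elbow_select <- function(fit_curve) {
  m <- length(fit_curve)
  if (m < 3L) return(if (m >= 2L && fit_curve[2] > fit_curve[1] + 0.05) 2L
                     else 1L)
  d2 <- fit_curve[3:m] - 2 * fit_curve[2:(m - 1)] + fit_curve[1:(m - 2)]
  as.integer(which.min(d2) + 1L)
}

#' @export
print.cf_gradients <- function(x, ...) {
  cat(sprintf("<cf_gradients> %d mode(s) over %d parcels (elbow of fit curve: %s)\n",
              x$n_modes, nrow(x$scores),
              paste(sprintf("%.3f", x$fit_curve), collapse = ", ")))
  invisible(x)
}

#' @export
plot.cf_gradients <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(seq_along(x$fit_curve), x$fit_curve, type = "b",
                 xlab = "modes", ylab = "rank correlation (fit)", ...)
  graphics::abline(v = x$n_modes, lty = 2)
  if (x$n_modes >= 2) {
    graphics::plot(x$scores[, 1], x$scores[, 2], pch = 16,
                   xlab = "mode 1", ylab = "mode 2")
  } else {
    graphics::plot(x$scores[, 1], pch = 16, xlab = "parcel",
                   ylab = "mode 1")
  }
  invisible(x)
}

#' Regress a task contrast map on connectivity gradients
#'
#' Ordinary least squares predicting per-parcel task activation from the
#' topographic gradients and (optionally) the per-parcel average
#' convergence. All predictors and the response are z-scored within the
#' analyzed parcel set, so the intercept is zero and the coefficients are
#' standardized betas.
#'
#' @param gradients a `cf_gradients` object or a numeric matrix of
#'   per-parcel gradient scores.
#' @param task_map numeric vector of per-parcel contrast values.
#' @param convergence optional numeric vector of per-parcel average
#'   convergence.
#' @return An object of class `cf_taskreg`: `coefficients` (data.frame
#'   with term, beta, se, t, p_value), `r_squared`, `n`.
#' @export
task_map_regression <- function(gradients, task_map, convergence = NULL) {
  G <- if (inherits(gradients, "cf_gradients")) gradients$scores
  else as.matrix(gradients)
  if (is.null(colnames(G))) colnames(G) <- paste0("mode_", seq_len(ncol(G)))
  X <- G
  if (!is.null(convergence)) X <- cbind(X, convergence = convergence)
  if (length(task_map) != nrow(X))
    stop("'task_map' length does not match the number of parcels")
  Xs <- scale(X)
  y <- as.vector(scale(task_map))
  qrX <- qr(cbind(1, Xs))
  if (qrX$rank < ncol(Xs) + 1L) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(Xs) + 1L), keep) - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(Xs)[dropped], collapse = ", "))
  }
  df <- data.frame(y = y, Xs)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  out <- list(
    coefficients = data.frame(
      term = rownames(co), beta = co[, 1], se = co[, 2], t = co[, 3],
      p_value = co[, 4], row.names = NULL),
    r_squared = sm$r.squared, n = length(y), lm_fit = fit)
  class(out) <- "cf_taskreg"
  out
}

#' @export
print.cf_taskreg <- function(x, ...) {
  cat(sprintf("Task-map regression (n = %d parcels, R^2 = %.2f)\n", x$n,
              x$r_squared))
  co <- x$coefficients
  co$term <- sub("^X\\.Intercept\\.$|^\\(Intercept\\)$", "Intercept",
                 co$term)
  for (r in seq_len(nrow(co)))
    cat(sprintf("  %-12s beta %6.2f  SE %5.2f  t %6.2f  p %.3g\n",
                co$term[r], co$beta[r], co$se[r], co$t[r], co$p_value[r]))
  invisible(x)
}

#' Per-parcel average convergence
#'
#' The mean corrected KS of each parcel as seed over all mapping parcels,
#' from a [pairwise_linearity()] run with `compute_convergence = TRUE`.
#'
#' @param lm a [linearity_matrix] with a `convergence` matrix.
#' @return named numeric vector, one value per parcel.
#' @export
average_convergence <- function(lm) {
  stopifnot(inherits(lm, "linearity_matrix"))
  if (is.null(lm$convergence))
    stop("linearity matrix carries no convergence values; rerun ",
         "pairwise_linearity(compute_convergence = TRUE)")
  out <- rowMeans(lm$convergence, na.rm = TRUE)
  names(out) <- lm$parcel_ids
  out
}

#' Write a linearity matrix to TSV (long format) and CSV (square)
#'
#' @param lm a [linearity_matrix].
#' @param tsv_path long-format TSV path (seed_id, map_id, linearity, p,
#'   resels, low_resel_flag); NULL to skip.
#' @param csv_path square-matrix CSV path; NULL to skip.
#' @export
write_linearity_matrix <- function(lm, tsv_path = NULL, csv_path = NULL) {
  stopifnot(inherits(lm, "linearity_matrix"))
  if (!is.null(tsv_path)) {
    k <- length(lm$parcel_ids)
    idx <- which(row(lm$values) != col(lm$values), arr.ind = TRUE)
    long <- data.frame(
      seed_id = lm$parcel_ids[idx[, 1]], map_id = lm$parcel_ids[idx[, 2]],
      linearity = lm$values[idx],
      p_value = if (!is.null(lm$p_values)) lm$p_values[idx] else NA,
      resels = if (!is.null(lm$resels)) lm$resels[idx] else NA,
      low_resel_flag = if (!is.null(lm$low_resel)) lm$low_resel[idx]
      else NA)
    utils::write.table(long, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(csv_path))
    utils::write.csv(lm$values, csv_path, row.names = TRUE)
  invisible(lm)
}
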