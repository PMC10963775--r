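#' Double-well quasi-potential model
#'
#' The state-transition model represents the transcriptome as a particle in
#' a quartic quasi-potential whose gradient is
#' `U_p'(x) = scale * (x - c1) * (x - c2) * (x - c3)`: `c1` is the normal
#' minimum, `c2` the unstable barrier maximum, `c3` the leukemic minimum.
#' The integration constant is fixed by `U_p(c1) = 0`, so well energies are
#' directly comparable and the Boltzmann exponent between the wells equals
#' `-U_p(c3)`.
#'
#' @param c1,c2,c3 Critical points with `c1 < c2 < c3` (state-space units).
#' @param scale Positive scaling coefficient of the potential.
#' @param beta_inv Diffusion coefficient (>= 0) used by the dynamics.
#' @return Object of class `potential_model`.
#' @export
potential_model <- function(c1, c2, c3, scale = 64, beta_inv = 0) {
  if (!(c1 < c2 && c2 < c3)) stop("critical points must satisfy c1 < c2 < c3")
  if (scale <= 0) stop("scale must be positive")
  if (beta_inv < 0) stop("beta_inv must be >= 0")
  structure(list(c1 = c1, c2 = c2, c3 = c3, scale = scale, beta_inv = beta_inv),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("Quasi-potential: c1 = %.4g, c2 = %.4g, c3 = %.4g (scale %.4g, beta_inv %.4g)\n",
              x$c1, x$c2, x$c3, x$scale, x$beta_inv))
  cat(sprintf("  barrier U(c2) = %.4g, leukemic well U(c3) = %.4g\n",
              potential_value(x, x$c2), potential_value(x, x$c3)))
  invisible(x)
}

#' Evaluate the quasi-potential and its gradient
#'
#' `potential_value()` integrates the cubic gradient analytically:
#' `U_p(x) = scale * (x^4/4 - s1 x^3/3 + s2 x^2/2 - s3 x) + K` with
#' `s1 = c1+c2+c3`, `s2 = c1 c2 + c1 c3 + c2 c3`, `s3 = c1 c2 c3`, and `K`
#' chosen so `U_p(c1) = 0`. `potential_gradient()` evaluates the cubic
#' itself.
#'
#' @param m A [potential_model()].
#' @param x Coordinate(s).
#' @return Potential (or gradient) values, vectorized over `x`.
#' @export
potential_value <- function(m, x) {
  s1 <- m$c1 + m$c2 + m$c3
  s2 <- m$c1 * m$c2 + m$c1 * m$c3 + m$c2 * m$c3
  s3 <- m$c1 * m$c2 * m$c3
  U <- function(z) m$scale * (z^4 / 4 - s1 * z^3 / 3 + s2 * z^2 / 2 - s3 * z)
  U(x) - U(m$c1)
}

#' @rdname potential_value
#' @export
potential_gradient <- function(m, x) {
  m$scale * (x - m$c1) * (x - m$c2) * (x - m$c3)
}

#' Estimate the stable critical points c1 and c3 by k-means
#'
#' Clusters the 1-D state-space coordinates with k-means (k = 2, seeded
#' restarts). The centroid of the cluster holding the majority of
#' normal-labelled samples becomes `c1`, the other centroid `c3`.
#'
#' @param coords Named per-sample coordinates.
#' @param labels Sample table or label vector.
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return List with `c1`, `c3`, `cluster` (factor `"c1"`/`"c3"` per
#'   sample) and `observed_ratio` (= n(c3 cluster) / n(c1 cluster), the
#'   observed Boltzmann occupancy ratio).
#' @export
estimate_c1_c3 <- function(coords, labels, seed = 1L, nstart = 10L) {
  if (length(unique(coords)) < 2L) stop("need at least 2 distinct coordinates")
  y <- label_vector(labels, names(coords) %||% seq_along(coords))
  km <- with_seed(seed, stats::kmeans(coords, centers = 2L, nstart = nstart))
  if (any(km$size == 0L)) stop("k-means produced an empty cluster")
  n_normal <- vapply(1:2, function(j) sum(y == 0L & km$cluster == j), integer(1))
  c1_cluster <- which.max(n_normal)
  c1 <- unname(km$centers[c1_cluster, 1L])
  c3 <- unname(km$centers[3L - c1_cluster, 1L])
  cluster <- factor(ifelse(km$cluster == c1_cluster, "c1", "c3"),
                    levels = c("c1", "c3"))
  names(cluster) <- names(coords)
  list(c1 = c1, c3 = c3, cluster = cluster,
       observed_ratio = sum(cluster == "c3") / sum(cluster == "c1"))
}

#' Locate the unstable critical point c2 from the Boltzmann ratio
#'
#' Scans candidate `c2` values strictly inside `(c1, c3)` and selects the
#' one for which the theoretical Boltzmann occupancy ratio
#' `Pr(c3)/Pr(c1) = exp(U_p(c1) - U_p(c3))` matches the observed sample
#' ratio, i.e. minimizes `|ln(observed_ratio) - (U_p(c1) - U_p(c3))|`. The
#' grid optimum is refined by golden-section search; exact ties on the
#' grid resolve toward the midpoint.
#'
#' @param c1,c3 Stable critical points, `c1 < c3`.
#' @param observed_ratio Positive observed ratio n(c3)/n(c1).
#' @param scale Scaling coefficient of the potential.
#' @param n_grid Number of grid candidates.
#' @return List with `c2`, `residual` (absolute mismatch of the log
#'   ratios at the optimum) and `converged` (`FALSE`, with a warning, when
#'   the residual exceeds 1e-3: no interior `c2` matches the observed
#'   ratio at this scale).
#' @export
estimate_c2 <- function(c1, c3, observed_ratio, scale = 64, n_grid = 1000L) {
  if (!(c1 < c3)) stop("need c1 < c3")
  if (!is.finite(observed_ratio) || observed_ratio <= 0)
    stop("observed_ratio must be a positive number")
  target <- log(observed_ratio)
  # U_p(c1) - U_p(c3) as a function of the candidate c2 (closed form)
  mism <- function(c2) {
    s1 <- c1 + c2 + c3
    s2 <- c1 * c2 + c1 * c3 + c2 * c3
    s3 <- c1 * c2 * c3
    U <- function(z) scale * (z^4 / 4 - s1 * z^3 / 3 + s2 * z^2 / 2 - s3 * z)
    abs(target - (U(c1) - U(c3)))
  }
  h <- (c3 - c1) / (n_grid + 1)
  grid <- c1 + h * seq_len(n_grid)
  obj <- vapply(grid, mism, numeric(1))
  best <- which(obj <= min(obj) + 0)
  if (length(best) > 1L)                       # tie: prefer the midpoint
    best <- best[which.min(abs(grid[best] - (c1 + c3) / 2))]
  lo <- grid[max(best - 1L, 1L)]; hi <- grid[min(best + 1L, n_grid)]
  opt <- stats::optimize(mism, c(lo, hi), tol = .Machine$double.eps^0.5)
  c2 <- opt$minimum; residual <- opt$objective
  if (residual > 1e-3)
    warning(sprintf("no interior c2 matches the observed ratio at scale %g (residual %.3g)",
                    scale, residual))
  list(c2 = c2, residual = residual, converged = residual <= 1e-3)
}

#' Assign samples to their nearest critical point
#'
#' Each coordinate is associated with the nearest of `c1`, `c2`, `c3`;
#' exact ties go to `c2`, conservatively flagging the unstable state.
#'
#' @param coords Named per-sample coordinates.
#' @param m A [potential_model()].
#' @return data.frame with `sample_id`, `coordinate`, `assigned`
#'   (factor `c1`/`c2`/`c3`) and `distance`.
#' @export
assign_critical_points <- function(coords, m) {
  stopifnot(inherits(m, "potential_model"))
  cp <- c(c1 = m$c1, c2 = m$c2, c3 = m$c3)
  assigned <- character(length(coords)); dist <- numeric(length(coords))
  for (i in seq_along(coords)) {
    d <- abs(coords[i] - cp)
    nearest <- names(cp)[d == min(d)]
    assigned[i] <- if ("c2" %in% nearest) "c2" else nearest[1L]
    dist[i] <- min(d)
  }
  data.frame(sample_id = names(coords) %||% as.character(seq_along(coords)),
             coordinate = unname(coords),
             assigned = factor(assigned, levels = c("c1", "c2", "c3")),
             distance = dist, stringsAsFactors = FALSE)
}

#' Estimate the diffusion coefficient from the normal well
#'
#' Stationary harmonic approximation at the normal minimum: with curvature
#' `kappa = U_p''(c1) = scale * (c1 - c2) * (c1 - c3)` and the observed
#' variance `s^2` of the c1-cluster coordinates, the Boltzmann-Gaussian
#' relation `s^2 = beta_inv / kappa` gives `beta_inv = kappa * s^2`.
#'
#' @param c1,c2,c3,scale Potential parameters.
#' @param c1_coords Coordinates of the samples in the normal (c1) cluster.
#' @return Nonnegative diffusion coefficient.
#' @export
estimate_beta_inv <- function(c1, c2, c3, scale, c1_coords) {
  if (length(c1_coords) < 2L) stop("need at least 2 samples in the c1 cluster")
  kappa <- scale * (c1 - c2) * (c1 - c3)
  kappa * stats::var(c1_coords)
}

#' Rescale state-space coordinates to the unit interval
#'
#' Affine map `u = (x - c1) / (c3 - c1)` sending the normal well to 0 and
#' the leukemic well to 1, in which the default potential scale 64 gives a
#' symmetric barrier height of exactly 1 energy unit.
#'
#' @param coords Coordinates in state-space units.
#' @param c1,c3 Well positions in the same units.
#' @return Rescaled coordinates.
#' @export
rescale_coordinates <- function(coords, c1, c3) {
  if (!(c1 < c3)) stop("need c1 < c3")
  (coords - c1) / (c3 - c1)
}

#' Pseudotime from a marker gene
#'
#' Orders cross-sectional samples by the expression of a designated marker
#' gene (the empirical rank rescaled to [0, 1], ties sharing midranks).
#' The marker's suitability is checked by a two-sample t-test between the
#' normal and AML groups: a non-significant difference produces a warning
#' (the ordering is still returned), a constant marker an error.
#'
#' @param m Expression matrix (linear scale, genes x samples).
#' @param marker_gene_id Gene to use as the pseudotime marker.
#' @param labels Sample table or label vector.
#' @param level Significance level of the marker check.
#' @return List with `pseudotime` (named vector in [0, 1], monotone in the
#'   marker), `p_value` of the marker test and `significant`.
#' @export
pseudotime_from_marker <- function(m, marker_gene_id, labels, level = 0.05) {
  if (!marker_gene_id %in% rownames(m)) stop("marker gene not found: ", marker_gene_id)
  x <- m[marker_gene_id, ]
  if (stats::sd(x) == 0) stop("marker gene is constant; pseudotime undefined")
  y <- label_vector(labels, colnames(m))
  if (min(table(y)) < 2L) {
    warning("too few samples per group to test the marker; skipping the check")
    p <- NA_real_
  } else p <- stats::t.test(x[y == 1L], x[y == 0L])$p.value
  if (!is.na(p) && p >= level)
    warning(sprintf("marker '%s' does not differ between groups (p = %.3g)",
                    marker_gene_id, p))
  r <- rank(x, ties.method = "average")
  pt <- (r - 1) / (length(x) - 1)
  list(pseudotime = stats::setNames(pt, colnames(m)), p_value = p,
       significant = if (is.na(p)) NA else p < level)
}
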