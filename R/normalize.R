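## Surface smoothing and the two-stage z-score normalization that makes
## features comparable across vertices and subjects.

## Precomputed heat-diffusion smoother for a mesh: explicit Euler steps of
## the cotangent Laplace-Beltrami operator with barycentric vertex masses.
## For diffusion time T the impulse response approaches a geodesic Gaussian
## with per-axis variance sigma^2 = 2T, which calibrates the iteration count
## for a requested FWHM (sigma^2 = FWHM^2 / (8 ln 2)).
.make_smoother <- function(mesh, fwhm, lambda = 0.5) {
  sigma2 <- fwhm^2 / (8 * log(2))
  cw <- .cot_weights(mesh, clamp = TRUE)
  n <- nrow(mesh$vertices)
  A <- mesh$vertex_areas
  rw <- .accumulate(cw$i, cw$w, n) + .accumulate(cw$j, cw$w, n)
  ratio <- A / pmax(rw, 1e-12)
  iso <- rw < 1e-12  # isolated after clamping: left unchanged
  dt_max <- lambda * min(ratio[!iso])
  n_iter <- max(1L, as.integer(ceiling(sigma2 / (2 * dt_max))))
  dt <- sigma2 / (2 * n_iter)
  # P = I + dt * M^-1 L ; row-stochastic up to clamping, hence max principle
  W <- Matrix::sparseMatrix(i = c(cw$i, cw$j), j = c(cw$j, cw$i),
                            x = rep(cw$w, 2L), dims = c(n, n))
  P <- Matrix::Diagonal(n, 1 - dt * rw / A) + Matrix::Diagonal(n, dt / A) %*% W
  list(P = P, n_iter = n_iter, isolated = iso)
}

#' Gaussian surface smoothing by FWHM
#'
#' Iterative area-weighted diffusion on the mesh, with the step count
#' calibrated so that a point source spreads to the requested full width at
#' half maximum (on a flat mesh; on folded cortex the FWHM is approximate).
#' The area-weighted mean of the map is preserved to machine precision and
#' smoothing never exceeds the input extrema. Masked (`NA`) vertices are
#' excluded and stay masked.
#'
#' @param map per-vertex numeric map, or a matrix with one map per column.
#' @param mesh the `fcd_mesh` carrying the map.
#' @param fwhm kernel full width at half maximum in mm.
#' @return smoothed map (same shape as the input).
#' @export
smooth_fwhm <- function(map, mesh, fwhm = 10) {
  stopifnot(inherits(mesh, "fcd_mesh"))
  if (fwhm <= 0) stop("fwhm must be > 0")
  sm <- .make_smoother(mesh, fwhm)
  .apply_smoother(sm, map, mesh)
}

.apply_smoother <- function(sm, map, mesh) {
  x <- if (is.matrix(map)) map else matrix(as.double(map), ncol = 1L)
  nav <- is.na(x)
  if (any(nav)) {
    ## renormalized diffusion: diffuse value*indicator and indicator, divide
    ind <- 1 - nav * 1
    x0 <- x
    x0[nav] <- 0
    for (it in seq_len(sm$n_iter)) {
      x0 <- as.matrix(sm$P %*% x0)
      ind <- as.matrix(sm$P %*% ind)
    }
    x <- x0 / pmax(ind, 1e-12)
    x[nav] <- NA_real_
  } else {
    for (it in seq_len(sm$n_iter)) x <- as.matrix(sm$P %*% x)
  }
  if (any(sm$isolated)) {
    warning("mesh has isolated vertices; left unsmoothed")
    x[sm$isolated, ] <- (if (is.matrix(map)) map else
      matrix(as.double(map), ncol = 1L))[sm$isolated, ]
  }
  if (is.matrix(map)) x else {
    out <- x[, 1L]
    if (inherits(map, "fcd_scalar_map"))
      out <- scalar_map(out, attr(map, "name"), attr(map, "units"))
    out
  }
}

#' Within-subject z-score normalization
#'
#' Centers and scales a feature map over its valid vertices so the output
#' has mean 0 and standard deviation 1 (population convention, divisor n).
#' Invariant under any positive affine rescaling of the input.
#'
#' @param map per-vertex numeric map (`NA` = masked).
#' @return an `fcd_scalar_map` in z units.
#' @export
zscore_within_subject <- function(map) {
  v <- as.double(map)
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 valid vertices to z-score")
  m <- mean(v[ok])
  s <- sqrt(mean((v[ok] - m)^2))
  nm <- attr(map, "name") %||% "map"
  if (s < 1e-12)
    stop("feature '", nm, "' has zero variance; cannot z-score")
  scalar_map((v - m) / s, nm, "z")
}

#' Control-cohort normalization statistics
#'
#' Per-vertex mean and standard deviation of each feature over the control
#' cohort (population convention, divisor n, consistent with the
#' within-subject stage). Vertices masked in a control subject are excluded
#' from that vertex's statistics; vertices with fewer than 2 contributing
#' controls or near-zero spread are flagged and masked downstream.
#'
#' @param controls list of control subjects; each a named list of per-vertex
#'   feature vectors (all on the common template, equal lengths).
#' @param sd_floor minimal admissible standard deviation in feature units.
#' @return object of class `fcd_control_stats`: per-feature `mean` and `sd`
#'   vectors, the feature registry, and the cohort size.
#' @export
fit_control_stats <- function(controls, sd_floor = 1e-6) {
  if (length(controls) < 2L) stop("need at least 2 control subjects")
  feats <- names(controls[[1L]])
  for (s in controls)
    if (!identical(names(s), feats))
      stop("all control subjects must share the same feature registry")
  stats <- lapply(feats, function(f) {
    X <- vapply(controls, function(s) as.double(s[[f]]),
                numeric(length(controls[[1L]][[f]])))
    k <- rowSums(!is.na(X))
    mu <- rowMeans(X, na.rm = TRUE)
    sdv <- sqrt(rowMeans((X - mu)^2, na.rm = TRUE))
    bad <- k < 2L | !is.finite(sdv) | sdv < sd_floor
    mu[bad] <- NA_real_
    sdv[bad] <- NA_real_
    list(mean = mu, sd = sdv)
  })
  names(stats) <- feats
  structure(list(stats = stats, features = feats,
                 n_controls = length(controls), sd_floor = sd_floor),
            class = "fcd_control_stats")
}

#' @export
print.fcd_control_stats <- function(x, ...) {
  cat("Control cohort statistics:", x$n_controls, "controls,",
      length(x$features), "features\n")
  invisible(x)
}

#' Between-subject z-score normalization
#'
#' Standardizes a subject's feature map against the control cohort:
#' `z_i = (x_i - mean_i) / sd_i` with the per-vertex control statistics.
#' Vertices flagged in the control statistics are masked.
#'
#' @param map per-vertex numeric map.
#' @param stats an `fcd_control_stats` object.
#' @param feature feature name to look up in `stats`; defaults to the map's
#'   own name.
#' @return an `fcd_scalar_map` in control-z units.
#' @export
zscore_between_subjects <- function(map, stats, feature = NULL) {
  stopifnot(inherits(stats, "fcd_control_stats"))
  feature <- feature %||% attr(map, "name")
  if (is.null(feature) || !feature %in% stats$features)
    stop("feature '", feature, "' not present in the control statistics")
  st <- stats$stats[[feature]]
  v <- as.double(map)
  if (length(v) != length(st$mean))
    stop("map length ", length(v), " does not match the template's ",
         length(st$mean), " vertices")
  scalar_map((v - st$mean) / st$sd, feature, "z")
}

#' Save / load control statistics
#'
#' Serializes an `fcd_control_stats` object to a single JSON archive
#' (per-vertex mean/sd arrays plus a manifest) for reuse across runs.
#' @param stats an `fcd_control_stats`.
#' @param path output JSON path.
#' @return `read_control_stats()` returns the restored object.
#' @export
write_control_stats <- function(stats, path) {
  stopifnot(inherits(stats, "fcd_control_stats"))
  jsonlite::write_json(
    list(manifest = list(n_controls = stats$n_controls,
                         features = stats$features,
                         sd_floor = stats$sd_floor),
         stats = stats$stats),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_control_stats
#' @export
read_control_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats <- lapply(obj$stats, function(s)
    list(mean = as.double(s$mean), sd = as.double(s$sd)))
  structure(list(stats = stats, features = obj$manifest$features,
                 n_controls = obj$manifest$n_controls,
                 sd_floor = obj$manifest$sd_floor),
            class = "fcd_control_stats")
}
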