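## Subject-level feature bundles: the full multimodal per-vertex feature
## set, its smoothing/normalization, and flattening into classifier inputs.

.base_registry <- c("thickness", "gwc", "curv", "sulc", "lcd",
                    "flair_0", "flair_25", "flair_50", "flair_75",
                    "flair_wm05", "flair_wm1", "pet_hypo")

#' Extract the multimodal feature bundle of one subject
#'
#' Computes, per hemisphere: cortical thickness, GM/WM intensity contrast,
#' mean curvature (white surface), sulcal depth (pial), local cortical
#' deformation, the six-depth FLAIR profile and normalized PET uptake; then
#' the doughnut contrast maps of GM/WM contrast, thickness and each FLAIR
#' depth (distances on the inflated surface); and finally the
#' interhemispheric asymmetry of every base and doughnut feature through the
#' homotopic correspondence (the PET asymmetry feature is the asymmetry of
#' the normalized PET map). 40 feature maps per hemisphere in total.
#'
#' @param subject an `fcd_subject` (or any list with the same shape:
#'   `hemis$left/right` carrying `pair` and `inflated`, `volumes$left/right`
#'   carrying `t1`, `flair`, `pet`, and `corr`).
#' @param lcd_radius radius of the intrinsic-curvature disc in mm.
#' @param doughnut_radius doughnut disc radius in mm.
#' @param crown_eps crown tolerance for sulcal depth, in mm.
#' @return object of class `fcd_features`: per-hemisphere named lists of
#'   `fcd_scalar_map`s plus the feature `registry`.
#' @export
extract_features <- function(subject, lcd_radius = 25, doughnut_radius = 6,
                             crown_eps = 0.5) {
  hemis <- subject$hemis
  out <- list()
  for (h in c("left", "right")) {
    pair <- hemis[[h]]$pair
    vols <- subject$volumes[[h]]
    maps <- list(
      thickness = cortical_thickness(pair),
      gwc = gwc(vols$t1, pair),
      curv = mean_curvature(pair$white),
      sulc = sulcal_depth(pair$pial, eps = crown_eps),
      lcd = local_cortical_deformation(pair$white, radius = lcd_radius))
    maps <- c(maps, flair_profile(vols$flair, pair))
    out[[h]] <- maps
  }
  pet <- pet_hypointensity(subject$volumes$left$pet, hemis$left$pair,
                           subject$volumes$right$pet, hemis$right$pair)
  out$left$pet_hypo <- pet$left
  out$right$pet_hypo <- pet$right

  dough_feats <- c("gwc", "thickness", "flair_0", "flair_25", "flair_50",
                   "flair_75", "flair_wm05", "flair_wm1")
  for (h in c("left", "right")) {
    infl <- hemis[[h]]$inflated
    vals <- vapply(dough_feats, function(f) as.double(out[[h]][[f]]),
                   numeric(nrow(infl$vertices)))
    st <- .disc_annulus_stats(infl, vals, doughnut_radius, 2 * doughnut_radius)
    d <- st$disc - st$annulus
    d[st$n_annulus == 0L, ] <- NA_real_
    for (j in seq_along(dough_feats))
      out[[h]][[paste0("doughnut_", dough_feats[j])]] <-
        scalar_map(d[, j], paste0("doughnut_", dough_feats[j]),
                   attr(out[[h]][[dough_feats[j]]], "units"))
  }
  plain <- names(out$left)
  for (f in plain) {
    ai <- asymmetry_index(out$left[[f]], out$right[[f]], subject$corr)
    out$left[[paste0("asym_", f)]] <- ai$left
    out$right[[paste0("asym_", f)]] <- ai$right
  }
  structure(list(left = out$left, right = out$right,
                 registry = names(out$left),
                 n = nrow(hemis$left$pair$pial$vertices)),
            class = "fcd_features")
}

#' @export
print.fcd_features <- function(x, ...) {
  cat("Feature bundle:", length(x$registry), "features x", x$n,
      "vertices per hemisphere\n")
  invisible(x)
}

## stack a bundle into a (2N x p) matrix, left hemisphere rows first
.features_as_matrix <- function(feat) {
  stopifnot(inherits(feat, "fcd_features"))
  do.call(rbind, lapply(c("left", "right"), function(h)
    vapply(feat$registry, function(f) as.double(feat[[h]][[f]]),
           numeric(feat$n))))
}

.matrix_as_features <- function(X, template, units = "z") {
  out <- template
  for (j in seq_along(template$registry)) {
    f <- template$registry[j]
    out$left[[f]] <- scalar_map(X[seq_len(template$n), j], f, units)
    out$right[[f]] <- scalar_map(X[template$n + seq_len(template$n), j], f, units)
  }
  out
}

#' Smooth and z-normalize a feature bundle
#'
#' The normalization pipeline, in the pinned order: (1) each feature map is
#' smoothed on its hemisphere's white surface with a Gaussian kernel of the
#' given FWHM; (2) within-subject z-scoring of each feature over all valid
#' vertices of both hemispheres; (3) if control-cohort statistics are
#' supplied, between-subject z-scoring against the per-vertex control mean
#' and SD.
#'
#' @param feat an `fcd_features` bundle.
#' @param subject the subject the bundle came from (supplies the meshes).
#' @param fwhm smoothing kernel FWHM in mm.
#' @param stats optional `fcd_control_stats` for the between-subject stage.
#' @return a normalized `fcd_features` bundle.
#' @export
normalize_features <- function(feat, subject, fwhm = 10, stats = NULL) {
  stopifnot(inherits(feat, "fcd_features"))
  n <- feat$n
  X <- matrix(NA_real_, 2L * n, length(feat$registry))
  for (h in c("left", "right")) {
    mesh <- subject$hemis[[h]]$pair$white
    sm <- .make_smoother(mesh, fwhm)
    M <- vapply(feat$registry, function(f) as.double(feat[[h]][[f]]), numeric(n))
    rows <- if (h == "left") seq_len(n) else n + seq_len(n)
    X[rows, ] <- .apply_smoother(sm, M, mesh)
  }
  for (j in seq_along(feat$registry)) {
    X[, j] <- as.double(zscore_within_subject(
      scalar_map(X[, j], feat$registry[j])))
    if (!is.null(stats)) {
      st <- stats$stats[[feat$registry[j]]]
      if (is.null(st)) stop("control statistics lack feature '",
                            feat$registry[j], "'")
      if (length(st$mean) != nrow(X))
        stop("control statistics were fit on a different template")
      X[, j] <- (X[, j] - st$mean) / st$sd
    }
  }
  .matrix_as_features(X, feat)
}

## control stats input: list of flattened per-feature vectors per subject
.features_for_stats <- function(feat) {
  X <- .features_as_matrix(feat)
  setNames(lapply(seq_len(ncol(X)), function(j) X[, j]), feat$registry)
}

#' Fit control-cohort statistics from normalized bundles
#'
#' Convenience wrapper around [fit_control_stats()] taking smoothed,
#' within-subject-normalized `fcd_features` bundles of the control arm.
#'
#' @param bundles list of normalized `fcd_features` from control subjects.
#' @param ... passed to [fit_control_stats()].
#' @return an `fcd_control_stats` over the concatenated (left, right)
#'   vertex template.
#' @export
fit_control_stats_bundles <- function(bundles, ...) {
  fit_control_stats(lapply(bundles, .features_for_stats), ...)
}
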