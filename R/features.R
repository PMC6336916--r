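## Per-vertex multimodal feature operators: morphology, FLAIR intensity
## profile, PET metabolism, doughnut contrast, interhemispheric asymmetry.

#' Cortical thickness
#'
#' Euclidean distance between corresponding white and pial vertices.
#' @param pair an `fcd_surface_pair`.
#' @return an `fcd_scalar_map` in mm (non-negative).
#' @export
cortical_thickness <- function(pair) {
  stopifnot(inherits(pair, "fcd_surface_pair"))
  d <- sqrt(rowSums((pair$pial$vertices - pair$white$vertices)^2))
  scalar_map(d, "thickness", "mm")
}

#' GM/WM intensity contrast
#'
#' Ratio of gray-matter to white-matter T1 signal: the GM sample is taken
#' 30% through the cortical ribbon, the WM sample 1 mm below the GM/WM
#' boundary. Blurring of the boundary pulls the ratio toward 1, the FCD
#' signature direction. Vertices where the WM sample is non-positive or
#' either sample leaves the volume are masked.
#'
#' @param t1 co-registered T1 `fcd_volume`.
#' @param pair an `fcd_surface_pair`.
#' @param gm_fraction cortical depth of the GM sample.
#' @param wm_depth_mm WM sampling depth below the boundary in mm.
#' @return an `fcd_scalar_map` (unitless ratio).
#' @export
gwc <- function(t1, pair, gm_fraction = 0.30, wm_depth_mm = 1.0) {
  gm <- as.double(sample_at_fraction(t1, pair, gm_fraction))
  wm <- as.double(sample_below_white(t1, pair, wm_depth_mm))
  out <- gm / wm
  out[!is.na(wm) & wm <= 0] <- NA_real_
  scalar_map(out, "gwc", "ratio")
}

#' FLAIR intensity depth profile
#'
#' Samples the FLAIR volume at the GM/WM boundary, at 25%, 50% and 75% of
#' cortical thickness, and at 0.5 mm and 1 mm below the boundary. A reduced
#' difference between the boundary sample and the 1-mm-below sample (the
#' vertical gradient) indicates GM/WM blurring.
#'
#' @param flair co-registered FLAIR `fcd_volume`.
#' @param pair an `fcd_surface_pair`.
#' @return named list of six `fcd_scalar_map`s: `flair_0`, `flair_25`,
#'   `flair_50`, `flair_75`, `flair_wm05`, `flair_wm1`.
#' @export
flair_profile <- function(flair, pair) {
  fr <- c(0, 0.25, 0.50, 0.75)
  maps <- lapply(fr, function(f) sample_at_fraction(flair, pair, f))
  maps <- c(maps, list(sample_below_white(flair, pair, 0.5),
                       sample_below_white(flair, pair, 1.0)))
  names(maps) <- c("flair_0", "flair_25", "flair_50", "flair_75",
                   "flair_wm05", "flair_wm1")
  for (nm in names(maps)) attr(maps[[nm]], "name") <- nm
  maps
}

#' Local cortical deformation
#'
#' Degree of intrinsic cortical folding around each vertex: the
#' area-weighted mean of |Gaussian curvature| over the geodesic disc of the
#' given radius. On a sphere of radius R this is 1/R^2 everywhere; on a
#' plane it is 0. Vertices whose disc contains fewer than 3 vertices are
#' masked.
#'
#' @param mesh the surface carrying the curvature (typically the white
#'   surface).
#' @param radius disc radius in mm.
#' @return an `fcd_scalar_map` in 1/mm^2.
#' @export
local_cortical_deformation <- function(mesh, radius = 25) {
  stopifnot(inherits(mesh, "fcd_mesh"))
  if (radius <= mean(mesh$edge_lengths))
    stop("radius must exceed the mean edge length")
  k <- abs(as.double(gaussian_curvature(mesh)))
  st <- .disc_annulus_stats(mesh, k, radius, radius)
  out <- st$disc[, 1L]
  out[st$n_disc < 3L] <- NA_real_
  scalar_map(out, "lcd", "1/mm^2")
}

#' PET hypometabolism map
#'
#' Normalized PET uptake per vertex: the volume is sampled at 50% cortical
#' depth and divided by the area-weighted mean uptake over all valid
#' cortical vertices of both hemispheres, so hypometabolic lesions fall
#' below 1 and the map is invariant to global scanner scaling.
#'
#' @param pet_left,pet_right co-registered PET `fcd_volume`s per hemisphere
#'   (pass the same volume twice if both hemispheres share one image).
#' @param pair_left,pair_right `fcd_surface_pair`s. The right hemisphere may
#'   be omitted, in which case normalization uses the left alone.
#' @param fraction cortical sampling depth.
#' @return list of `fcd_scalar_map`s `left` and (if given) `right`.
#' @export
pet_hypointensity <- function(pet_left, pair_left, pet_right = NULL,
                              pair_right = NULL, fraction = 0.5) {
  raw_l <- as.double(sample_at_fraction(pet_left, pair_left, fraction))
  raw_r <- if (!is.null(pet_right))
    as.double(sample_at_fraction(pet_right, pair_right, fraction))
  vals <- c(raw_l, raw_r)
  areas <- c(pair_left$white$vertex_areas,
             if (!is.null(pet_right)) pair_right$white$vertex_areas)
  ok <- !is.na(vals)
  m <- sum(vals[ok] * areas[ok]) / sum(areas[ok])
  if (!is.finite(m) || m <= 0)
    stop("global mean PET uptake is not positive; corrupt PET volume?")
  out <- list(left = scalar_map(raw_l / m, "pet_hypo", "ratio"))
  if (!is.null(pet_right))
    out$right <- scalar_map(raw_r / m, "pet_hypo", "ratio")
  out
}

#' Interhemispheric asymmetry index
#'
#' Vertex-wise asymmetry between homotopic locations:
#' `asym_L(i) = 2 * (L_i - R_c(i)) / (L_i + R_c(i))` where `c` is the
#' homotopic correspondence; the right-hemisphere map is its negation
#' mapped back through `c`, so `asym_L(i) = -asym_R(c(i))`. Vertices where
#' `|L + R|` falls below `eps` (or either side is masked) are masked.
#'
#' @param left,right numeric per-vertex maps on each hemisphere.
#' @param corr an `fcd_homotopic` correspondence.
#' @param eps denominator floor.
#' @return list of `fcd_scalar_map`s `left` and `right`.
#' @export
asymmetry_index <- function(left, right, corr, eps = 1e-9) {
  stopifnot(inherits(corr, "fcd_homotopic"))
  l2r <- corr$left_to_right
  l <- as.double(left)
  r <- as.double(right)
  if (length(l2r) != length(l))
    stop("correspondence length does not match the left hemisphere")
  rr <- rep(NA_real_, length(l))
  ok <- !is.na(l2r)
  rr[ok] <- r[l2r[ok]]
  s <- l + rr
  a_l <- ifelse(abs(s) < eps, NA_real_, 2 * (l - rr) / s)
  a_r <- rep(NA_real_, length(r))
  a_r[l2r[ok]] <- -a_l[ok]
  nm <- attr(left, "name")
  nm <- if (is.null(nm)) "asym" else paste0("asym_", nm)
  list(left = scalar_map(a_l, nm, "ratio"), right = scalar_map(a_r, nm, "ratio"))
}

#' Doughnut contrast map
#'
#' Local contrast of a feature map: the area-weighted mean over the geodesic
#' disc of radius `radius` centered at each vertex minus the mean over the
#' surrounding annulus (`radius` to `outer_radius`). Distances are measured
#' on `surface` - conventionally the inflated surface, where disc radii are
#' unaffected by folding. Vertices with an empty annulus are masked; the
#' operator is linear in the input map and exactly 0 for constant maps.
#'
#' @param map per-vertex numeric map.
#' @param surface `fcd_mesh` used for geodesic distances and areas.
#' @param radius disc radius in mm.
#' @param outer_radius outer annulus radius in mm.
#' @return an `fcd_scalar_map` in the input map's units.
#' @export
doughnut_map <- function(map, surface, radius = 6, outer_radius = 2 * radius) {
  stopifnot(inherits(surface, "fcd_mesh"))
  if (radius <= 0 || outer_radius <= radius)
    stop("need 0 < radius < outer_radius")
  v <- as.double(map)
  if (length(v) != nrow(surface$vertices))
    stop("map length does not match the surface vertex count")
  st <- .disc_annulus_stats(surface, v, radius, outer_radius)
  out <- st$disc[, 1L] - st$annulus[, 1L]
  out[st$n_annulus == 0L] <- NA_real_
  nm <- attr(map, "name")
  nm <- if (is.null(nm)) "doughnut" else paste0("doughnut_", nm)
  scalar_map(out, nm, attr(map, "units") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
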