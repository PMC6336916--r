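## Synthetic cohort generator: folded phantom hemispheres, co-registered
## T1/FLAIR/PET phantom volumes, homotopic correspondences, and planted
## geodesic-disc lesions carrying the radiological signatures of FCD II
## (thickening, GM/WM blurring, FLAIR hyperintensity, PET hypometabolism,
## interhemispheric asymmetry).

.run_seed <- function(seed, k) (as.numeric(seed) * 977 + 7919 * k) %% 2147483647

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic cohort specification
#'
#' Parameters of the synthetic study: cohort sizes, phantom geometry, lesion
#' effect sizes and modality noise. The defaults define the reference
#' conditions used throughout the package's end-to-end validation: 10
#' patients and 10 controls, icosphere subdivision 4 (2562 vertices per
#' hemisphere), hemisphere radius 45 mm with 4 mm sinusoidal folds, 3 mm
#' baseline cortical thickness, 10 mm geodesic lesion discs with +1.5 mm
#' thickening, 2 mm GM/WM boundary blur, +15% FLAIR signal and -40% PET
#' uptake, and 1 mm isotropic phantom volumes.
#'
#' @param n_patients,n_controls cohort arm sizes.
#' @param subdivisions icosphere subdivision level (>= 2).
#' @param radius_mm mean hemisphere radius.
#' @param fold_amplitude_mm amplitude of the sinusoidal folding.
#' @param fold_frequency angular frequency of the folds.
#' @param thickness_mm baseline cortical thickness.
#' @param lesion_radius_mm geodesic radius of the planted lesion disc.
#' @param resection_margin_mm extra geodesic margin of the resection label.
#' @param delta_thickness_mm lesional cortical thickening.
#' @param blur_sigma_mm Gaussian blur of the lesional GM/WM interface.
#' @param flair_increase fractional lesional FLAIR hyperintensity.
#' @param pet_reduction fractional lesional PET uptake reduction.
#' @param noise_sd per-modality additive Gaussian noise SD (t1, flair, pet).
#' @param recon_noise_mm SD of the smooth radial vertex displacement
#'   emulating surface-reconstruction error, drawn independently per
#'   hemisphere and surface (0 gives exactly mirror-symmetric anatomy).
#' @param voxel_mm isotropic voxel size of the phantom volumes.
#' @param seed master seed; every random draw in the generator derives from
#'   it.
#' @return object of class `fcd_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10, n_controls = 10, subdivisions = 4,
                        radius_mm = 45, fold_amplitude_mm = 4,
                        fold_frequency = 10, thickness_mm = 3,
                        lesion_radius_mm = 10, resection_margin_mm = 5,
                        delta_thickness_mm = 1.5, blur_sigma_mm = 2,
                        flair_increase = 0.15, pet_reduction = 0.40,
                        noise_sd = c(t1 = 5, flair = 5, pet = 5),
                        recon_noise_mm = 0.15, voxel_mm = 1, seed = 1) {
  if (subdivisions < 2) stop("subdivisions must be >= 2")
  stopifnot(n_patients >= 0, n_controls >= 0, thickness_mm > 0,
            lesion_radius_mm > 0, all(is.finite(c(
              delta_thickness_mm, blur_sigma_mm, flair_increase,
              pet_reduction))))
  noise_sd <- noise_sd[c("t1", "flair", "pet")]
  structure(as.list(environment()), class = "fcd_cohort_spec")
}

#' @export
print.fcd_cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d patients / %d controls, seed %s\n",
              x$n_patients, x$n_controls, format(x$seed)))
  cat(sprintf("  effects: +%g mm thickness, blur %g mm, FLAIR +%g%%, PET -%g%%\n",
              x$delta_thickness_mm, x$blur_sigma_mm, 100 * x$flair_increase,
              100 * x$pet_reduction))
  invisible(x)
}

## neighbor-average a per-vertex field a few times (icosphere topology)
.smooth_field_on_faces <- function(x, faces, iterations) {
  n <- length(x)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key <- (pmin(e[, 1], e[, 2]) - 1) * n + pmax(e[, 1], e[, 2])
  e <- e[!duplicated(key), , drop = FALSE]
  i <- c(e[, 1], e[, 2]); j <- c(e[, 2], e[, 1])
  deg <- tabulate(i, nbins = n)
  for (it in seq_len(iterations))
    x <- .accumulate(i, x[j], n) / deg
  x
}

## smooth folding field g(u) in [-1, 1] over unit directions; frame and
## phases are per subject, the right hemisphere sees the mirrored direction
.fold_field <- function(u, geom) {
  if (geom$mirror) u <- u %*% diag(c(-1, 1, 1))
  a1 <- geom$freq * (u %*% geom$frame[, 1L]) + geom$phase[1L]
  a2 <- geom$freq * (u %*% geom$frame[, 2L]) + geom$phase[2L]
  as.vector(sin(a1) * sin(a2))
}

## pial radius in direction u, including the lesional thickening cap
.pial_radius <- function(u, geom) {
  rho <- geom$radius + geom$amplitude * .fold_field(u, geom)
  if (!is.null(geom$lesion_cap)) {
    inside <- as.vector(u %*% geom$lesion_cap$dir) >= geom$lesion_cap$cos_psi
    rho <- rho + geom$lesion_cap$delta * inside
  }
  rho
}

#' Synthetic folded hemisphere
#'
#' Builds one phantom hemisphere: the pial surface is an icosphere deformed
#' radially by a product-of-sinusoids folding field with a subject-specific
#' random orientation and phase; the white surface is the pial offset
#' inward radially by the baseline thickness (so the thickness feature
#' recovers it exactly); the inflated surface is a heavily smoothed pial.
#' The right hemisphere is the exact mirror image of the left (x -> -x,
#' with faces rewound), so the identity map is an exact homotopic
#' correspondence.
#'
#' @param spec an `fcd_cohort_spec`.
#' @param side `"left"` or `"right"`.
#' @param seed subject seed controlling fold orientation and phases.
#' @return object of class `fcd_synth_hemi`: `pair` (`fcd_surface_pair`),
#'   `inflated` (`fcd_mesh`), and the analytic geometry record `geom`.
#' @export
make_hemisphere <- function(spec, side = c("left", "right"), seed = spec$seed) {
  side <- match.arg(side)
  ico <- icosphere(spec$subdivisions)
  frame_phase <- .with_seed(.run_seed(seed, 1), {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 3] <- -q[, 3]
    list(frame = q, phase = runif(2, 0, 2 * pi))
  })
  geom <- list(radius = spec$radius_mm, amplitude = spec$fold_amplitude_mm,
               freq = spec$fold_frequency, frame = frame_phase$frame,
               phase = frame_phase$phase, thickness = spec$thickness_mm,
               mirror = side == "right", lesion_cap = NULL)
  u <- ico$vertices
  if (geom$mirror) u <- u %*% diag(c(-1, 1, 1))
  rho <- .pial_radius(u, geom)
  ## smooth per-hemisphere radial displacement emulating surface
  ## reconstruction error; independent between hemispheres and surfaces
  recon <- .with_seed(.run_seed(seed, if (side == "left") 7 else 8), {
    lapply(1:2, function(i)
      .smooth_field_on_faces(rnorm(nrow(u)), ico$faces, 10))
  })
  scale_recon <- function(x) if (spec$recon_noise_mm > 0 && sd(x) > 0)
    x * spec$recon_noise_mm / sd(x) else 0 * x
  pial_v <- u * (rho + scale_recon(recon[[1L]]))
  white_v <- u * (rho - geom$thickness + scale_recon(recon[[2L]]))
  faces <- ico$faces
  if (geom$mirror) faces <- faces[, c(1L, 3L, 2L)]
  pial <- triangle_mesh(pial_v, faces)
  white <- triangle_mesh(white_v, faces)
  infl_v <- .smooth_coordinates(pial, 60)
  ## rescale the inflated surface back to the pial's mean radius so
  ## geodesic disc radii remain comparable between the two
  infl_v <- infl_v * mean(rho) / mean(sqrt(rowSums(infl_v^2)))
  inflated <- triangle_mesh(infl_v, faces)
  structure(list(pair = surface_pair(white, pial), inflated = inflated,
                 geom = geom, side = side), class = "fcd_synth_hemi")
}

## separable 3-D Gaussian blur of an array (reflecting boundaries)
.gaussian_blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  blur_first <- function(m) {
    n <- nrow(m)
    xp <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1), , drop = FALSE])
    f <- stats::filter(xp, k, sides = 2)
    matrix(f[(r + 1):(r + n), ], n)
  }
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- blur_first(matrix(a, d[ax]))
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

## voxel-center world coordinates and derived direction/radius fields
.volume_grid <- function(spec) {
  half <- ceiling(spec$radius_mm + spec$fold_amplitude_mm +
                  abs(spec$delta_thickness_mm) + 8)
  coords <- seq(-half, half, by = spec$voxel_mm)
  n <- length(coords)
  affine <- diag(c(spec$voxel_mm, spec$voxel_mm, spec$voxel_mm, 1))
  affine[1:3, 4] <- -half
  x <- array(coords, c(n, n, n))
  y <- aperm(x, c(2, 1, 3))
  z <- aperm(x, c(3, 2, 1))
  r <- sqrt(x^2 + y^2 + z^2)
  list(dim = c(n, n, n), affine = affine,
       u = cbind(as.vector(x), as.vector(y), as.vector(z)) /
         pmax(as.vector(r), 1e-9),
       r = as.vector(r))
}

#' Synthetic phantom volumes for one hemisphere
#'
#' Fills 1 mm isotropic T1, FLAIR and PET volumes from the analytic
#' compartment model of the hemisphere (WM inside the white surface, GM in
#' the cortical ribbon, CSF/background outside): T1 WM/GM/CSF = 120/80/30,
#' FLAIR = 70/100/20, PET = 40/100/10, plus i.i.d. Gaussian noise per
#' modality. If the hemisphere carries a planted lesion the lesional
#' signatures (thickened ribbon, blurred T1 interface, FLAIR
#' hyperintensity, PET hypometabolism) are baked into the noiseless fields
#' before noise is added.
#'
#' @param hemi an `fcd_synth_hemi` (possibly after [plant_lesion()]).
#' @param spec the `fcd_cohort_spec`.
#' @param seed seed for the noise fields (noise is drawn identically and
#'   scaled by `noise_sd`, so sd = 0 yields the noiseless field).
#' @return named list of `fcd_volume`s: `t1`, `flair`, `pet`.
#' @export
make_volumes <- function(hemi, spec, seed = spec$seed) {
  stopifnot(inherits(hemi, "fcd_synth_hemi"))
  g <- .volume_grid(spec)
  geom <- hemi$geom
  rho_p <- .pial_radius(g$u, geom)
  rho_w <- rho_p - geom$thickness
  if (!is.null(geom$lesion_cap))  # white surface is not displaced
    rho_w <- rho_w - geom$lesion_cap$delta *
      (as.vector(g$u %*% geom$lesion_cap$dir) >= geom$lesion_cap$cos_psi)
  wm <- g$r < rho_w
  gm <- !wm & g$r <= rho_p
  base <- function(v_wm, v_gm, v_bg) {
    out <- rep(v_bg, length(g$r))
    out[wm] <- v_wm
    out[gm] <- v_gm
    array(out, g$dim)
  }
  t1 <- base(120, 80, 30)
  flair <- base(70, 100, 20)
  pet <- base(40, 100, 10)
  if (!is.null(geom$lesion_cap)) {
    cap <- as.vector(g$u %*% geom$lesion_cap$dir) >= geom$lesion_cap$cos_psi
    flair[cap & g$r > rho_w - 2 & g$r <= rho_p] <-
      flair[cap & g$r > rho_w - 2 & g$r <= rho_p] * (1 + spec$flair_increase)
    pet[cap & gm] <- pet[cap & gm] * (1 - spec$pet_reduction)
    if (spec$blur_sigma_mm > 0) {
      blurred <- .gaussian_blur3d(t1, spec$blur_sigma_mm / spec$voxel_mm)
      sel <- cap & abs(g$r - rho_w) <= 3 * spec$blur_sigma_mm
      t1[sel] <- blurred[sel]
    }
  }
  noise <- .with_seed(.run_seed(seed, 2), {
    lapply(1:3, function(i) array(rnorm(prod(g$dim)), g$dim))
  })
  sd_ <- spec$noise_sd
  list(t1 = scalar_volume(t1 + sd_[["t1"]] * noise[[1L]], g$affine),
       flair = scalar_volume(flair + sd_[["flair"]] * noise[[2L]], g$affine),
       pet = scalar_volume(pet + sd_[["pet"]] * noise[[3L]], g$affine))
}

#' Plant an FCD-like lesion into a synthetic hemisphere
#'
#' The lesion is the geodesic disc of the configured radius centered on
#' `center` (on the pial surface). Inside it the pial surface is pushed
#' outward radially by the thickening effect; the analytic geometry record
#' gains a lesion cap so that subsequently generated volumes carry the
#' blurred T1 interface, FLAIR hyperintensity and PET hypometabolism. The
#' resection label is the lesion disc dilated by the resection margin.
#'
#' Call this *before* [make_volumes()] so the volumes include the lesion.
#'
#' @param hemi an `fcd_synth_hemi`.
#' @param spec the `fcd_cohort_spec`.
#' @param center lesion center vertex index.
#' @return the modified `fcd_synth_hemi`, with `lesion` and `resection`
#'   `fcd_label`s attached.
#' @export
plant_lesion <- function(hemi, spec, center) {
  stopifnot(inherits(hemi, "fcd_synth_hemi"))
  pial <- hemi$pair$pial
  n <- nrow(pial$vertices)
  center <- as.integer(center)
  if (center < 1L || center > n) stop("lesion center out of range")
  disc <- geodesic_neighborhood(pial, center, spec$lesion_radius_mm)
  res <- geodesic_neighborhood(pial, center,
                               spec$lesion_radius_mm + spec$resection_margin_mm)
  ## angular cap guaranteed to contain the geodesic disc
  rho_min <- spec$radius_mm - spec$fold_amplitude_mm
  cap <- list(dir = pial$vertices[center, ] /
                sqrt(sum(pial$vertices[center, ]^2)),
              cos_psi = cos(spec$lesion_radius_mm / rho_min),
              delta = spec$delta_thickness_mm)
  hemi$geom$lesion_cap <- cap
  if (spec$delta_thickness_mm != 0) {
    v <- pial$vertices
    idx <- disc$vertex
    rad <- sqrt(rowSums(v[idx, , drop = FALSE]^2))
    v[idx, ] <- v[idx, , drop = FALSE] * (rad + spec$delta_thickness_mm) / rad
    hemi$pair <- surface_pair(hemi$pair$white, triangle_mesh(v, pial$faces))
  }
  hemi$lesion <- vertex_label(disc$vertex, "lesion", n)
  hemi$resection <- vertex_label(res$vertex, "resection", n)
  hemi$lesion_center <- center
  hemi
}

#' Simulate one synthetic subject
#'
#' Generates both hemispheres (mirror images, exact homotopy), plants a
#' lesion on a random hemisphere and vertex for patients, and fills the
#' per-hemisphere phantom volumes.
#'
#' @param spec an `fcd_cohort_spec`.
#' @param id subject identifier string.
#' @param patient logical: plant a lesion?
#' @param seed subject seed.
#' @param center,side optional lesion center vertex and hemisphere
#'   (`"left"`/`"right"`); drawn from `seed` when omitted.
#' @return object of class `fcd_subject` with elements `id`, `hemis`
#'   (list `left`/`right` of `fcd_synth_hemi`), `volumes` (per hemisphere),
#'   `corr`, `lesion_side`.
#' @export
make_subject <- function(spec, id = "sub-01", patient = FALSE,
                         seed = spec$seed, center = NULL, side = NULL) {
  hemis <- list(left = make_hemisphere(spec, "left", seed),
                right = make_hemisphere(spec, "right", seed))
  n <- nrow(hemis$left$pair$pial$vertices)
  lesion_side <- NULL
  if (patient) {
    drawn <- .with_seed(.run_seed(seed, 3), {
      list(side = sample(c("left", "right"), 1L), center = sample.int(n, 1L))
    })
    if (is.null(side)) side <- drawn$side
    if (is.null(center)) center <- drawn$center
    hemis[[side]] <- plant_lesion(hemis[[side]], spec, center)
    lesion_side <- side
  }
  volumes <- list(left = make_volumes(hemis$left, spec, .run_seed(seed, 4)),
                  right = make_volumes(hemis$right, spec, .run_seed(seed, 5)))
  structure(list(id = id, hemis = hemis, volumes = volumes,
                 corr = homotopic_correspondence(seq_len(n)),
                 patient = patient, lesion_side = lesion_side,
                 seed = seed), class = "fcd_subject")
}

#' @export
print.fcd_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject %s (%s)%s\n", x$id,
              if (x$patient) "patient" else "control",
              if (!is.null(x$lesion_side))
                sprintf(", lesion on %s hemisphere", x$lesion_side) else ""))
  invisible(x)
}

#' Simulate a full cohort in memory
#'
#' Patients receive lesions at centers drawn without replacement across the
#' cohort from the master seed.
#'
#' @param spec an `fcd_cohort_spec`.
#' @return list with `subjects` (list of `fcd_subject`) and `manifest`.
#' @export
simulate_cohort <- function(spec) {
  n_total <- spec$n_patients + spec$n_controls
  n_vert <- 10 * 4^spec$subdivisions + 2
  draws <- .with_seed(.run_seed(spec$seed, 6), {
    list(centers = sample.int(n_vert, spec$n_patients),
         sides = sample(c("left", "right"), spec$n_patients, replace = TRUE))
  })
  subjects <- vector("list", n_total)
  manifest <- list(seed = spec$seed,
                   spec = unclass(spec)[setdiff(names(unclass(spec)), "")],
                   subjects = list())
  for (i in seq_len(n_total)) {
    patient <- i <= spec$n_patients
    id <- sprintf("sub-%02d", i)
    subjects[[i]] <- make_subject(
      spec, id, patient = patient, seed = .run_seed(spec$seed, 100 + i),
      center = if (patient) draws$centers[i] else NULL,
      side = if (patient) draws$sides[i] else NULL)
    manifest$subjects[[id]] <- list(
      id = id, group = if (patient) "patient" else "control",
      lesion_center = if (patient) draws$centers[i] else NA,
      lesion_side = if (patient) draws$sides[i] else NA)
  }
  list(subjects = subjects, manifest = manifest)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject FreeSurfer surfaces (white, pial, inflated), NIfTI
#' volumes, lesion/resection labels and a JSON manifest recording the seed,
#' the full specification and the planted lesion centers. All paths in the
#' manifest are relative, so the cohort directory is relocatable.
#'
#' @param spec an `fcd_cohort_spec`.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory?
#' @return the manifest, invisibly.
#' @export
generate_cohort <- function(spec, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force)
    stop("output directory ", dir, " exists and is not empty; use force = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(spec)
  for (s in sim$subjects) {
    sd_ <- file.path(dir, s$id)
    dir.create(sd_, showWarnings = FALSE)
    for (h in c("left", "right")) {
      hm <- s$hemis[[h]]
      write_surface(hm$pair$white, file.path(sd_, paste0(h, ".white")))
      write_surface(hm$pair$pial, file.path(sd_, paste0(h, ".pial")))
      write_surface(hm$inflated, file.path(sd_, paste0(h, ".inflated")))
      for (v in c("t1", "flair", "pet"))
        write_volume(s$volumes[[h]][[v]],
                     file.path(sd_, paste0(h, "_", v, ".nii.gz")))
      if (!is.null(hm$lesion)) {
        write_label(hm$lesion, file.path(sd_, paste0(h, ".lesion.label")),
                    coords = hm$pair$pial$vertices[hm$lesion$vertices, ,
                                                   drop = FALSE])
        write_label(hm$resection, file.path(sd_, paste0(h, ".resection.label")),
                    coords = hm$pair$pial$vertices[hm$resection$vertices, ,
                                                   drop = FALSE])
      }
    }
  }
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(sim$manifest)
}
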