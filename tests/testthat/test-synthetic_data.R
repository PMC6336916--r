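# Synthetic cohort generator: determinism, mirror construction, planted
# signatures and on-disk bookkeeping.

test_that("hemisphere generation is deterministic and mirror-exact", {
  spec <- tiny_spec(recon_noise_mm = 0)
  a <- make_hemisphere(spec, "left", seed = 5)
  b <- make_hemisphere(spec, "left", seed = 5)
  expect_identical(a$pair$pial$vertices, b$pair$pial$vertices)
  expect_identical(a$pair$white$faces, b$pair$white$faces)

  r <- make_hemisphere(spec, "right", seed = 5)
  mirrored <- a$pair$pial$vertices %*% diag(c(-1, 1, 1))
  expect_lt(max(abs(r$pair$pial$vertices - mirrored)), 1e-6)
  # both windings produce outward normals (positive mean curvature magnitude)
  expect_gt(mean(sign(rowSums(r$pair$pial$vertex_normals *
                              r$pair$pial$vertices))), 0.99)
})

test_that("the thickness baseline and lesional thickening are recovered", {
  spec <- tiny_spec(recon_noise_mm = 0, seed = 2)
  hemi <- make_hemisphere(spec, "left", seed = 2)
  th <- as.double(cortical_thickness(hemi$pair))
  expect_lt(max(abs(th - spec$thickness_mm)) / spec$thickness_mm, 0.02)

  planted <- plant_lesion(hemi, spec, center = 100L)
  th2 <- as.double(cortical_thickness(planted$pair))
  inl <- planted$lesion$vertices
  expect_equal(mean(th2[inl]) - mean(th2[-inl]), spec$delta_thickness_mm,
               tolerance = 0.02)
  expect_true(all(planted$lesion$vertices %in% planted$resection$vertices))
  expect_gt(length(planted$resection$vertices), length(planted$lesion$vertices))
})

test_that("noiseless volumes realize the analytic compartments", {
  spec <- tiny_spec(noise_sd = c(t1 = 0, flair = 0, pet = 0),
                    recon_noise_mm = 0, seed = 3)
  hemi <- make_hemisphere(spec, "left", seed = 3)
  vols <- make_volumes(hemi, spec, seed = 3)
  # corners are background/CSF
  d <- dim(vols$t1$data)
  corners <- rbind(c(1, 1, 1), c(d[1], 1, 1), c(1, d[2], d[3]), d)
  expect_true(all(vols$t1$data[corners] == 30))
  expect_true(all(vols$pet$data[corners] == 10))
  # gwc far from any lesion ~ GM/WM = 80/120 up to trilinear interface mixing
  g <- as.double(gwc(vols$t1, hemi$pair))
  expect_lt(abs(median(g, na.rm = TRUE) - 80 / 120), 0.05)
  # identical seeds give identical noise structure: sd 0 vs > 0 differ by
  # the scaled noise field only
  spec_n <- tiny_spec(noise_sd = c(t1 = 4, flair = 0, pet = 0),
                      recon_noise_mm = 0, seed = 3)
  vols_n <- make_volumes(hemi, spec_n, seed = 3)
  diff <- vols_n$t1$data - vols$t1$data
  expect_equal(sd(as.vector(diff)), 4, tolerance = 0.01)
  expect_identical(vols_n$flair$data, vols$flair$data)
})

test_that("planted lesions carry the radiological signature directions", {
  spec <- tiny_spec(noise_sd = c(t1 = 0, flair = 0, pet = 0),
                    recon_noise_mm = 0, seed = 4)
  sub <- make_subject(spec, "p", patient = TRUE, seed = 4)
  side <- sub$lesion_side
  hemi <- sub$hemis[[side]]
  inl <- hemi$lesion$vertices

  # PET -40% through the asymmetry index: 2(0.6-1)/1.6 = -0.5
  pet <- pet_hypointensity(sub$volumes$left$pet, sub$hemis$left$pair,
                           sub$volumes$right$pet, sub$hemis$right$pair)
  ai <- asymmetry_index(pet$left, pet$right, sub$corr)
  a <- as.double(if (side == "left") ai$left else ai$right)
  expect_equal(median(a[inl]), -0.5, tolerance = 0.05)

  # FLAIR hyperintensity inside the lesion
  fp <- flair_profile(sub$volumes[[side]]$flair, hemi$pair)
  expect_gt(median(fp$flair_50[inl]),
            1.10 * median(fp$flair_50[-inl], na.rm = TRUE))

  # GM/WM blurring pulls gwc toward 1 inside the lesion
  gg <- as.double(gwc(sub$volumes[[side]]$t1, hemi$pair))
  expect_gt(median(gg[inl]), median(gg[-inl], na.rm = TRUE))
})

test_that("zero effect sizes make patients look like controls", {
  spec <- tiny_spec(delta_thickness_mm = 0, blur_sigma_mm = 0,
                    flair_increase = 0, pet_reduction = 0, seed = 6)
  pat <- make_subject(spec, "p", patient = TRUE, seed = 6)
  ctl <- make_subject(spec, "c", patient = FALSE, seed = 6)
  for (h in c("left", "right")) {
    expect_identical(pat$volumes[[h]]$flair$data, ctl$volumes[[h]]$flair$data)
    expect_identical(pat$volumes[[h]]$pet$data, ctl$volumes[[h]]$pet$data)
    expect_identical(pat$hemis[[h]]$pair$white$vertices,
                     ctl$hemis[[h]]$pair$white$vertices)
    expect_identical(pat$hemis[[h]]$pair$pial$vertices,
                     ctl$hemis[[h]]$pair$pial$vertices)
  }
  expect_gt(length(pat$hemis[[pat$lesion_side]]$lesion$vertices), 0)
})

test_that("asymmetry maps vanish on a mirror-symmetric subject", {
  spec <- tiny_spec(noise_sd = c(t1 = 0, flair = 0, pet = 0),
                    recon_noise_mm = 0, seed = 7)
  sub <- make_subject(spec, "c", patient = FALSE, seed = 7)
  feat <- extract_features(sub, lcd_radius = 15)
  for (f in c("thickness", "gwc", "curv", "sulc", "lcd", "flair_50",
              "pet_hypo")) {
    a <- as.double(feat$left[[paste0("asym_", f)]])
    expect_lt(max(abs(a), na.rm = TRUE), 1e-9)
  }
})

test_that("cohorts are written with complete, reproducible bookkeeping", {
  spec <- tiny_spec(seed = 9)
  d1 <- withr::local_tempdir()
  man1 <- generate_cohort(spec, file.path(d1, "cohort"))
  expect_error(generate_cohort(spec, file.path(d1, "cohort")), "force")

  subs <- list.dirs(file.path(d1, "cohort"), recursive = FALSE)
  expect_length(subs, spec$n_patients + spec$n_controls)
  centers <- vapply(man1$subjects, function(s)
    if (identical(s$group, "patient")) s$lesion_center else NA_integer_,
    numeric(1))
  centers <- centers[!is.na(centers)]
  expect_length(centers, spec$n_patients)
  expect_false(anyDuplicated(centers) > 0)  # drawn without replacement

  # byte-identical manifests on regeneration with the same spec + seed
  d2 <- withr::local_tempdir()
  generate_cohort(spec, file.path(d2, "cohort"))
  expect_identical(readLines(file.path(d1, "cohort", "manifest.json")),
                   readLines(file.path(d2, "cohort", "manifest.json")))

  # the cohort reads back and the labels match the manifest
  back <- read_cohort(file.path(d1, "cohort"))
  expect_length(back$subjects, 4)
  pat <- Filter(function(s) s$patient, back$subjects)[[1]]
  expect_s3_class(pat$hemis[[pat$lesion_side]]$lesion, "fcd_label")
  expect_gt(length(pat$hemis[[pat$lesion_side]]$lesion$vertices), 0)
  ctl <- Filter(function(s) !s$patient, back$subjects)[[1]]
  expect_null(ctl$hemis$left$lesion)
})

test_that("every generated subject passes the feature operators cleanly", {
  spec <- tiny_spec(seed = 10)
  sub <- make_subject(spec, "s", patient = TRUE, seed = 10)
  feat <- extract_features(sub, lcd_radius = 15)
  X <- fcdsurf:::.features_as_matrix(feat)
  expect_lt(mean(is.na(X)), 0.01)  # essentially no masking away from edges
  expect_true(all(is.finite(X[!is.na(X)])))
})
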