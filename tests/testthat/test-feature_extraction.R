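# Multimodal feature operators: morphology, intensity, metabolism,
# asymmetry and doughnut contrast.

test_that("cortical thickness is the per-vertex white-pial distance", {
  g <- grid_mesh(8, 8, 2)
  same <- surface_pair(triangle_mesh(g$vertices, g$faces),
                       triangle_mesh(g$vertices, g$faces))
  expect_equal(as.double(cortical_thickness(same)), rep(0, same$n))

  pair <- planar_pair(z_white = 0, z_pial = 3)
  expect_equal(as.double(cortical_thickness(pair)), rep(3, pair$n))

  ico <- icosphere(2)
  spheres <- surface_pair(triangle_mesh(ico$vertices * 50, ico$faces),
                          triangle_mesh(ico$vertices * 53, ico$faces))
  expect_equal(as.double(cortical_thickness(spheres)), rep(3, spheres$n),
               tolerance = 1e-6)
})

test_that("gwc reproduces the sharp phantom ratio and moves toward 1 with blur", {
  pair <- planar_pair(z_white = 0, z_pial = 3)
  expect_equal(as.double(gwc(uniform_volume(100), pair)), rep(1, pair$n))

  sharp <- two_compartment_volume(gm = 80, wm = 120)
  g_sharp <- as.double(gwc(sharp, pair))
  expect_equal(g_sharp, rep(80 / 120, pair$n), tolerance = 1e-9)

  # blur the boundary: contrast must move strictly toward 1 at every vertex
  blurred <- scalar_volume(fcdsurf:::.gaussian_blur3d(sharp$data, 2),
                           sharp$affine)
  g_blur <- as.double(gwc(blurred, pair))
  expect_true(all(g_blur > g_sharp))
  expect_true(all(g_blur < 1))

  # trilinear oracle at the two sampling points of the blurred phantom
  center <- which.min(rowSums(pair$white$vertices[, 1:2]^2))
  xy <- pair$white$vertices[center, 1:2]
  gm_pt <- sample_volume(blurred, cbind(xy[1], xy[2], 0.9))
  wm_pt <- sample_volume(blurred, cbind(xy[1], xy[2], -1))
  expect_equal(g_blur[center], gm_pt / wm_pt, tolerance = 1e-9)

  # non-positive WM sample is masked
  neg <- fn_volume(function(x, y, z) ifelse(z >= 0, 80, -5))
  expect_true(all(is.na(gwc(neg, pair))))
})

test_that("the FLAIR profile is affine in depth on a ramp and flags blurring", {
  pair <- planar_pair(z_white = 0, z_pial = 3)
  u <- flair_profile(uniform_volume(77), pair)
  expect_equal(length(u), 6L)
  for (m in u) expect_equal(as.double(m), rep(77, pair$n))

  fp <- flair_profile(ramp_volume(), pair)
  depths <- c(0, 0.75, 1.5, 2.25, -0.5, -1)  # world z of each sample
  for (i in seq_along(depths))
    expect_equal(as.double(fp[[i]]), rep(depths[i], pair$n), tolerance = 1e-9)

  # blurring reduces the vertical gradient |boundary - 1 mm below|
  sharp <- two_compartment_volume(gm = 100, wm = 70)
  fb_sharp <- flair_profile(sharp, pair)
  blurred <- scalar_volume(fcdsurf:::.gaussian_blur3d(sharp$data, 2),
                           sharp$affine)
  fb_blur <- flair_profile(blurred, pair)
  grad_sharp <- as.double(fb_sharp$flair_0) - as.double(fb_sharp$flair_wm1)
  grad_blur <- as.double(fb_blur$flair_0) - as.double(fb_blur$flair_wm1)
  expect_true(all(abs(grad_blur) < abs(grad_sharp)))
})

test_that("local cortical deformation recovers 1/R^2 and ranks a bump highest", {
  p <- plane_mesh(31, 31, 2)
  lcd_p <- as.double(local_cortical_deformation(p, radius = 10))
  expect_true(all(abs(lcd_p[interior_vertices(p)]) < 1e-6, na.rm = TRUE))

  s <- sphere_mesh(50, 3)
  lcd_s <- as.double(local_cortical_deformation(s, radius = 25))
  expect_true(all(abs(lcd_s - 4e-4) / 4e-4 < 0.10))

  # one Gaussian bump on a plane: lcd maximal where the disc covers it
  g <- grid_mesh(41, 41, 1)
  v <- g$vertices
  v[, 3] <- 4 * exp(-(v[, 1]^2 + v[, 2]^2) / (2 * 3^2))
  bump <- triangle_mesh(v, g$faces)
  lcd_b <- as.double(local_cortical_deformation(bump, radius = 8))
  center <- which.min(rowSums(v[, 1:2]^2))
  far <- which(rowSums(v[, 1:2]^2) > 15^2 & !bump$boundary)
  expect_gt(lcd_b[center], max(lcd_b[far], na.rm = TRUE))
})

test_that("PET hypometabolism is normalized, scale-invariant and detects a disc", {
  pair <- planar_pair(z_white = 0, z_pial = 3)
  u <- pet_hypointensity(uniform_volume(100), pair)
  expect_equal(as.double(u$left), rep(1, pair$n), tolerance = 1e-12)

  disc_vol <- fn_volume(function(x, y, z)
    ifelse(x^2 + y^2 < 36, 60, 100))
  m <- pet_hypointensity(disc_vol, pair)
  # direct oracle: sampled uptake / area-weighted mean of sampled uptake
  raw <- as.double(sample_at_fraction(disc_vol, pair, 0.5))
  oracle <- raw / weighted.mean(raw, pair$white$vertex_areas)
  expect_equal(as.double(m$left), oracle, tolerance = 1e-12)
  inside <- rowSums(pair$white$vertices[, 1:2]^2) < 25
  expect_true(all(m$left[inside] < 0.75))

  scaled <- scalar_volume(disc_vol$data * 3.7, disc_vol$affine)
  expect_equal(as.double(pet_hypointensity(scaled, pair)$left),
               as.double(m$left), tolerance = 1e-12)

  neg <- fn_volume(function(x, y, z) rep(-1, length(x)))
  expect_error(pet_hypointensity(neg, pair), "not positive")
})

test_that("asymmetry index follows the 2(L-R)/(L+R) convention", {
  n <- 20
  corr <- homotopic_correspondence(seq_len(n))
  same <- asymmetry_index(rep(5, n), rep(5, n), corr)
  expect_equal(as.double(same$left), rep(0, n))

  ai <- asymmetry_index(rep(90, n), rep(110, n), corr)
  expect_equal(as.double(ai$left), rep(-0.2, n))
  expect_equal(as.double(ai$right), rep(0.2, n))

  # antisymmetry through a nontrivial correspondence
  set.seed(3)
  perm <- sample.int(n)
  corr2 <- homotopic_correspondence(perm)
  l <- runif(n, 50, 150); r <- runif(n, 50, 150)
  ai2 <- asymmetry_index(l, r, corr2)
  expect_equal(as.double(ai2$left), -as.double(ai2$right)[perm])

  # near-zero denominators are masked
  ai3 <- asymmetry_index(c(1, -1), c(2, 1), homotopic_correspondence(1:2))
  expect_true(is.na(ai3$left[2]))
})

test_that("doughnut maps equal the brute-force disc/annulus oracle", {
  m <- plane_mesh(25, 25, 1)
  const <- doughnut_map(rep(3.3, nrow(m$vertices)), m, radius = 3)
  expect_equal(as.double(const), rep(0, nrow(m$vertices)), tolerance = 1e-12)

  # indicator of the disc at a center vertex: strictly positive there
  center <- which.min(rowSums(m$vertices^2))
  nb <- geodesic_neighborhood(m, center, 3)
  ind <- numeric(nrow(m$vertices)); ind[nb$vertex] <- 1
  d <- doughnut_map(ind, m, radius = 3)
  expect_gt(d[center], 0)

  # brute-force oracle via geodesic_neighborhood at sampled vertices
  set.seed(5)
  for (v in sample(interior_vertices(m), 5)) {
    disc <- geodesic_neighborhood(m, v, 3)
    ring <- geodesic_neighborhood(m, v, 6)
    ann <- setdiff(ring$vertex, disc$vertex)
    o <- weighted.mean(ind[disc$vertex], m$vertex_areas[disc$vertex]) -
      weighted.mean(ind[ann], m$vertex_areas[ann])
    expect_equal(unname(d[v]), o, tolerance = 1e-9)
  }

  # linearity: negating the map negates the doughnut
  set.seed(9)
  x <- rnorm(nrow(m$vertices))
  expect_equal(as.double(doughnut_map(-x, m, radius = 3)),
               -as.double(doughnut_map(x, m, radius = 3)), tolerance = 1e-12)
})
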