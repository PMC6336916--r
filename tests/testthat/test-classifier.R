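# Training-set assembly, PCA, network training, folds and clustering.

make_fake_prepared <- function(id, patient, n = 30, p = 4, seed = 1,
                               lesion = 3:6, side = "left") {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * p), 2 * n, p)
  colnames(x) <- paste0("f", seq_len(p))
  list(id = id, patient = patient, x = x,
       registry = colnames(x), n = n,
       lesion = if (patient) vertex_label(lesion, "lesion", n),
       lesion_side = if (patient) side,
       corr = homotopic_correspondence(seq_len(n)))
}

test_that("training sets pair lesion vertices with contralateral homotopics", {
  s <- make_fake_prepared("p1", TRUE, lesion = c(3L, 5L, 9L), side = "left")
  s$features <- structure(list(registry = s$registry, n = s$n), class = "fcd_features")
  # use the internal row builder through assemble on a crafted subject
  rows <- fcdsurf:::.training_rows(s)
  expect_equal(rows$pos, c(3L, 5L, 9L))
  expect_equal(rows$neg, 30L + c(3L, 5L, 9L))
  s2 <- make_fake_prepared("p2", TRUE, lesion = c(2L, 4L), side = "right")
  rows2 <- fcdsurf:::.training_rows(s2)
  expect_equal(rows2$pos, 30L + c(2L, 4L))
  expect_equal(rows2$neg, c(2L, 4L))
})

test_that("assemble_training_set builds balanced labeled rows per subject", {
  spec <- tiny_spec(seed = 31)
  sub <- make_subject(spec, "p1", patient = TRUE, seed = 31)
  feat <- extract_features(sub, lcd_radius = 15)
  norm <- normalize_features(feat, sub, fwhm = 8)
  prep <- list(list(id = "p1", features = norm,
                    lesion = sub$hemis[[sub$lesion_side]]$lesion,
                    lesion_side = sub$lesion_side, corr = sub$corr))
  ts <- assemble_training_set(prep)
  expect_equal(sum(ts$y == 1), sum(ts$y == 0))
  expect_true(all(ts$meta$hemi[ts$y == 0] != sub$lesion_side))
  expect_false(anyNA(ts$x))
  # dropping a feature column changes width, not row count
  prep2 <- prep
  drop <- setdiff(norm$registry, "lcd")
  prep2[[1]]$features$registry <- drop
  ts2 <- assemble_training_set(prep2)
  expect_equal(ncol(ts2$x), ncol(ts$x) - 1L)
  expect_equal(nrow(ts2$x), nrow(ts$x))

  empty <- prep
  empty[[1]]$lesion <- vertex_label(integer(0), "lesion")
  expect_warning(expect_error(assemble_training_set(empty), "no usable"),
                 "empty lesion")
})

test_that("PCA retains the planned subspace", {
  set.seed(10)
  basis <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  scores <- matrix(rnorm(200), 100, 2) %*% t(basis)  # exactly rank 2 in 5-D
  pca <- fit_pca(scores, retained_variance = 0.95)
  expect_equal(pca$k, 2L)
  proj <- predict(pca, scores)
  recon <- proj %*% t(pca$rotation)
  expect_equal(recon, sweep(scores, 2, pca$center), tolerance = 1e-9)
  expect_equal(unname(as.matrix(crossprod(pca$rotation))), diag(2), tolerance = 1e-8)
  # the training mean projects to the origin
  expect_equal(as.double(predict(pca, matrix(colMeans(scores), 1))),
               rep(0, 2), tolerance = 1e-9)

  x <- matrix(rnorm(120), 40, 3)
  expect_equal(fit_pca(x, retained_variance = 1)$k, 3L)
  xc <- cbind(x, 5)
  expect_warning(p2 <- fit_pca(xc, 0.9), "constant")
  expect_equal(length(p2$kept), 3L)
})

test_that("the network separates well-separated blobs and agrees with nnet", {
  set.seed(20)
  n <- 200
  x <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = 6), n, 2))
  y <- rep(c(0L, 1L), each = n)
  net <- train_ann(x, y, hidden = 10, epochs = 300, seed = 5)
  p <- predict(net, x)
  expect_gte(mean((p >= 0.5) == (y == 1)), 0.95)
  expect_gte(net$metrics["test"], 0.95)

  # independent cross-check: nnet on the same problem
  ref <- nnet::nnet(x, y, size = 5, entropy = TRUE, trace = FALSE,
                    maxit = 200)
  pref <- as.double(predict(ref, x))
  expect_gte(mean((pref >= 0.5) == (p >= 0.5)), 0.95)

  expect_error(train_ann(x, rep(0L, 2 * n)), "both classes")
})

test_that("training is deterministic and invariant to row permutations", {
  set.seed(21)
  x <- matrix(rnorm(300), 100, 3)
  y <- as.integer(x[, 1] + rnorm(100, sd = 0.3) > 0)
  a <- train_ann(x, y, hidden = 4, epochs = 50, seed = 9)
  b <- train_ann(x, y, hidden = 4, epochs = 50, seed = 9)
  expect_identical(a$W, b$W)
  perm <- sample.int(100)
  c_ <- train_ann(x[perm, ], y[perm], hidden = 4, epochs = 50, seed = 9)
  expect_identical(a$W, c_$W)
  d <- train_ann(x, y, hidden = 4, epochs = 50, seed = 10)
  expect_false(identical(a$W, d$W))
})

test_that("detector predictions are probabilities and respect masks", {
  set.seed(22)
  x <- matrix(rnorm(400), 100, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- as.integer(rowSums(x[, 1:2]) > 0)
  det <- fcd_detector(x, y, retained_variance = 1, hidden = 5,
                      epochs = 100, seed = 2)
  p <- predict(det, x)
  expect_true(all(p >= 0 & p <= 1))
  # all-zero input: sigmoid of the bias path, still in [0, 1]
  p0 <- predict(det, matrix(0, 1, 4, dimnames = list(NULL, paste0("f", 1:4))))
  expect_true(p0 >= 0 && p0 <= 1)
  # masked rows give NA and do not disturb the others
  xna <- rbind(x[1:3, ], NA)
  pna <- predict(det, xna)
  expect_true(is.na(pna[4]))
  expect_equal(pna[1:3], p[1:3], tolerance = 1e-12)
  # registry mismatch names the missing feature
  bad <- x; colnames(bad) <- c("f1", "f2", "f3", "zz")
  expect_error(predict(det, bad), "f4")
  # round trip through serialization predicts identically
  f <- withr::local_tempfile(fileext = ".json")
  write_detector(det, f)
  expect_equal(predict(read_detector(f), x), p, tolerance = 1e-12)
})

test_that("fold assignments are balanced, exhaustive and seeded", {
  folds <- cv_folds(10, k = 5, iterations = 7, seed = 3)
  expect_length(folds, 7)
  for (f in folds) {
    expect_equal(sort(unique(f)), 1:5)
    expect_true(all(table(f) == 2))  # every subject held out exactly once
  }
  expect_identical(folds, cv_folds(10, k = 5, iterations = 7, seed = 3))
  expect_false(identical(folds, cv_folds(10, 5, 7, seed = 4)))
  expect_error(cv_folds(3, k = 5), "fewer subjects")
})

test_that("thresholded clusters match a flood-fill oracle", {
  m <- plane_mesh(20, 20, 1)
  n <- nrow(m$vertices)
  p <- rep(0.1, n)
  patch1 <- geodesic_neighborhood(m, which.min(rowSums(sweep(m$vertices, 2,
    c(-5, -5, 0))^2)), 2.5)$vertex
  patch2 <- geodesic_neighborhood(m, which.min(rowSums(sweep(m$vertices, 2,
    c(6, 6, 0))^2)), 3.5)$vertex
  p[patch1] <- 0.8
  p[patch2] <- 0.95
  cl <- threshold_and_cluster(p, m, threshold = 0.5)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$peak, 0.95)
  expect_setequal(cl[[1]]$vertices, patch2)
  expect_setequal(cl[[2]]$vertices, patch1)

  # igraph connected-component oracle on the suprathreshold subgraph
  supra <- which(p >= 0.5)
  sub <- igraph::subgraph_from_edges(
    igraph::graph_from_edgelist(m$edges, directed = FALSE),
    which(m$edges[, 1] %in% supra & m$edges[, 2] %in% supra),
    delete.vertices = FALSE)
  comp <- igraph::components(sub)$membership[supra]
  expect_equal(length(unique(comp)), 2)
  for (cc in unique(comp))
    expect_true(any(vapply(cl, function(k)
      setequal(k$vertices, supra[comp == cc]), logical(1))))

  expect_length(threshold_and_cluster(rep(0.2, n), m, 0.5), 0)
  big <- sum(m$vertex_areas) + 1
  expect_length(threshold_and_cluster(p, m, 0.5, min_area_mm2 = big), 0)
  expect_error(threshold_and_cluster(p, m, 1.5), "threshold")
})
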