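## Vertex-wise lesion classifier: training-set assembly, PCA reduction,
## feedforward neural network, subject-level cross-validation, probability
## maps and surface clustering.

#' Assemble a vertex-wise training set
#'
#' Builds the labeled feature matrix from patients with lesion labels:
#' label-1 rows are the lesion vertices of the lesional hemisphere, label-0
#' rows the homotopic vertices of the same lesion set on the contralateral
#' healthy hemisphere (equal counts by construction, so the classes are
#' balanced without reweighting). Row pairs in which either member carries
#' a masked feature are dropped symmetrically. Subjects with an empty
#' lesion label are skipped with a warning.
#'
#' @param subjects list of prepared subjects; each needs `features` (a
#'   normalized `fcd_features`), `lesion` (an `fcd_label`), `lesion_side`
#'   (`"left"`/`"right"`), `corr` (`fcd_homotopic`) and `id`.
#' @return list with `x` (rows x features matrix), `y` (0/1 labels), and
#'   `meta` (data.frame: subject, hemi, vertex).
#' @export
assemble_training_set <- function(subjects) {
  xs <- list(); ys <- list(); metas <- list()
  for (s in subjects) {
    if (is.null(s$lesion) || length(s$lesion$vertices) == 0L) {
      warning("subject ", s$id, " has an empty lesion label; skipped")
      next
    }
    feat <- s$features
    n <- feat$n
    X <- .features_as_matrix(feat)
    les <- s$lesion$vertices
    l2r <- s$corr$left_to_right
    if (s$lesion_side == "left") {
      pos <- les; neg <- n + l2r[les]
      neg_hemi <- "right"
    } else {
      pos <- n + les; neg <- match(les, l2r)
      neg_hemi <- "left"
    }
    keep <- !is.na(neg) & rowSums(is.na(X[pos, , drop = FALSE])) == 0L &
      rowSums(is.na(X[neg, , drop = FALSE])) == 0L
    pos <- pos[keep]; neg <- neg[keep]
    xs[[s$id]] <- X[c(pos, neg), , drop = FALSE]
    ys[[s$id]] <- rep(c(1L, 0L), each = length(pos))
    metas[[s$id]] <- data.frame(
      subject = s$id,
      hemi = rep(c(s$lesion_side, neg_hemi), each = length(pos)),
      vertex = c(les[keep], if (neg_hemi == "right") l2r[les][keep]
                 else match(les, l2r)[keep]))
  }
  if (length(xs) == 0L) stop("no usable training subjects")
  x <- do.call(rbind, xs)
  colnames(x) <- subjects[[1L]]$features$registry
  list(x = x, y = unlist(ys, use.names = FALSE),
       meta = do.call(rbind, metas))
}

#' Principal component reduction
#'
#' Centers the feature matrix and retains the smallest number of principal
#' components whose cumulative explained variance reaches
#' `retained_variance`. Constant columns are dropped with a warning before
#' the decomposition.
#'
#' @param x numeric matrix (rows = samples).
#' @param retained_variance fraction of variance to retain, in (0, 1].
#' @return object of class `fcd_pca`: `center`, `rotation` (p x k,
#'   orthonormal), `k`, `explained`, `kept` (column indices used).
#' @export
fit_pca <- function(x, retained_variance = 0.95) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (retained_variance <= 0 || retained_variance > 1)
    stop("retained_variance must be in (0, 1]")
  v <- apply(x, 2L, stats::var)
  kept <- which(v > 1e-12)
  if (length(kept) < ncol(x))
    warning("dropped ", ncol(x) - length(kept), " constant feature columns")
  p <- prcomp(x[, kept, drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  ev <- ev[ev > 1e-12 * ev[1L]]
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= retained_variance - 1e-12)[1L]
  structure(list(center = p$center,
                 rotation = p$rotation[, seq_len(k), drop = FALSE],
                 k = k, explained = cum[k], kept = kept),
            class = "fcd_pca")
}

#' @export
predict.fcd_pca <- function(object, newdata, ...) {
  nd <- newdata[, object$kept, drop = FALSE]
  sweep(nd, 2L, object$center) %*% object$rotation
}

## ---- feedforward network -------------------------------------------------

.sigmoid <- function(z) 1 / (1 + exp(-z))

.mlp_forward <- function(w, X) {
  acts <- list(X)
  a <- X
  for (l in seq_along(w$W)) {
    a <- .sigmoid(sweep(a %*% w$W[[l]], 2L, w$b[[l]], `+`))
    acts[[l + 1L]] <- a
  }
  acts
}

.xent <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Canonical row order: lexicographic in (label, features). Makes training
## exactly invariant to the order in which rows are presented.
.canonical_order <- function(X, y) {
  do.call(order, c(list(y), lapply(seq_len(ncol(X)), function(j) X[, j])))
}

#' Train a feedforward neural network vertex classifier
#'
#' Fully connected network with sigmoid hidden and output units, trained by
#' full-batch gradient descent (with momentum) on the cross-entropy loss.
#' Rows are first put into a canonical order and then split 70/15/15 into
#' training, validation and test subsets by a seeded shuffle; training uses
#' early stopping on the validation loss and reports accuracy on all three
#' splits. Training is exactly reproducible given the seed, and invariant
#' to permutations of the input rows.
#'
#' @param x numeric matrix of inputs (typically PCA scores).
#' @param y 0/1 labels; both classes must be present.
#' @param hidden integer vector of hidden-layer sizes.
#' @param epochs maximum training epochs.
#' @param learning_rate gradient-descent step size.
#' @param momentum momentum coefficient.
#' @param val_fraction,test_fraction validation/test split fractions.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed for initialization and splits.
#' @return object of class `fcd_mlp` with weights `W`, biases `b`, the
#'   training `history`, and `metrics` per split.
#' @export
train_ann <- function(x, y, hidden = 10, epochs = 500, learning_rate = 0.5,
                      momentum = 0.9, val_fraction = 0.15,
                      test_fraction = 0.15, patience = 30, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes")
  ord <- .canonical_order(x, y)
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  n <- nrow(x)
  sizes <- c(ncol(x), as.integer(hidden), 1L)
  init <- .with_seed(.run_seed(seed, 11), {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -r, r),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    perm <- sample.int(n)
    list(W = W, b = b, perm = perm)
  })
  n_val <- floor(val_fraction * n)
  n_test <- floor(test_fraction * n)
  idx_val <- init$perm[seq_len(n_val)]
  idx_test <- init$perm[n_val + seq_len(n_test)]
  idx_tr <- init$perm[-(seq_len(n_val + n_test))]
  Xtr <- x[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]
  Xval <- x[idx_val, , drop = FALSE]; yval <- y[idx_val]
  w <- list(W = init$W, b = init$b)
  vel <- list(W = lapply(w$W, function(m) m * 0),
              b = lapply(w$b, function(v) v * 0))
  best <- list(loss = Inf, w = w, epoch = 0L)
  hist <- matrix(NA_real_, epochs, 2L,
                 dimnames = list(NULL, c("train", "val")))
  stall <- 0L
  ntr <- nrow(Xtr)
  nl <- length(w$W)
  for (ep in seq_len(epochs)) {
    acts <- .mlp_forward(w, Xtr)
    p <- acts[[nl + 1L]][, 1L]
    if (!all(is.finite(p))) stop("non-finite network output at epoch ", ep)
    delta <- matrix((p - ytr) / ntr, ncol = 1L)
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        a <- acts[[l]]
        delta <- (delta %*% t(w$W[[l]])) * a * (1 - a)
      }
      vel$W[[l]] <- momentum * vel$W[[l]] - learning_rate * gW
      vel$b[[l]] <- momentum * vel$b[[l]] - learning_rate * gb
      w$W[[l]] <- w$W[[l]] + vel$W[[l]]
      w$b[[l]] <- w$b[[l]] + vel$b[[l]]
    }
    hist[ep, "train"] <- .xent(p, ytr)
    if (n_val > 0L) {
      pv <- .mlp_forward(w, Xval)[[nl + 1L]][, 1L]
      lv <- .xent(pv, yval)
      hist[ep, "val"] <- lv
      if (lv < best$loss - 1e-9) {
        best <- list(loss = lv, w = w, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    } else best <- list(loss = hist[ep, "train"], w = w, epoch = ep)
  }
  w <- best$w
  acc <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    p <- .mlp_forward(w, x[idx, , drop = FALSE])[[nl + 1L]][, 1L]
    mean((p >= 0.5) == (y[idx] == 1L))
  }
  structure(list(
    W = w$W, b = w$b, sizes = sizes, activation = "sigmoid",
    history = hist[!is.na(hist[, 1L]), , drop = FALSE],
    best_epoch = best$epoch,
    metrics = c(train = acc(idx_tr), validation = acc(idx_val),
                test = acc(idx_test)),
    config = list(hidden = hidden, epochs = epochs,
                  learning_rate = learning_rate, momentum = momentum,
                  val_fraction = val_fraction, test_fraction = test_fraction,
                  patience = patience, seed = seed)),
    class = "fcd_mlp")
}

#' @export
predict.fcd_mlp <- function(object, newdata, ...) {
  nl <- length(object$W)
  .mlp_forward(list(W = object$W, b = object$b),
               as.matrix(newdata))[[nl + 1L]][, 1L]
}

## ---- detector ------------------------------------------------------------

#' Fit the FCD vertex detector (PCA + feedforward network)
#'
#' The package's central model: a principal-component reduction of the
#' normalized multimodal feature set followed by a feedforward neural
#' network emitting a per-vertex lesion probability.
#'
#' @param x training matrix (rows = vertices, columns = registered
#'   features), e.g. from [assemble_training_set()].
#' @param y 0/1 vertex labels.
#' @param retained_variance PCA variance fraction to retain.
#' @param hidden hidden-layer sizes of the network.
#' @param ... further arguments passed to [train_ann()].
#' @param seed RNG seed.
#' @return object of class `fcd_detector`.
#' @seealso [predict.fcd_detector()], [predict_probability_map()],
#'   [threshold_and_cluster()]
#' @export
fcd_detector <- function(x, y, retained_variance = 0.95, hidden = 10,
                         seed = 1, ...) {
  stopifnot(is.matrix(x))
  pca <- fit_pca(x, retained_variance)
  scores <- predict(pca, x)
  net <- train_ann(scores, y, hidden = hidden, seed = seed, ...)
  structure(list(pca = pca, net = net,
                 registry = colnames(x),
                 n_train = nrow(x), seed = seed,
                 y = y, x = x),
            class = "fcd_detector")
}

#' @export
print.fcd_detector <- function(x, ...) {
  cat("FCD vertex detector\n")
  cat(sprintf("  features: %d -> %d principal components (%.1f%% variance)\n",
              length(x$registry) %||% ncol(x$x), x$pca$k,
              100 * x$pca$explained))
  cat(sprintf("  network: %s (sigmoid), trained on %d vertices\n",
              paste(x$net$sizes, collapse = "-"), x$n_train))
  cat(sprintf("  split accuracy: train %.3f, validation %.3f, test %.3f\n",
              x$net$metrics["train"], x$net$metrics["validation"],
              x$net$metrics["test"]))
  invisible(x)
}

#' @export
summary.fcd_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  early stopping at epoch %d of %d\n",
              object$net$best_epoch, object$net$config$epochs))
  invisible(object)
}

#' @export
coef.fcd_detector <- function(object, ...) {
  list(pca_rotation = object$pca$rotation, W = object$net$W, b = object$net$b)
}

#' @export
plot.fcd_detector <- function(x, ...) {
  h <- x$net$history
  graphics::matplot(h, type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "cross-entropy", ...)
  graphics::legend("topright", legend = colnames(h), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Predict vertex lesion probabilities
#'
#' @param object an `fcd_detector`.
#' @param newdata matrix with the detector's registered feature columns.
#'   Rows containing `NA` yield `NA` probabilities.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.fcd_detector <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$registry)) {
    missing <- setdiff(object$registry, colnames(newdata))
    if (length(missing))
      stop("newdata lacks registered features: ",
           paste(missing, collapse = ", "))
    newdata <- newdata[, object$registry, drop = FALSE]
  } else if (ncol(newdata) != length(object$pca$center) &&
             ncol(newdata) < max(object$pca$kept)) {
    stop("newdata has ", ncol(newdata), " columns; detector expects ",
         max(object$pca$kept))
  }
  out <- rep(NA_real_, nrow(newdata))
  ok <- rowSums(is.na(newdata)) == 0L
  if (any(ok))
    out[ok] <- predict(object$net, predict(object$pca,
                                           newdata[ok, , drop = FALSE]))
  out
}

#' @export
fitted.fcd_detector <- function(object, ...) predict(object, object$x)

#' @export
residuals.fcd_detector <- function(object, ...)
  object$y - fitted(object)

#' Per-vertex probability maps for a subject
#'
#' Applies the detector to every vertex of both hemispheres of a normalized
#' feature bundle; masked vertices stay masked.
#'
#' @param detector an `fcd_detector`.
#' @param feat a normalized `fcd_features` bundle.
#' @return list of `fcd_scalar_map`s `left` and `right` with values in
#'   `[0, 1]`.
#' @export
predict_probability_map <- function(detector, feat) {
  stopifnot(inherits(feat, "fcd_features"))
  X <- .features_as_matrix(feat)
  colnames(X) <- feat$registry
  p <- predict(detector, X)
  list(left = scalar_map(p[seq_len(feat$n)], "lesion_probability", "p"),
       right = scalar_map(p[feat$n + seq_len(feat$n)],
                          "lesion_probability", "p"))
}

## ---- clustering ----------------------------------------------------------

#' Threshold a probability map and extract surface clusters
#'
#' Connected components (mesh edge adjacency) of the vertices at or above
#' the probability threshold, filtered by minimal surface area and sorted
#' by peak probability (descending). An empty result is valid.
#'
#' @param prob_map per-vertex probabilities (`NA` = masked).
#' @param mesh the `fcd_mesh` the map lives on.
#' @param threshold probability cut, in (0, 1).
#' @param min_area_mm2 minimal cluster surface area.
#' @return list of `fcd_cluster` objects (`vertices`, `peak`,
#'   `peak_vertex`, `area_mm2`, `centroid_vertex`).
#' @export
threshold_and_cluster <- function(prob_map, mesh, threshold,
                                  min_area_mm2 = 0) {
  stopifnot(inherits(mesh, "fcd_mesh"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  p <- as.double(prob_map)
  n <- nrow(mesh$vertices)
  if (length(p) != n) stop("map length does not match the mesh")
  supra <- !is.na(p) & p >= threshold
  if (!any(supra)) return(list())
  comp <- integer(n)
  cid <- 0L
  for (v in which(supra)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      nb <- mesh$neighbors[[cur]]
      nb <- nb[supra[nb] & comp[nb] == 0L]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  clusters <- lapply(seq_len(cid), function(k) {
    vs <- which(comp == k)
    area <- sum(mesh$vertex_areas[vs])
    ctr <- colSums(mesh$vertices[vs, , drop = FALSE] *
                     mesh$vertex_areas[vs]) / area
    d2 <- rowSums(sweep(mesh$vertices[vs, , drop = FALSE], 2L, ctr)^2)
    structure(list(vertices = vs, peak = max(p[vs]),
                   peak_vertex = vs[which.max(p[vs])],
                   area_mm2 = area, centroid_vertex = vs[which.min(d2)]),
              class = "fcd_cluster")
  })
  clusters <- Filter(function(cl) cl$area_mm2 >= min_area_mm2, clusters)
  ## rank by peak probability; ties (e.g. saturated maps) broken by area
  clusters[order(vapply(clusters, `[[`, numeric(1L), "peak"),
                 vapply(clusters, `[[`, numeric(1L), "area_mm2"),
                 decreasing = TRUE)]
}

#' @export
print.fcd_cluster <- function(x, ...) {
  cat(sprintf("Cluster: %d vertices, %.1f mm^2, peak p = %.3f at vertex %d\n",
              length(x$vertices), x$area_mm2, x$peak, x$peak_vertex))
  invisible(x)
}
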