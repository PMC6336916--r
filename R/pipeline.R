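## Cohort-level orchestration: feature preparation, subject-level k-fold
## cross-validation, detector application and the patient-level report.

#' Prepare a subject for classification
#'
#' Runs feature extraction and the subject-local normalization stages
#' (surface smoothing, within-subject z-scoring). The between-subject stage
#' is deliberately deferred: it depends on the control cohort, and inside
#' cross-validation must be fit on training controls only.
#'
#' @param subject an `fcd_subject`.
#' @param fwhm smoothing kernel FWHM in mm.
#' @param ... passed to [extract_features()].
#' @return a prepared-subject list: `id`, `patient`, `x` (2N x p matrix of
#'   smoothed within-subject z-features), `registry`, `n`, `meshes`,
#'   `lesion`, `resection`, `lesion_side`, `corr`.
#' @export
prepare_subject <- function(subject, fwhm = 10, ...) {
  feat <- extract_features(subject, ...)
  norm <- normalize_features(feat, subject, fwhm = fwhm, stats = NULL)
  x <- .features_as_matrix(norm)
  colnames(x) <- norm$registry
  les_hemi <- subject$lesion_side
  list(id = subject$id, patient = isTRUE(subject$patient),
       x = x, registry = norm$registry, n = feat$n,
       meshes = list(left = subject$hemis$left$pair$pial,
                     right = subject$hemis$right$pair$pial),
       lesion = if (!is.null(les_hemi)) subject$hemis[[les_hemi]]$lesion,
       resection = if (!is.null(les_hemi)) subject$hemis[[les_hemi]]$resection,
       lesion_side = les_hemi, corr = subject$corr)
}

#' @rdname prepare_subject
#' @param subjects list of `fcd_subject`.
#' @export
prepare_cohort <- function(subjects, fwhm = 10, ...) {
  lapply(subjects, prepare_subject, fwhm = fwhm, ...)
}

## per-vertex control mean/sd (population) across prepared control subjects
.control_stats_matrix <- function(prepared, control_ids, sd_floor = 1e-6) {
  xs <- lapply(prepared[control_ids], `[[`, "x")
  if (length(xs) < 2L) stop("need at least 2 controls for normalization")
  m <- length(xs)
  s1 <- Reduce(`+`, lapply(xs, function(x) ifelse(is.na(x), 0, x)))
  s2 <- Reduce(`+`, lapply(xs, function(x) ifelse(is.na(x), 0, x^2)))
  k <- Reduce(`+`, lapply(xs, function(x) !is.na(x)))
  mu <- s1 / k
  sdv <- sqrt(pmax(s2 / k - mu^2, 0))
  bad <- k < 2L | sdv < sd_floor
  mu[bad] <- NA_real_
  sdv[bad] <- NA_real_
  list(mean = mu, sd = sdv)
}

.apply_control_stats <- function(x, st) (x - st$mean) / st$sd

## training rows of one prepared patient: lesion vertices + homotopic
## contralateral vertices, NA pairs dropped symmetrically
.training_rows <- function(s) {
  les <- s$lesion$vertices
  l2r <- s$corr$left_to_right
  if (s$lesion_side == "left") {
    pos <- les
    neg <- s$n + l2r[les]
  } else {
    pos <- s$n + les
    neg <- match(les, l2r)
  }
  list(pos = pos, neg = neg)
}

## clusters across both hemispheres for one subject's probability vector
.subject_clusters <- function(s, p, threshold, min_area_mm2) {
  cl_l <- threshold_and_cluster(p[seq_len(s$n)], s$meshes$left,
                                threshold, min_area_mm2)
  cl_r <- threshold_and_cluster(p[s$n + seq_len(s$n)], s$meshes$right,
                                threshold, min_area_mm2)
  for (i in seq_along(cl_l)) cl_l[[i]]$hemi <- "left"
  for (i in seq_along(cl_r)) cl_r[[i]]$hemi <- "right"
  cl <- c(cl_l, cl_r)
  cl[order(vapply(cl, `[[`, numeric(1L), "peak"),
           vapply(cl, `[[`, numeric(1L), "area_mm2"), decreasing = TRUE)]
}

## patient-level call for one subject at one threshold
.subject_call <- function(s, p, threshold, min_area_mm2, against = "lesion") {
  cl <- .subject_clusters(s, p, threshold, min_area_mm2)
  if (!s$patient)
    return(list(positive = length(cl) > 0L, concordant = NA, dice = NA_real_))
  ref <- s[[against]]
  if (length(cl) == 0L)
    return(list(positive = FALSE, concordant = FALSE, dice = 0))
  top <- cl[[1L]]
  hit <- top$hemi == s$lesion_side &&
    length(intersect(top$vertices, ref$vertices)) >= 1L
  dice <- if (top$hemi == s$lesion_side)
    2 * length(intersect(top$vertices, ref$vertices)) /
      (length(top$vertices) + length(ref$vertices)) else 0
  list(positive = TRUE, concordant = hit, dice = dice)
}

#' Youden-optimal probability threshold
#'
#' Scans a threshold grid and returns the value maximizing Youden's J: the
#' patient-level detection rate minus the control false-positive rate (ties
#' resolved toward the higher threshold).
#'
#' @param prepared list of prepared subjects (see [prepare_subject()]).
#' @param probs named list of per-subject probability vectors.
#' @param grid candidate thresholds.
#' @param min_area_mm2 minimal cluster area.
#' @return the selected threshold.
#' @export
choose_threshold <- function(prepared, probs, grid = c(seq(0.3, 0.9, by = 0.1), 0.95, 0.99),
                             min_area_mm2 = 150) {
  j <- vapply(grid, function(th) {
    det <- 0L; npat <- 0L; fp <- 0L; nctl <- 0L
    for (s in prepared) {
      call <- .subject_call(s, probs[[s$id]], th, min_area_mm2)
      if (s$patient) {
        npat <- npat + 1L
        det <- det + isTRUE(call$concordant)
      } else {
        nctl <- nctl + 1L
        fp <- fp + call$positive
      }
    }
    (if (npat > 0) det / npat else 0) - (if (nctl > 0) fp / nctl else 0)
  }, numeric(1L))
  grid[max(which(j == max(j)))]
}

#' Random subject-level fold assignments
#'
#' For each iteration, an independent random partition of the subjects into
#' k equal-sized folds (at subject level, so vertices of one subject never
#' straddle a fold boundary). Deterministic given the seed.
#'
#' @param n number of subjects.
#' @param k number of folds.
#' @param iterations number of independent re-partitions.
#' @param seed RNG seed.
#' @return list of length `iterations`; each an integer vector of fold ids.
#' @export
cv_folds <- function(n, k = 5, iterations = 100, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer subjects (", n, ") than folds (", k, ")")
  .with_seed(.run_seed(seed, 21), {
    lapply(seq_len(iterations), function(i)
      sample(rep_len(seq_len(k), n)))
  })
}

#' Subject-level k-fold cross-validation of the detector
#'
#' For each of `iterations` random k-partitions of the cohort, each fold is
#' held out in turn: the between-subject normalization is fit on the
#' training controls, the detector is trained on the training patients'
#' lesion and homotopic non-lesion vertices, the probability threshold is
#' chosen on the training subjects by Youden's J (unless fixed), and the
#' held-out subjects are called at patient level (major cluster overlapping
#' the lesion label for patients; any cluster counting as a false positive
#' for controls).
#'
#' @param prepared prepared cohort from [prepare_cohort()].
#' @param k number of folds.
#' @param iterations number of re-randomized iterations.
#' @param seed RNG seed (folds and network initializations).
#' @param retained_variance,hidden detector hyperparameters.
#' @param threshold fixed probability threshold, or `NULL` for Youden.
#' @param min_area_mm2 minimal cluster area.
#' @param against reference label for patient concordance: `"lesion"` or
#'   `"resection"`.
#' @param ... further arguments to [train_ann()].
#' @return object of class `fcd_cv`: per-fold metrics, their mean/sd
#'   summary, pooled confusion counts and the per-subject call table.
#' @export
cross_validate <- function(prepared, k = 5, iterations = 100, seed = 1,
                           retained_variance = 0.95, hidden = 10,
                           threshold = NULL, min_area_mm2 = 150,
                           against = "lesion", ...) {
  n <- length(prepared)
  ids <- vapply(prepared, `[[`, character(1L), "id")
  names(prepared) <- ids
  is_pat <- vapply(prepared, `[[`, logical(1L), "patient")
  folds <- cv_folds(n, k, iterations, seed)
  fold_rows <- list()
  calls <- list()
  pooled <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  for (it in seq_len(iterations)) {
    assign_ <- folds[[it]]
    for (fold in seq_len(k)) {
      test_ids <- ids[assign_ == fold]
      train_ids <- ids[assign_ != fold]
      tr_pat <- train_ids[is_pat[train_ids]]
      tr_ctl <- train_ids[!is_pat[train_ids]]
      if (length(tr_pat) == 0L || length(tr_ctl) < 2L)
        stop("fold without training patients or controls; reduce k")
      st <- .control_stats_matrix(prepared, tr_ctl)
      xs <- list(); ys <- list()
      for (id in tr_pat) {
        s <- prepared[[id]]
        z <- .apply_control_stats(s$x, st)
        rows <- .training_rows(s)
        keep <- !is.na(rows$neg) &
          rowSums(is.na(z[rows$pos, , drop = FALSE])) == 0L &
          rowSums(is.na(z[rows$neg, , drop = FALSE])) == 0L
        xs[[id]] <- z[c(rows$pos[keep], rows$neg[keep]), , drop = FALSE]
        ys[[id]] <- rep(c(1L, 0L), each = sum(keep))
      }
      x <- do.call(rbind, xs)
      colnames(x) <- prepared[[1L]]$registry
      det <- fcd_detector(x, unlist(ys, use.names = FALSE),
                          retained_variance = retained_variance,
                          hidden = hidden,
                          seed = .run_seed(seed, 1000 * it + fold), ...)
      predict_subject <- function(id)
        predict(det, .apply_control_stats(prepared[[id]]$x, st))
      th <- threshold
      if (is.null(th)) {
        probs_tr <- lapply(train_ids, predict_subject)
        names(probs_tr) <- train_ids
        th <- choose_threshold(prepared[train_ids], probs_tr,
                               min_area_mm2 = min_area_mm2)
      }
      cts <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
      for (id in test_ids) {
        s <- prepared[[id]]
        call <- .subject_call(s, predict_subject(id), th, min_area_mm2,
                              against = against)
        if (s$patient) {
          if (isTRUE(call$concordant)) cts["tp"] <- cts["tp"] + 1L
          else cts["fn"] <- cts["fn"] + 1L
        } else {
          if (call$positive) cts["fp"] <- cts["fp"] + 1L
          else cts["tn"] <- cts["tn"] + 1L
        }
        calls[[length(calls) + 1L]] <- data.frame(
          iteration = it, fold = fold, subject = id,
          patient = s$patient, positive = call$positive,
          concordant = if (s$patient) call$concordant else NA,
          dice = call$dice, threshold = th)
      }
      pooled <- pooled + cts
      m <- confusion_metrics(confusion_counts(cts["tp"], cts["fn"],
                                              cts["fp"], cts["tn"]))
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        iteration = it, fold = fold, threshold = th,
        sensitivity = m["sensitivity"], specificity = m["specificity"],
        accuracy = m["accuracy"], row.names = NULL)
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  summ <- sapply(c("sensitivity", "specificity", "accuracy"), function(f)
    c(mean = mean(folds_df[[f]], na.rm = TRUE),
      sd = sd(folds_df[[f]], na.rm = TRUE)))
  structure(list(folds = folds_df, summary = summ,
                 counts = confusion_counts(pooled["tp"], pooled["fn"],
                                           pooled["fp"], pooled["tn"]),
                 calls = do.call(rbind, calls),
                 k = k, iterations = iterations, seed = seed),
            class = "fcd_cv")
}

#' @export
print.fcd_cv <- function(x, ...) {
  cat(sprintf("Subject-level %d-fold cross-validation, %d iteration(s)\n",
              x$k, x$iterations))
  cm <- confusion_metrics(x$counts)
  cat(sprintf("  pooled: TP %d, FN %d, FP %d, TN %d\n",
              x$counts$tp, x$counts$fn, x$counts$fp, x$counts$tn))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              cm["sensitivity"], cm["specificity"], cm["accuracy"]))
  invisible(x)
}

#' Patient-level evaluation report
#'
#' Turns pooled confusion counts into the cohort summary: sensitivity,
#' specificity, accuracy, and Cohen's kappa (with band) of the agreement
#' between ground truth and the automated calls.
#'
#' @param counts an `fcd_confusion`.
#' @return list with `counts`, `metrics`, `kappa`, `agreement_table`.
#' @export
evaluation_report <- function(counts) {
  stopifnot(inherits(counts, "fcd_confusion"))
  tab <- matrix(c(counts$tp, counts$fn, counts$fp, counts$tn), 2L, 2L,
                byrow = TRUE,
                dimnames = list(truth = c("patient", "control"),
                                call = c("positive", "negative")))
  list(counts = unclass(counts), metrics = as.list(confusion_metrics(counts)),
       kappa = cohens_kappa(tab), agreement_table = tab)
}
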