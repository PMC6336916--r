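# Patient-level agreement statistics and their worked examples.

test_that("confusion metrics reproduce the cohort worked example", {
  m <- confusion_metrics(confusion_counts(31, 9, 13, 20))
  expect_equal(unname(m["sensitivity"]), 31 / 40)      # 77.5%
  expect_equal(unname(m["specificity"]), 20 / 33)      # 60.6%
  expect_equal(round(100 * unname(m["accuracy"]), 1), 69.9)

  expect_equal(unname(confusion_metrics(confusion_counts(1, 1, 1, 1))),
               rep(0.5, 3))
  expect_equal(unname(confusion_metrics(confusion_counts(5, 0, 0, 7))),
               rep(1, 3))
  expect_true(is.na(confusion_metrics(confusion_counts(0, 0, 2, 3))["sensitivity"]))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("accuracy is the class-size weighted mean of sensitivity and specificity", {
  set.seed(12)
  for (i in 1:50) {
    cts <- confusion_counts(sample(0:30, 1) + 1, sample(0:30, 1),
                            sample(0:30, 1), sample(0:30, 1) + 1)
    m <- confusion_metrics(cts)
    npat <- cts$tp + cts$fn; nctl <- cts$fp + cts$tn
    expect_equal(unname(m["accuracy"]),
                 (npat * m[["sensitivity"]] + nctl * m[["specificity"]]) /
                   (npat + nctl), tolerance = 1e-12)
  }
})

test_that("Cohen's kappa reproduces the agreement worked example and bands", {
  k <- cohens_kappa(matrix(c(31, 9, 13, 20), 2, byrow = TRUE))
  expect_equal(round(k$kappa, 3), 0.385)
  expect_equal(k$band, "fair")

  expect_equal(cohens_kappa(diag(c(10, 15)))$kappa, 1)
  expect_equal(cohens_kappa(diag(c(10, 15)))$band, "almost perfect")
  # identical rows: agreement at chance level
  expect_equal(cohens_kappa(matrix(c(4, 6, 4, 6), 2, byrow = TRUE))$kappa, 0)
  expect_equal(cohens_kappa(matrix(c(4, 6, 4, 6), 2, byrow = TRUE))$band,
               "slight")
  # boundary values belong to the lower band; symmetric tables with
  # diagonal d and off-diagonal o have kappa = (d - o)/(d + o) exactly
  expect_equal(cohens_kappa(matrix(c(6, 4, 4, 6), 2))$band, "slight")    # 0.2
  expect_equal(cohens_kappa(matrix(c(7, 3, 3, 7), 2))$band, "fair")      # 0.4
  expect_equal(cohens_kappa(matrix(c(15, 5, 5, 15), 2))$band, "moderate") # 0.5
  # transpose invariance
  set.seed(8)
  for (i in 1:20) {
    t_ <- matrix(rpois(4, 10), 2)
    expect_equal(cohens_kappa(t_)$kappa, cohens_kappa(t(t_))$kappa,
                 tolerance = 1e-12)
  }
})

test_that("the uncorrected chi-square reproduces the demographic comparisons", {
  sex <- pearson_chi_square(matrix(c(19, 21, 17, 16), 2, byrow = TRUE))
  expect_equal(round(sex$statistic, 3), 0.117)
  expect_equal(round(sex$p, 3), 0.733)
  hemi <- pearson_chi_square(matrix(c(21, 19, 18, 15), 2, byrow = TRUE))
  expect_equal(round(hemi$statistic, 3), 0.030)
  expect_equal(round(hemi$p, 3), 0.862)
  expect_equal(sex$df, 1L)

  # exactly proportional table -> 0
  expect_equal(pearson_chi_square(matrix(c(10, 20, 5, 10), 2,
                                         byrow = TRUE))$statistic, 0)
  # invariance under row/column swaps
  t_ <- matrix(c(12, 7, 9, 21), 2)
  expect_equal(pearson_chi_square(t_)$statistic,
               pearson_chi_square(t_[2:1, ])$statistic)
  expect_equal(pearson_chi_square(t_)$statistic,
               pearson_chi_square(t_[, 2:1])$statistic)
  expect_warning(pearson_chi_square(matrix(c(2, 3, 4, 5), 2)), "fisher")
})

test_that("chi-square agrees with brute-force computation on random tables", {
  set.seed(99)
  for (i in 1:1000) {
    t_ <- matrix(rpois(4, 20) + 1, 2)
    got <- pearson_chi_square(t_)$statistic
    e <- outer(rowSums(t_), colSums(t_)) / sum(t_)
    expect_equal(got, sum((t_ - e)^2 / e), tolerance = 1e-12)
  }
  # and with stats::chisq.test without continuity correction
  t_ <- matrix(c(19, 21, 17, 16), 2, byrow = TRUE)
  expect_equal(pearson_chi_square(t_)$statistic,
               unname(stats::chisq.test(t_, correct = FALSE)$statistic),
               tolerance = 1e-12)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  # [[2,0],[0,2]]: all tables with margins (2,2)x(2,2); p(two-sided) = 1/3
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  # enumeration oracle for a second table
  t_ <- matrix(c(3, 1, 1, 4), 2)
  probs <- dhyper(0:4, 4, 5, 4)
  obs <- dhyper(3, 4, 5, 4)
  expect_equal(fisher_exact(t_), sum(probs[probs <= obs + 1e-12]),
               tolerance = 1e-9)
})

test_that("Mann-Whitney U behaves at the reference points", {
  set.seed(13)
  x <- rnorm(12)
  same <- mann_whitney_u(x, x)
  expect_gt(same$p, 0.95)
  sep <- mann_whitney_u(1:10, 21:30)
  expect_equal(unname(sep$U), 0)
  expect_lt(sep$p, 0.001)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("concordance counts only the major cluster", {
  res <- vertex_label(10:20, "resection")
  expect_false(concordance(list(), res)$concordant)

  cl <- function(v, peak) structure(list(vertices = v, peak = peak,
                                         area_mm2 = 10 * length(v)),
                                    class = "fcd_cluster")
  inside <- concordance(list(cl(12:14, 0.9)), res)
  expect_true(inside$concordant)
  expect_equal(inside$dice, 2 * 3 / (3 + 11))
  # top cluster disjoint, second overlapping: not concordant
  two <- concordance(list(cl(50:55, 0.95), cl(12:14, 0.9)), res)
  expect_false(two$concordant)
  expect_error(concordance(list(), vertex_label(integer(0), "resection")),
               "empty")
})

test_that("the evaluation report composes counts, metrics and kappa", {
  rep_ <- evaluation_report(confusion_counts(31, 9, 13, 20))
  expect_equal(round(100 * rep_$metrics[["accuracy"]], 1), 69.9)
  expect_equal(round(rep_$kappa$kappa, 3), 0.385)
  expect_equal(rep_$agreement_table[1, 1], 31)
})
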