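test_that("map evaluation against reference points counts correctly", {
  set.seed(61)
  truth <- elev_grid(matrix(as.numeric(runif(100) < 0.4), 10, 10),
                     cell_size = 10)
  pts <- sample_ground_truth(truth, 20, 20, seed = 3)

  cm_same <- evaluate_map(truth, pts)
  expect_equal(c(cm_same$fn, cm_same$fp), c(0, 0))
  expect_equal(c(cm_same$tp, cm_same$tn), c(20, 20))

  comp <- elev_grid(1 - truth$values, 10)
  cm_comp <- evaluate_map(comp, pts)
  expect_equal(c(cm_comp$tp, cm_comp$tn), c(0, 0))

  for (i in 1:5) {
    m <- elev_grid(matrix(as.numeric(runif(100) < 0.5), 10, 10), 10)
    cm <- evaluate_map(m, pts)
    mapped <- value_at(m, pts$x, pts$y) != 0
    truthv <- pts$true_class == "cliff"
    expect_equal(cm$tp, sum(mapped & truthv))
    expect_equal(cm$fp, sum(mapped & !truthv))
    expect_equal(cm$fn + cm$tn, sum(!mapped))
  }
})

test_that("published confusion counts reproduce the printed metrics", {
  t2 <- table2_counts
  expect_equal(vapply(t2, overall_accuracy, numeric(1)),
               c(sv = 100, s_min = 94, s_25 = 79, s_50 = 72))
  expect_equal(vapply(t2, producers_accuracy, numeric(1)),
               c(sv = 100, s_min = 98, s_25 = 58, s_50 = 44))
  expect_equal(vapply(t2, omission_error_rate, numeric(1)),
               c(sv = 0, s_min = 0.02, s_25 = 0.42, s_50 = 0.56))
  expect_equal(vapply(t2, commission_error_rate, numeric(1)),
               c(sv = 0, s_min = 0.10, s_25 = 0, s_50 = 0))
  expect_equal(vapply(t2, users_accuracy, numeric(1)),
               c(sv = 100, s_min = 90, s_25 = 100, s_50 = 100))
  expect_equal(cohens_kappa(t2$sv), 1)
})

test_that("both user's-accuracy conventions are available and distinct", {
  cm <- table2_counts$s_min
  expect_equal(users_accuracy(cm, convention = "map"), 100 * 49 / 54)
  expect_equal(users_accuracy(cm, convention = "reference"), 90)
  expect_equal(commission_error_rate(cm, "map"), 5 / 54)
  expect_equal(commission_error_rate(cm, "reference"), 0.10)
  # no false positives -> 100 under both conventions
  expect_equal(users_accuracy(table2_counts$s_25, convention = "map"), 100)
  expect_equal(users_accuracy(table2_counts$s_25,
                              convention = "reference"), 100)
})

test_that("kappa follows the closed form, not the printed coefficients", {
  expect_equal(cohens_kappa(table2_counts$s_min), 0.88)
  expect_equal(cohens_kappa(table2_counts$s_25), 0.58)
  expect_equal(cohens_kappa(table2_counts$s_50), 0.44)
})

test_that("kappa is zero under chance agreement and follows the balanced identity", {
  # counts proportional to marginals: po == pe
  expect_equal(cohens_kappa(confusion_2x2(tp = 12, fn = 28,
                                          fp = 18, tn = 42)), 0)
  set.seed(71)
  for (i in 1:20) {
    tp <- sample(0:50, 1); fn <- 50 - tp
    fp <- sample(0:50, 1); tn <- 50 - fp
    cm <- confusion_2x2(tp, fn, fp, tn)
    po <- (tp + tn) / 100
    expect_equal(cohens_kappa(cm), 2 * po - 1)
  }
})

test_that("metrics are invariant when all counts are scaled", {
  set.seed(81)
  for (i in 1:10) {
    counts <- sample(1:40, 4)
    k <- sample(2:7, 1)
    a <- confusion_2x2(counts[1], counts[2], counts[3], counts[4])
    b <- confusion_2x2(counts[1] * k, counts[2] * k,
                       counts[3] * k, counts[4] * k)
    expect_equal(overall_accuracy(a), overall_accuracy(b))
    expect_equal(producers_accuracy(a), producers_accuracy(b))
    expect_equal(users_accuracy(a), users_accuracy(b))
    expect_equal(omission_error_rate(a), omission_error_rate(b))
    expect_equal(commission_error_rate(a), commission_error_rate(b))
    expect_equal(cohens_kappa(a), cohens_kappa(b))
  }
})

test_that("overall accuracy is the reference-weighted producer mean", {
  set.seed(91)
  for (i in 1:10) {
    cm <- confusion_2x2(sample(1:30, 1), sample(1:30, 1),
                        sample(1:30, 1), sample(1:30, 1))
    n_cliff <- cm$tp + cm$fn
    n_non <- cm$fp + cm$tn
    expect_equal(overall_accuracy(cm),
                 (n_cliff * producers_accuracy(cm, "cliff") +
                    n_non * producers_accuracy(cm, "non-cliff")) /
                   (n_cliff + n_non))
  }
})

test_that("degenerate confusion matrices raise undefined-ratio errors", {
  expect_error(overall_accuracy(confusion_2x2(0, 0, 0, 0)), "points")
  expect_error(producers_accuracy(confusion_2x2(0, 0, 3, 7)), "cliff")
  expect_error(users_accuracy(confusion_2x2(5, 5, 0, 0),
                              convention = "reference"), "non-cliff")
  expect_error(confusion_2x2(-1, 0, 0, 0), "non-negative")
})

test_that("stratified sampling allocates 100 points as 14-15 per square", {
  truth <- elev_grid(matrix(rep(c(1, 0), 350), 25, 28), cell_size = 10)
  strata <- lapply(1:7, function(s) {
    m <- matrix(FALSE, 25, 28)
    m[, (4 * s - 3):(4 * s)] <- TRUE
    m
  })
  pts <- sample_ground_truth(truth, 50, 50, strata = strata, seed = 17)
  expect_equal(nrow(pts), 100)
  expect_equal(sum(pts$true_class == "cliff"), 50)
  per_stratum <- table(pts$stratum)
  expect_true(all(per_stratum %in% c(14, 15)))
})

test_that("ground-truth sampling is seeded, classed, and without replacement", {
  set.seed(101)
  truth <- elev_grid(matrix(as.numeric(runif(400) < 0.3), 20, 20), 10)
  a <- sample_ground_truth(truth, 30, 30, seed = 5)
  b <- sample_ground_truth(truth, 30, 30, seed = 5)
  expect_identical(a, b)
  c_ <- sample_ground_truth(truth, 30, 30, seed = 6)
  expect_false(identical(a, c_))
  expect_false(any(duplicated(a[, c("x", "y")])))
  expect_equal(value_at(truth, a$x, a$y) != 0, a$true_class == "cliff")

  none <- sample_ground_truth(truth, 0, 10, seed = 1)
  expect_true(all(none$true_class == "non-cliff"))
})

test_that("infeasible strata error under strict sampling and redistribute otherwise", {
  truth <- elev_grid(cbind(matrix(1, 10, 2), matrix(0, 10, 8)), 10)
  strata <- list(rbind(matrix(TRUE, 5, 10), matrix(FALSE, 5, 10)),
                 rbind(matrix(FALSE, 5, 10), matrix(TRUE, 5, 10)))
  # 30 cliff points but only 20 cliff cells in total
  expect_error(sample_ground_truth(truth, 30, 10, strata = strata,
                                   strict = FALSE), "cells")
  # 14 points need 7 per stratum; feasible only by redistribution when a
  # stratum is partly masked out
  region <- matrix(TRUE, 10, 10); region[1:5, 1] <- FALSE
  expect_error(sample_ground_truth(truth, 14, 0, strata = strata,
                                   region_mask = region, seed = 2),
               "stratum 1")
  pts <- sample_ground_truth(truth, 14, 0, strata = strata,
                             region_mask = region, seed = 2,
                             strict = FALSE)
  expect_equal(nrow(pts), 14)
  expect_equal(sum(pts$stratum == 1), 5)
})
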