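test_that("euclidean error and the strict 10 mm failure rule", {
  expect_equal(euclidean_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_error(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(euclidean_error(a, b), euclidean_error(b, a))
  }
  expect_false(failure_flag(9.9))
  expect_false(failure_flag(10.0))   # "larger than 10 mm" is strict
  expect_true(failure_flag(10.1))
})

test_that("localization statistics summarize errors and failure rate", {
  s <- localization_stats(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$failures, 0)

  errs <- c(rep(2, 82), 11, 12, 13)   # 3 failures among 85
  s2 <- localization_stats(errs)
  expect_equal(s2$failures, 3)
  expect_equal(s2$error_rate, 3 / 85)
  expect_equal(round(100 * s2$error_rate, 1), 3.5)

  s3 <- localization_stats(rep(0, 5))
  expect_equal(c(s3$mean, s3$sd, s3$error_rate), c(0, 0, 0))
  expect_error(localization_stats(numeric(0)), "empty")
})

test_that("confusion matrices count predicted-by-true pairs", {
  p <- factor(c("femoral", "middle", "tibial"),
              levels = c("femoral", "middle", "tibial"))
  cm <- confusion(p, p)
  expect_equal(diag(cm), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(sum(cm), 3)

  cm2 <- confusion("middle", "femoral")
  expect_equal(cm2["middle", "femoral"], 1, ignore_attr = TRUE)
  expect_equal(sum(cm2), 1)
  expect_error(confusion(c("middle", "middle"), "femoral"), "mismatch")

  # bundled 3D-CNN benchmark matrix has the study's true-class totals
  cm3 <- acl_reader_confusions()$cnn3d
  expect_equal(colSums(cm3), c(43, 35, 7), ignore_attr = TRUE)
})

test_that("one-vs-rest metrics follow the standard formulas", {
  m <- class_metrics(acl_reader_confusions()$cnn3d)
  fem <- m$per_class[m$per_class$class == "femoral", ]
  expect_equal(fem$sensitivity, 37 / 43, tolerance = 1e-12)
  expect_equal(fem$specificity, 33 / 42, tolerance = 1e-12)
  expect_equal(m$overall_accuracy, 67 / 85, tolerance = 1e-12)

  perfect <- class_metrics(diag(c(10, 10, 10)))
  expect_true(all(unlist(perfect$per_class[-1]) == 1))
  expect_equal(perfect$overall_accuracy, 1)

  tib2d <- class_metrics(acl_reader_confusions()$cnn2d)$per_class
  expect_equal(tib2d$f1[tib2d$class == "tibial"], 1 / 6, tolerance = 1e-12)

  # zero denominators surface as NA, never silently as 0 or 1
  cm0 <- matrix(c(5, 0, 0, 3, 0, 0, 2, 0, 0), 3, 3)
  m0 <- class_metrics(cm0)
  expect_true(is.na(m0$per_class$precision[2]))  # middle row empty
  expect_true(is.na(m0$per_class$sensitivity[3]) ||
                m0$per_class$sensitivity[3] == 0)
})

test_that("F1 equals the harmonic mean of precision and sensitivity", {
  set.seed(303)
  for (i in 1:1000) {
    cm <- matrix(rpois(9, 6), 3, 3)
    if (sum(cm) == 0) next
    m <- class_metrics(cm)$per_class
    for (r in seq_len(3)) {
      pr <- m$precision[r]; se <- m$sensitivity[r]; f1 <- m$f1[r]
      if (is.na(pr) || is.na(se) || (pr + se) == 0) next
      expect_equal(f1, 2 * pr * se / (pr + se), tolerance = 1e-12)
    }
  }
})

test_that("accuracy is invariant under simultaneous class permutation", {
  set.seed(9)
  cm <- matrix(rpois(9, 5) + 1, 3, 3)
  m0 <- class_metrics(cm)
  expect_equal(sum(vapply(1:3, function(c) cm[c, c], numeric(1))),
               m0$overall_accuracy * sum(cm))
  perm <- c(3, 1, 2)
  expect_equal(class_metrics(cm[perm, perm])$overall_accuracy,
               m0$overall_accuracy)
})

test_that("ICC(2,1) matches an explicit sums-of-squares oracle", {
  # perfect agreement
  ratings <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc_single_absolute(ratings)$icc, 1, tolerance = 1e-9)

  # fixed worked matrix vs an independent variance-components computation
  m <- matrix(c(9, 6, 8, 7, 10, 6,
                2, 1, 4, 1, 5, 2,
                5, 3, 6, 2, 6, 4), 6, 3)
  got <- icc_single_absolute(m)
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got$icc, icc_oracle, tolerance = 1e-9)
  expect_equal(c(got$msr, got$msc, got$mse), c(msr, msc, mse),
               tolerance = 1e-9)
  expect_true(got$lower < got$icc && got$icc < got$upper)

  # rater-independent noise: ICC near zero
  set.seed(404)
  noise <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(icc_single_absolute(noise)$icc), 0.1)

  # degenerate input flagged, not fabricated
  expect_true(icc_single_absolute(matrix(5, 4, 3))$degenerate)
})

test_that("one-way ANOVA matches the classical decomposition", {
  same <- list(c(1, 2, 3), c(1, 2, 3))
  r <- anova_oneway(same)
  expect_equal(r$F, 0, tolerance = 1e-12)
  expect_equal(anova_oneway(list(c(2, 2), c(2, 2)))$p, 1)

  set.seed(11)
  g1 <- rnorm(4, 0, 1e-6); g2 <- 1 + rnorm(4, 0, 1e-6)
  expect_lt(anova_oneway(list(g1, g2))$p, 1e-6)

  # explicit sums-of-squares oracle on random groups
  set.seed(12)
  groups <- list(rnorm(7), rnorm(5, 0.5), rnorm(9, -0.3))
  r2 <- anova_oneway(groups)
  y <- unlist(groups); gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1; dfw <- length(y) - length(groups)
  f_oracle <- (ssb / dfb) / (ssw / dfw)
  expect_equal(r2$F, f_oracle, tolerance = 1e-9)
  expect_equal(r2$p, stats::pf(f_oracle, dfb, dfw, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("k-fold splits partition the cases evenly and reproducibly", {
  ids <- sprintf("c%02d", 1:85)
  s <- fivefold_split(ids, k = 5, seed = 3)
  expect_equal(unname(table(s)), rep(17L, 5), ignore_attr = TRUE)
  expect_setequal(names(s), ids)
  expect_identical(s, fivefold_split(ids, k = 5, seed = 3))
  expect_false(identical(s, fivefold_split(ids, k = 5, seed = 4)))
  expect_error(fivefold_split(ids[1:3], k = 5), "more folds")

  # stratified splits balance each side across folds
  strata <- rep(c("femoral", "middle", "tibial"), c(40, 35, 10))
  ss <- fivefold_split(sprintf("c%02d", 1:85), k = 5, seed = 5, strata = strata)
  for (side in unique(strata)) {
    tab <- table(ss[strata == side])
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("cross-validation with oracle models is exact", {
  cases <- make_dataset(10, tiny_spec(noise_sd = 0), seed = 71)
  trainer <- function(train_cases) "oracle"
  predictor <- function(bundle, cs) cs$gt$rupture_point
  cv <- cross_validate(cases, trainer, predictor, k = 5, seed = 1)
  expect_equal(cv$pooled_stats$mean, 0)
  expect_equal(cv$pooled_metrics$overall_accuracy, 1)
  expect_equal(sum(cv$confusion), 10)

  # leave-one-out: 5 folds of size 1
  cv2 <- cross_validate(cases[1:5], trainer, predictor, k = 5, seed = 2)
  expect_equal(vapply(cv2$folds, function(f) length(f$errors), numeric(1)),
               rep(1, 5))

  # 3-fold structural report on 30 cases
  cases30 <- make_dataset(30, tiny_spec(noise_sd = 0), seed = 72)
  cv3 <- cross_validate(cases30, trainer, predictor, k = 3, seed = 3)
  expect_equal(sort(vapply(cv3$folds, function(f) length(f$errors),
                           numeric(1))), c(10, 10, 10))
  expect_s3_class(cv3$pooled_metrics, "acl_metrics")
})
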