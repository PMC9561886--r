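# Study statistics: localization error and failure rate, three-class
# confusion matrices with one-vs-rest metrics, ICC(2,1) agreement, one-way
# ANOVA and k-fold bookkeeping.

#' Euclidean localization error
#'
#' @param pred,truth physical mm 3-vectors.
#' @return distance in mm.
#' @export
euclidean_error <- function(pred, truth) {
  stopifnot(all(is.finite(pred)), all(is.finite(truth)))
  sqrt(sum((as.numeric(pred) - as.numeric(truth))^2))
}

#' Localization failure rule
#'
#' A case is a failure when the predicted-to-true distance is strictly larger
#' than the threshold (10 mm by default): exactly 10.0 mm is still a success.
#'
#' @param error error in mm (>= 0).
#' @param threshold failure threshold in mm.
#' @return logical.
#' @export
failure_flag <- function(error, threshold = 10) {
  stopifnot(all(error >= 0))
  error > threshold
}

#' Summary statistics for a set of localization errors
#'
#' @param errors non-empty numeric vector of per-case errors (mm).
#' @param threshold failure threshold in mm (strict, see [failure_flag()]).
#' @return list of class `acl_loc_stats`: `errors`, `mean`, `sd` (sample,
#'   n-1), `failures`, `error_rate` (= failures / total).
#' @export
localization_stats <- function(errors, threshold = 10) {
  if (length(errors) == 0) stop("empty error list")
  f <- sum(failure_flag(errors, threshold))
  structure(list(errors = errors, mean = mean(errors),
                 sd = if (length(errors) > 1) stats::sd(errors) else 0,
                 failures = f, error_rate = f / length(errors),
                 threshold = threshold),
            class = "acl_loc_stats")
}

#' @export
print.acl_loc_stats <- function(x, ...) {
  cat(sprintf("localization: %.2f +/- %.2f mm, error rate %.1f%% (%d/%d)\n",
              x$mean, x$sd, 100 * x$error_rate, x$failures, length(x$errors)))
  invisible(x)
}

.side_factor <- function(x) {
  if (is.list(x) && !is.null(x$value)) x <- x$value
  factor(as.character(x), levels = .side_levels)
}

#' Three-class confusion matrix (rows predicted, columns true)
#'
#' @param preds,truths equal-length vectors of side classes (factors, strings,
#'   or `classify_side()` results).
#' @return 3x3 integer matrix, class order (femoral, middle, tibial).
#' @export
confusion <- function(preds, truths) {
  if (is.list(preds)) preds <- vapply(preds, function(p) as.character(.side_factor(p)), "")
  if (is.list(truths)) truths <- vapply(truths, function(p) as.character(.side_factor(p)), "")
  preds <- .side_factor(preds); truths <- .side_factor(truths)
  if (length(preds) != length(truths)) stop("length mismatch")
  m <- table(predicted = preds, true = truths)
  matrix(as.integer(m), 3, 3, dimnames = dimnames(m))
}

#' Per-class one-vs-rest metrics and overall accuracy
#'
#' Reduces the 3x3 matrix one class at a time: TP is the diagonal entry, FP
#' the rest of the predicted row, FN the rest of the true column, TN the
#' remainder. Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), F1 = TP/(TP + 0.5(FP+FN)); overall accuracy = trace/total.
#' Metrics with a zero denominator are reported as `NA` (undefined), never 0
#' or 1.
#'
#' @param cm 3x3 confusion matrix, rows predicted, columns true.
#' @return list of class `acl_metrics`: `per_class` data.frame (sensitivity,
#'   specificity, precision, f1 per class) and `overall_accuracy`.
#' @export
class_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == 3, ncol(cm) == 3, all(cm >= 0), sum(cm) > 0)
  total <- sum(cm)
  rows <- lapply(1:3, function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[c, ]) - tp
    fn <- sum(cm[, c]) - tp
    tn <- total - tp - fp - fn
    sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
    data.frame(class = .side_levels[c],
               sensitivity = sdiv(tp, tp + fn),
               specificity = sdiv(tn, tn + fp),
               precision = sdiv(tp, tp + fp),
               f1 = sdiv(tp, tp + 0.5 * (fp + fn)))
  })
  structure(list(per_class = do.call(rbind, rows),
                 overall_accuracy = sum(diag(cm)) / total,
                 total = total),
            class = "acl_metrics")
}

#' @export
print.acl_metrics <- function(x, ...) {
  print(cbind(x$per_class[1], round(x$per_class[-1], 2)))
  cat(sprintf("overall accuracy: %.2f (n = %d)\n", x$overall_accuracy, x$total))
  invisible(x)
}

#' Single-measure ICC, two-way random effects, absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA decomposition (subjects x raters, no
#' replicates), with the standard F-based 95% confidence interval. A
#' degenerate matrix (zero total variance) yields an undefined (NA) ICC with
#' `degenerate = TRUE`.
#'
#' @param ratings numeric subjects x raters matrix, no missing cells,
#'   >= 2 subjects and >= 2 raters.
#' @param conf_level confidence level for the interval.
#' @return list of class `acl_icc`: `icc`, `lower`, `upper`, mean squares
#'   (`msr`, `msc`, `mse`) and `degenerate`.
#' @export
icc_single_absolute <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (any(!is.finite(m))) stop("ratings must be complete and finite")
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2, k >= 2)
  if (stats::var(as.vector(m)) < .Machine$double.eps^0.75) {
    return(structure(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                          msr = 0, msc = 0, mse = 0, degenerate = TRUE),
                     class = "acl_icc"))
  }
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  # the F-test warning for an exact fit is irrelevant: only mean squares are used
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ subject + rater, data = df))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = icc, lower = lower, upper = upper, msr = msr,
                 msc = msc, mse = mse, degenerate = FALSE),
            class = "acl_icc")
}

#' @export
print.acl_icc <- function(x, ...) {
  if (x$degenerate) cat("ICC undefined (degenerate ratings)\n")
  else cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f, %.3f)\n",
                   x$icc, x$lower, x$upper))
  invisible(x)
}

#' One-way ANOVA across groups
#'
#' Classical between/within decomposition; p-value from the F distribution.
#'
#' @param groups list (>= 2) of numeric vectors, each with n >= 2.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(y) < .Machine$double.eps^0.75)
    return(list(F = 0, p = 1, df_between = length(groups) - 1,
                df_within = length(y) - length(groups)))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       df_between = unname(ht$parameter[1]), df_within = unname(ht$parameter[2]))
}

#' Seeded k-fold split
#'
#' Shuffles the ids with the seed, then deals them round-robin (optionally
#' within side strata): folds are disjoint, exhaustive, and their sizes differ
#' by at most one.
#'
#' @param case_ids vector of case ids.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @param strata optional vector (same length) of side classes to stratify by.
#' @return named integer vector: fold index in `0..k-1` per case id.
#' @export
fivefold_split <- function(case_ids, k = 5, seed = 1, strata = NULL) {
  n <- length(case_ids)
  stopifnot(k >= 2)
  if (k > n) stop("more folds than cases")
  set.seed(seed)
  fold <- integer(n)
  if (is.null(strata)) {
    ord <- sample.int(n)
    fold[ord] <- (seq_len(n) - 1L) %% k
  } else {
    stopifnot(length(strata) == n)
    off <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      ord <- idx[sample.int(length(idx))]
      fold[ord] <- (off + seq_along(ord) - 1L) %% k
      off <- off + length(idx)
    }
  }
  stats::setNames(fold, case_ids)
}

#' Cross-validated localization and classification
#'
#' Generic k-fold driver: `trainer(cases)` returns a model bundle,
#' `predictor(bundle, case)` returns the predicted rupture point (mm) for one
#' case. Ground truth is taken from each case's `gt`. Reports per-fold
#' localization statistics and the pooled confusion/metrics over all held-out
#' predictions; a fold whose training fails is recorded and its cases skipped.
#'
#' @param cases named list of phantom cases (or any objects with `gt`).
#' @param trainer function(list of cases) -> model bundle.
#' @param predictor function(bundle, case) -> mm 3-vector.
#' @param k folds.
#' @param seed seed for the split.
#' @param threshold failure threshold (mm).
#' @return list of class `acl_cv`: `folds` (per-fold `acl_loc_stats`),
#'   `pooled_stats`, `pooled_metrics`, `confusion`, `split`, `fold_errors`.
#' @export
cross_validate <- function(cases, trainer, predictor, k = 5, seed = 1,
                           threshold = 10) {
  if (length(cases) < k) stop("dataset smaller than k")
  split <- fivefold_split(names(cases), k = k, seed = seed)
  errors <- numeric(0); preds <- character(0); truths <- character(0)
  folds <- vector("list", k)
  fold_failures <- character(0)
  for (f in 0:(k - 1)) {
    test_ids <- names(split)[split == f]
    train_ids <- setdiff(names(cases), test_ids)
    bundle <- tryCatch(trainer(cases[train_ids]), error = function(e) e)
    if (inherits(bundle, "error")) {
      fold_failures <- c(fold_failures, sprintf("fold %d: %s", f,
                                                conditionMessage(bundle)))
      next
    }
    ferr <- vapply(test_ids, function(id) {
      cs <- cases[[id]]
      pt <- predictor(bundle, cs)
      e <- euclidean_error(pt, cs$gt$rupture_point)
      axis <- acl_axis(cs$gt$femoral_center, cs$gt$tibial_center)
      preds <<- c(preds, as.character(classify_side(
        project_fraction(pt, axis))$value))
      truths <<- c(truths, as.character(cs$gt$side))
      e
    }, numeric(1))
    errors <- c(errors, ferr)
    folds[[f + 1]] <- localization_stats(ferr, threshold)
  }
  if (length(errors) == 0) stop("all folds failed: ",
                                paste(fold_failures, collapse = "; "))
  cm <- confusion(preds, truths)
  structure(list(folds = folds, pooled_stats = localization_stats(errors,
                                                                  threshold),
                 pooled_metrics = class_metrics(cm), confusion = cm,
                 split = split, fold_failures = fold_failures),
            class = "acl_cv")
}

#' Benchmark reader-study confusion matrices
#'
#' Reference benchmark from an 85-case ACL rupture side-classification
#' reader study: 3x3 confusion matrices (rows predicted, columns true; order
#' femoral, middle, tibial) for a 3D CNN pipeline, a 2D CNN pipeline, two
#' clinical residents and a musculoskeletal radiology fellow. Note the
#' `resident2` matrix records only 84 of the 85 cases.
#'
#' @return named list of five 3x3 integer matrices.
#' @export
acl_reader_confusions <- function() {
  mk <- function(...) {
    m <- matrix(c(...), 3, 3, byrow = TRUE,
                dimnames = list(predicted = .side_levels, true = .side_levels))
    m
  }
  list(
    cnn3d = mk(37, 9, 0,
               6, 25, 2,
               0, 1, 5),
    cnn2d = mk(28, 10, 1,
               13, 23, 5,
               2, 2, 1),
    resident1 = mk(8, 0, 0,
                   30, 30, 4,
                   5, 5, 3),
    resident2 = mk(1, 0, 0,
                   40, 32, 4,
                   1, 3, 3),
    fellow = mk(32, 10, 3,
                6, 13, 1,
                5, 12, 3)
  )
}
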