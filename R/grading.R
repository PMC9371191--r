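#' Area-circularity dispersion summary
#'
#' Measures nuclear pleomorphism as the total dispersion of the
#' (area, circularity) feature pair: the covariance matrix of the two
#' features is computed (denominator `n - 1`) and summarized by the sum of
#' its eigenvalues, `Lambda = Lambda_A + Lambda_C` (the trace). Because area
#' (px^2) and circularity ([0,1]) are incommensurate, features are z-scored
#' first; the scaling statistics default to the table's own but should be a
#' *pooled* reference when several tissue groups are compared (see
#' [dispersion_compare()]), otherwise Lambda degenerates to the number of
#' features for every table.
#'
#' @param table Tibble with columns `area` and `circularity` (one nucleus
#'   per row).
#' @param center,scale Optional reference means/sds (length-2, area first).
#' @param features Feature columns (default `c("area", "circularity")`).
#' @return A list (class `dispersion_summary`): `m` (2x2 covariance),
#'   `eigenvalues` (sorted descending), `lambda` (their sum), `n`.
#' @export
dispersion <- function(table, center = NULL, scale = NULL,
                       features = c("area", "circularity")) {
  x <- as.matrix(table[, features])
  if (nrow(x) < 2) stop("dispersion requires at least 2 nuclei")
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1  # flat feature: leave unscaled (contributes 0 anyway)
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  m <- stats::cov(z)
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  structure(list(m = m, eigenvalues = ev, lambda = sum(ev), n = nrow(x),
                 features = features),
            class = "dispersion_summary")
}

#' Compare feature dispersion across tissue groups
#'
#' Standardizes all groups with the pooled feature statistics, then computes
#' the per-group [dispersion()]. Healthy tissue (uniform, round nuclei)
#' yields a smaller `Lambda` than pleomorphic cancerous tissue.
#'
#' @param tables Named list of feature tibbles.
#' @param features Feature columns used.
#' @return Tibble with one row per group: `group`, `n`, `lambda`,
#'   `lambda_1`, `lambda_2`.
#' @export
dispersion_compare <- function(tables, features = c("area", "circularity")) {
  pooled <- dplyr::bind_rows(tables)
  ctr <- colMeans(as.matrix(pooled[, features]))
  scl <- apply(as.matrix(pooled[, features]), 2, sd)
  purrr::imap(tables, function(tb, nm) {
    d <- dispersion(tb, center = ctr, scale = scl, features = features)
    tibble(group = nm, n = d$n, lambda = d$lambda,
           lambda_1 = d$eigenvalues[1], lambda_2 = d$eigenvalues[2])
  }) |> dplyr::bind_rows()
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat("Feature dispersion over", x$n, "nuclei:",
      paste(x$features, collapse = " + "), "\n")
  cat("  Lambda =", round(x$lambda, 4),
      "(eigenvalues", paste(round(x$eigenvalues, 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Draw random nucleus subsets and summarize them
#'
#' Emulates the subset-sampling protocol used for grade analysis: from each
#' grade's nucleus pool, draw `count` subsets of `n` nuclei (uniformly,
#' without replacement inside a subset; independent across subsets) and keep
#' the subset-mean feature vector as one sample of that grade.
#'
#' @param pool Tibble of per-nucleus features with a `grade` column.
#' @param n Subset cardinality (the study uses 100, 500 or 2000).
#' @param count Number of subsets per grade.
#' @param seed Integer seed; sampling is fully reproducible.
#' @param features Feature columns to average.
#' @return Tibble with `grade`, `subset`, `n`, `with_replacement` and the
#'   mean of each feature column.
#' @export
sample_subsets <- function(pool, n, count, seed,
                           features = c("area", "mean_intensity", "circularity")) {
  stopifnot(n >= 1, count >= 1)
  features <- intersect(features, names(pool))
  grades <- sort(unique(pool$grade))
  if (length(grades) == 0L || nrow(pool) == 0L) stop("empty nucleus pool")
  withr::with_seed(as.integer(seed), {
    purrr::map(grades, function(g) {
      sub <- pool[pool$grade == g, , drop = FALSE]
      replace <- nrow(sub) < n
      purrr::map(seq_len(count), function(i) {
        take <- sub[sample.int(nrow(sub), n, replace = replace), features,
                    drop = FALSE]
        dplyr::bind_cols(tibble(grade = g, subset = i, n = n,
                                with_replacement = replace),
                         as_tibble(as.list(colMeans(as.matrix(take)))))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
}

#' K-nearest-neighbour grade classification
#'
#' Euclidean KNN with majority vote; ties break towards the smallest grade
#' index for determinism. Features are standardized with the *training*
#' statistics.
#'
#' @param train,test Tibbles with a `grade` column and feature columns.
#' @param k Number of neighbours (default 5).
#' @param features Feature columns (default mean area + mean intensity).
#' @return A list: `predictions` (tibble with `grade`, `predicted`),
#'   `accuracy`, `f1` (macro).
#' @export
knn_grade <- function(train, test, k = 5,
                      features = c("area", "mean_intensity")) {
  stopifnot(k >= 1)
  if (k > nrow(train)) stop("k exceeds training-set size")
  xtr <- as.matrix(train[, features]); xte <- as.matrix(test[, features])
  ctr <- colMeans(xtr); scl <- apply(xtr, 2, sd); scl[scl == 0] <- 1
  xtr <- sweep(sweep(xtr, 2, ctr), 2, scl, "/")
  xte <- sweep(sweep(xte, 2, ctr), 2, scl, "/")
  classes <- sort(unique(train$grade))
  pred <- vapply(seq_len(nrow(xte)), function(i) {
    d2 <- colSums((t(xtr) - xte[i, ])^2)
    nb <- train$grade[order(d2)[seq_len(k)]]
    votes <- table(factor(nb, levels = classes))
    classes[which.max(votes)]  # first max = smallest grade index
  }, character(1))
  predictions <- tibble(grade = test$grade, predicted = pred)
  list(predictions = predictions,
       accuracy = mean(pred == test$grade),
       f1 = macro_f1(test$grade, pred, classes))
}

macro_f1 <- function(truth, pred, classes) {
  f1s <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Stratified k-fold cross-validated KNN grading
#'
#' Splits the subset samples into stratified folds, trains on the remaining
#' folds and evaluates on the held-out fold, reporting mean and standard
#' deviation of accuracy and macro F1.
#'
#' @param samples Tibble of subset samples with `grade` and feature columns.
#' @param k Number of neighbours (default 5).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param features Feature columns.
#' @return An object of class `knn_cv`: list with per-fold tibble `folds`
#'   and summary statistics.
#' @export
knn_cross_validate <- function(samples, k = 5, folds = 10, seed = 1,
                               features = c("area", "mean_intensity")) {
  stopifnot(folds >= 2)
  fold_id <- integer(nrow(samples))
  withr::with_seed(as.integer(seed), {
    for (g in unique(samples$grade)) {
      idx <- which(samples$grade == g)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  res <- purrr::map(seq_len(folds), function(f) {
    tr <- samples[fold_id != f, , drop = FALSE]
    te <- samples[fold_id == f, , drop = FALSE]
    fit <- knn_grade(tr, te, k = k, features = features)
    tibble(fold = f, n_test = nrow(te),
           accuracy = fit$accuracy, f1 = fit$f1)
  }) |> dplyr::bind_rows()
  structure(
    list(folds = res, k = k, n_folds = folds, features = features,
         accuracy_mean = mean(res$accuracy), accuracy_sd = sd(res$accuracy),
         f1_mean = mean(res$f1), f1_sd = sd(res$f1)),
    class = "knn_cv"
  )
}

#' @export
print.knn_cv <- function(x, ...) {
  cat(sprintf("KNN (K=%d) %d-fold CV: accuracy %.3f +/- %.3f, F1 %.3f +/- %.3f\n",
              x$k, x$n_folds, x$accuracy_mean, x$accuracy_sd,
              x$f1_mean, x$f1_sd))
  invisible(x)
}

#' Per-fold results of a cross-validated KNN fit
#' @param x A `knn_cv` object.
#' @param ... Unused.
#' @export
tidy.knn_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validated KNN fit
#' @param x A `knn_cv` object.
#' @param ... Unused.
#' @export
glance.knn_cv <- function(x, ...) {
  tibble(k = x$k, folds = x$n_folds,
         accuracy = x$accuracy_mean, accuracy_sd = x$accuracy_sd,
         f1 = x$f1_mean, f1_sd = x$f1_sd)
}

#' Pixel-wise segmentation evaluation
#'
#' Confusion counts of a segmentation `ss` against a reference `st` over the
#' full image: `TP = ss & st`, `FP = ss & !st`, `FN = !ss & st`,
#' `TN = !(ss | st)`; precision, sensitivity and the Sørensen–Dice
#' coefficient `SDC = 2TP / (2TP + FP + FN)`. Undefined ratios (zero
#' denominators) are reported as `NA`.
#'
#' @param ss,st Logical/0-1 masks of identical dimensions (segmentation,
#'   reference).
#' @return One-row tibble with counts and metrics.
#' @export
evaluate_segmentation <- function(ss, st) {
  if (!all(dim(ss) == dim(st))) stop("mask dimensions differ")
  a <- ss != 0; b <- st != 0
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b); tn <- sum(!a & !b)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = safe(tp, tp + fp),
    sensitivity = safe(tp, tp + fn),
    accuracy = (tp + tn) / length(a),
    sdc = safe(2 * tp, 2 * tp + fp + fn)
  )
}

#' Scatter plot of grade subset samples
#'
#' @param object Tibble from [sample_subsets()].
#' @param features Two feature columns to plot.
#' @param ... Unused.
#' @export
plot_subsets <- function(object, features = c("area", "mean_intensity"), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[features[1]]],
                                       y = .data[[features[2]]],
                                       colour = .data$grade)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(title = "Grade subset samples") +
    ggplot2::theme_minimal()
}
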