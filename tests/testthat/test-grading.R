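test_that("dispersion handles degenerate and standard cases", {
  same <- tibble::tibble(area = rep(50, 10), circularity = rep(0.9, 10))
  d <- dispersion(same)
  expect_equal(d$lambda, 0)
  expect_error(dispersion(same[1, ]), "at least 2")

  set.seed(3)
  tb <- tibble::tibble(area = rnorm(200, 60, 15),
                       circularity = pmin(1, rnorm(200, 0.8, 0.1)))
  d2 <- dispersion(tb)
  # eigenvalue sum equals the trace
  expect_equal(d2$lambda, sum(diag(d2$m)))
  expect_true(all(d2$eigenvalues >= 0))
  # invariant to row order and to exact duplication of the table
  d3 <- dispersion(tb[sample(nrow(tb)), ])
  expect_equal(d3$lambda, d2$lambda)
  dup <- dplyr::bind_rows(tb, tb)
  d4 <- dispersion(dup, center = colMeans(as.matrix(tb)),
                   scale = apply(as.matrix(tb), 2, sd))
  expect_equal(d4$lambda, d2$lambda, tolerance = 0.01)
})

test_that("pooled standardization separates tight from spread pools", {
  set.seed(17)
  healthy <- tibble::tibble(area = rnorm(300, 50, 5),
                            circularity = pmin(1, rnorm(300, 0.95, 0.02)))
  cancer <- tibble::tibble(area = rnorm(300, 80, 30),
                           circularity = pmin(1, rnorm(300, 0.7, 0.2)))
  cmp <- dispersion_compare(list(healthy = healthy, cancer = cancer))
  expect_lt(cmp$lambda[cmp$group == "healthy"],
            cmp$lambda[cmp$group == "cancer"])
})

test_that("subset sampling is seeded and shrinks variance with cardinality", {
  set.seed(2)
  pool <- tibble::tibble(
    grade = rep(c("G1", "G2"), each = 3000),
    area = rnorm(6000, rep(c(55, 90), each = 3000), 20),
    mean_intensity = rnorm(6000, rep(c(110, 90), each = 3000), 10),
    circularity = runif(6000)
  )
  s1 <- sample_subsets(pool, n = 1, count = 5, seed = 7)
  # n = 1 subsets are single nuclei drawn from the pool
  expect_true(all(s1$area %in% pool$area))
  expect_identical(sample_subsets(pool, 50, 10, seed = 3),
                   sample_subsets(pool, 50, 10, seed = 3))
  v <- vapply(c(100, 500, 2000), function(n) {
    var(sample_subsets(pool, n, 60, seed = 11)$area[1:60])
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_error(sample_subsets(pool[0, ], 10, 5, 1), "empty")
})

test_that("KNN votes deterministically and validates inputs", {
  train <- tibble::tibble(grade = c(rep("G1", 5), rep("G2", 5)),
                          area = c(rep(10, 5), rep(50, 5)),
                          mean_intensity = c(rep(10, 5), rep(50, 5)))
  test <- tibble::tibble(grade = "G1", area = 11, mean_intensity = 10)
  fit <- knn_grade(train, test, k = 5)
  expect_equal(fit$predictions$predicted, "G1")
  expect_equal(fit$accuracy, 1)
  expect_error(knn_grade(train, test, k = 11), "exceeds")

  # single-grade training set predicts that grade everywhere
  tr1 <- tibble::tibble(grade = "G2", area = rnorm(10), mean_intensity = rnorm(10))
  te <- tibble::tibble(grade = c("G1", "G2"), area = c(0, 1),
                       mean_intensity = c(0, 1))
  fit1 <- knn_grade(tr1, te, k = 3)
  expect_true(all(fit1$predictions$predicted == "G2"))
  expect_equal(fit1$accuracy, 0.5)
})

test_that("KNN matches a hand-computed nearest-neighbour oracle", {
  train <- tibble::tibble(grade = c("G1", "G1", "G2", "G2", "G3"),
                          area = c(0, 1, 10, 11, 30),
                          mean_intensity = c(0, 1, 10, 11, 30))
  test <- tibble::tibble(grade = c("G1", "G2", "G3"),
                         area = c(0.4, 10.6, 28),
                         mean_intensity = c(0.4, 10.6, 28))
  fit <- knn_grade(train, test, k = 1)
  expect_equal(fit$predictions$predicted, c("G1", "G2", "G3"))
  expect_equal(fit$f1, 1)
  # tie case at k = 2: smallest grade index wins
  fit2 <- knn_grade(train[1:4, ], tibble::tibble(grade = "G1", area = 5.5,
                                                 mean_intensity = 5.5), k = 2)
  expect_equal(fit2$predictions$predicted, "G1")
})

test_that("cross-validated KNN separates well-separated synthetic grades", {
  set.seed(9)
  samples <- tibble::tibble(
    grade = rep(c("G1", "G2", "G3"), each = 60),
    area = rnorm(180, rep(c(50, 75, 100), each = 60), 4),
    mean_intensity = rnorm(180, rep(c(115, 95, 75), each = 60), 4)
  )
  cv <- knn_cross_validate(samples, k = 5, folds = 10, seed = 2)
  expect_gte(cv$accuracy_mean, 0.8)
  expect_equal(nrow(tidy(cv)), 10)
  expect_equal(glance(cv)$accuracy, cv$accuracy_mean)
})

test_that("segmentation metrics follow their closed forms", {
  a <- matrix(0, 10, 10); a[1:5, 1:5] <- 1
  expect_equal(evaluate_segmentation(a, a)$sdc, 1)
  expect_equal(evaluate_segmentation(a, a)$precision, 1)

  b <- matrix(0, 10, 10); b[6:9, 6:9] <- 1
  expect_equal(evaluate_segmentation(a, b)$sdc, 0)

  # prediction covers exactly half of the reference, no false positives
  st <- matrix(0, 10, 10); st[1:4, 1:10] <- 1
  ss <- matrix(0, 10, 10); ss[1:2, 1:10] <- 1
  ev <- evaluate_segmentation(ss, st)
  expect_equal(ev$precision, 1)
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$sdc, 2 / 3)

  # symmetry and harmonic-mean identity
  set.seed(4)
  x <- matrix(rbinom(400, 1, 0.3), 20, 20)
  y <- matrix(rbinom(400, 1, 0.3), 20, 20)
  e1 <- evaluate_segmentation(x, y); e2 <- evaluate_segmentation(y, x)
  expect_equal(e1$sdc, e2$sdc)
  expect_equal(e1$sdc, 2 * e1$precision * e1$sensitivity /
                 (e1$precision + e1$sensitivity))
  expect_error(evaluate_segmentation(x, matrix(0, 5, 5)), "dimensions")
  # undefined ratios flagged as NA
  z <- matrix(0, 10, 10)
  expect_true(is.na(evaluate_segmentation(z, z)$sdc))
})
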