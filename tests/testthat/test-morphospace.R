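# A small synthetic descriptor table for transform/PCA tests.
toy_features <- function(n = 500, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      object_id = sprintf("o%04d", seq_len(n)),
      area = rlnorm(n, 4, 0.5),
      perimeter = rlnorm(n, 3, 0.4),
      mean_grey = runif(n, 30, 220)
    )
  })
}

test_that("trimming drops rows outside the quantile envelope (union rule)", {
  # constant column: no extremes exist, nothing dropped
  d <- tibble::tibble(area = rep(5, 100))
  tr <- trim_extremes(d, vars = "area", trim_fraction = 0.01)
  expect_equal(nrow(tr$data), 100)

  # 10,000 standard normals at f = 0.001: count must equal the sort-based
  # oracle and be close to 10
  x <- withr::with_seed(5, rnorm(10000))
  d <- tibble::tibble(area = x)
  tr <- trim_extremes(d, vars = "area", trim_fraction = 0.001)
  q <- quantile(x, c(0.0005, 0.9995), names = FALSE)
  oracle_dropped <- sum(x < q[1] | x > q[2])
  expect_equal(10000 - nrow(tr$data), oracle_dropped)
  expect_true(oracle_dropped >= 5 && oracle_dropped <= 15)

  # rows extreme in both columns are dropped once (union, not sum): the
  # same rows fall outside the envelope of both variables
  xs <- withr::with_seed(6, rnorm(200))
  d2 <- tibble::tibble(a = xs, b = 2 * xs)
  q <- quantile(xs, c(0.025, 0.975), names = FALSE)
  expected_union <- sum(xs < q[1] | xs > q[2])
  tr2 <- trim_extremes(d2, vars = c("a", "b"), trim_fraction = 0.05)
  expect_equal(200 - nrow(tr2$data), expected_union)
  expect_gt(expected_union, 0)

  # pathological table: extremes in disjoint rows across many variables
  # push the union above 20%, which must error
  d3 <- as.data.frame(matrix(0, 100, 30))
  for (j in 1:30) d3[c(2 * j - 1, 2 * j), j] <- c(-1e6, 1e6)
  expect_error(trim_extremes(d3, vars = names(d3), trim_fraction = 0.05),
               "20%")
})

test_that("fit-time transform standardises and projection reuses constants", {
  ft <- toy_features()
  ms <- fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey"),
                        log_vars = c("area", "perimeter"),
                        n_components = 3, trim_fraction = 0)
  # every transformed training column has mean 0, sd 1
  z <- snowmorph:::apply_transform(ft, ms$constants)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # log10(1 + 0) = 0 before scaling
  d0 <- tibble::tibble(area = 0, perimeter = 1, mean_grey = 100)
  z0 <- snowmorph:::apply_transform(d0, ms$constants)
  expect_equal(
    z0[1, "area"] * ms$constants$scale[1] + ms$constants$center[1],
    c(area = 0)
  )
  # projecting the training table reproduces the fit-time scores exactly
  pr <- project_morphospace(ft, ms)
  expect_equal(as.matrix(pr[, c("PC1", "PC2", "PC3")]),
               as.matrix(ms$scores[, c("PC1", "PC2", "PC3")]),
               ignore_attr = TRUE)
  # negative value in a log-set variable errors with variable and id
  bad <- ft
  bad$area[3] <- -1
  expect_error(project_morphospace(bad, ms), "area.*o0003")
})

test_that("PCA matches the closed-form 2-variable case and is orthonormal", {
  # two standardized variables with exact correlation 0.8
  z1 <- rep(c(1, 1, -1, -1), 25)
  z2 <- rep(c(1, -1, 1, -1), 25)
  d <- tibble::tibble(a = z1, b = 0.8 * z1 + 0.6 * z2)
  ms <- fit_morphospace(d, vars = c("a", "b"), log_vars = character(0),
                        n_components = 2, trim_fraction = 0)
  expect_equal(ms$eigenvalues, c(1.8, 0.2), tolerance = 1e-9)
  expect_equal(ms$explained[1], 0.9, tolerance = 1e-9)

  # orthonormal loadings and non-increasing explained variances
  ft <- toy_features()
  ms2 <- fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey"),
                         log_vars = c("area", "perimeter"),
                         n_components = 3, trim_fraction = 0)
  rot <- ms2$rotation
  expect_equal(crossprod(rot), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(ms2$explained) <= 1e-12))
  # sign convention: dominant loading positive
  expect_true(all(apply(rot, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("full-rank fit reconstructs the transformed table", {
  ft <- toy_features(300)
  ms <- fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey"),
                        log_vars = character(0),
                        n_components = 3, trim_fraction = 0)
  z <- snowmorph:::apply_transform(ft, ms$constants)
  scores <- z %*% ms$rotation
  back <- scores %*% t(ms$rotation)
  expect_lt(max(abs(back - z)), 1e-6)
})

test_that("rank deficiency is reported when components exceed the rank", {
  ft <- toy_features(200)
  ft$dup <- 2 * ft$area + 1
  expect_error(
    fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey", "dup"),
                    log_vars = character(0), n_components = 4,
                    trim_fraction = 0),
    "collinear"
  )
  # but a request within the effective rank succeeds
  ms <- fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey", "dup"),
                        log_vars = character(0), n_components = 3,
                        trim_fraction = 0)
  expect_equal(ms$n_components, 3)
})

test_that("a row at the training mean projects to the origin", {
  ft <- toy_features()
  ms <- fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey"),
                        log_vars = character(0),
                        n_components = 3, trim_fraction = 0)
  centre_row <- tibble::tibble(
    area = ms$constants$center[1],
    perimeter = ms$constants$center[2],
    mean_grey = ms$constants$center[3]
  )
  pr <- project_morphospace(centre_row, ms)
  expect_lt(max(abs(as.matrix(pr[, c("PC1", "PC2", "PC3")]))), 1e-9)
})

test_that("missing variables are named in projection errors", {
  ft <- toy_features()
  ms <- fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey"),
                        log_vars = character(0), n_components = 2,
                        trim_fraction = 0)
  expect_error(project_morphospace(ft[, c("object_id", "area", "perimeter")],
                                   ms), "mean_grey")
})

test_that("tidy/glance expose loadings and fit summary", {
  ft <- toy_features()
  ms <- fit_morphospace(ft, vars = c("area", "perimeter", "mean_grey"),
                        log_vars = character(0), n_components = 2,
                        trim_fraction = 0)
  td <- tidy(ms)
  expect_equal(nrow(td), 6)  # 3 variables x 2 components
  expect_named(td, c("variable", "component", "loading"))
  gl <- glance(ms)
  expect_equal(gl$n_components, 2)
  expect_true(gl$var_explained > 0 && gl$var_explained <= 1)
})
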