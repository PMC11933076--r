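test_that("Box-Cox special cases and maximum-likelihood lambda", {
  x <- c(1.5, 2, 3.7, 9)
  expect_equal(box_cox_forward(x, lambda = 1), x - 1)
  expect_equal(box_cox_forward(exp(1), lambda = 0), 1)

  # lognormal data are exactly normalized at lambda = 0
  set.seed(401)
  lam <- fit_box_cox(exp(stats::rnorm(5000)))
  expect_equal(lam$shift, 0)
  expect_lt(abs(lam$lambda), 0.1)

  # cross-check against the profile-likelihood grid of an independent fitter
  set.seed(402)
  y <- stats::rgamma(500, shape = 2, rate = 0.5)
  ours <- fit_box_cox(y)$lambda
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-1, 1.5, 0.005), plotit = FALSE)
  expect_equal(ours, bc$x[which.max(bc$y)], tolerance = 0.01)

  expect_error(fit_box_cox(rep(3, 10)), "degenerate")
  expect_error(fit_box_cox(c(1, 2)), "degenerate")

  # non-positive columns get the minimal positivity shift
  sh <- fit_box_cox(c(0, 1, 2, 5))$shift
  expect_equal(sh, 1e-6)
})

test_that("Box-Cox forward and inverse are mutual inverses", {
  set.seed(403)
  x <- stats::runif(100, 0.1, 50)
  for (lam in c(-1.3, -0.5, 0, 0.33, 1, 2.7)) {
    z <- box_cox_forward(x, lam, shift = 0.2)
    expect_equal(box_cox_inverse(z, lam, shift = 0.2), x, tolerance = 1e-9)
  }
})

test_that("SoftImpute matches the minimal-nuclear-norm oracle on 2x2 patterns", {
  # [[1,2],[2,a]]: nuclear norm is sqrt(a^2 - 2a + 17) for a < 4, (1+a) after;
  # the lambda -> 0 limit is its argmin, a = 1 (closed form / grid oracle)
  agrid <- seq(-2, 6, by = 1e-4)
  nuc <- ifelse(agrid < 4, sqrt(agrid^2 - 2 * agrid + 17), 1 + agrid)
  expect_equal(agrid[which.min(nuc)], 1)
  m <- matrix(c(1, 2, 2, NA), 2, 2, byrow = TRUE)
  r <- soft_impute(m, lambda_nuclear = 0.01, tol = 1e-12, max_iter = 5e4)
  expect_equal(r$completed[2, 2], 1, tolerance = 1e-2)
  expect_equal(r$completed[!is.na(m)], m[!is.na(m)])  # observed untouched

  # decay pattern [[4,2],[2,a]]: the rank-1 completion (a = 1) IS the
  # minimal-nuclear-norm completion, recovered exactly as lambda -> 0
  m2 <- matrix(c(4, 2, 2, NA), 2, 2, byrow = TRUE)
  r2 <- soft_impute(m2, lambda_nuclear = 0.005, tol = 1e-12, max_iter = 1e5)
  expect_equal(r2$completed[2, 2], 1, tolerance = 1e-2)
})

test_that("SoftImpute recovers a random low-rank matrix and never increases its objective", {
  set.seed(404)
  A <- matrix(stats::rnorm(20 * 2), 20, 2) %*% matrix(stats::rnorm(2 * 8), 2, 8)
  mask <- sample(length(A), round(0.1 * length(A)))
  Am <- A
  Am[mask] <- NA
  r <- soft_impute(Am, lambda_nuclear = 0.01, tol = 1e-9, max_iter = 2e4)
  rmse <- sqrt(mean((r$completed[mask] - A[mask])^2))
  expect_lt(rmse, 0.05 * stats::sd(A))
  expect_true(all(diff(r$objective) <= 1e-8))
  expect_true(r$converged)

  # no missing cells: identity, zero sweeps
  r0 <- soft_impute(A)
  expect_identical(r0$n_iter, 0L)
  expect_equal(r0$completed, A)

  Abad <- A
  Abad[, 3] <- NA
  colnames(Abad) <- paste0("c", 1:8)
  expect_error(soft_impute(Abad), "c3")
})

test_that("min-max scaling hits its anchors and inverts", {
  expect_equal(min_max_scale(8, 8, 24), 0)
  expect_equal(min_max_scale(24, 8, 24), 1)
  # distance 15 cm on the published support [8, 24]
  expect_equal(min_max_scale(15, 8, 24), 0.4375)
  expect_equal(inverse_min_max(0.4375, 8, 24), 15)
  expect_error(min_max_scale(1, 2, 2), "degenerate")
})

test_that("preprocessing chain scales to [0,1], inverts, and preserves ranks", {
  ds <- small_dataset(n = 120, seed = 31)
  p <- preprocess_pipeline(ds)

  # all-observed dataset: the imputer is the identity
  expect_identical(p$imputation$n_iter, 0L)

  rng <- apply(p$dataset$features, 2, range)
  expect_equal(unname(rng[1, ]), rep(0, ncol(p$dataset$features)))
  expect_equal(unname(rng[2, ]), rep(1, ncol(p$dataset$features)))

  back <- transform_invert(p$state, p$dataset$features)
  expect_equal(back, ds$features, tolerance = 1e-6)
  backy <- transform_invert(p$state, p$dataset$labels)
  expect_equal(backy, ds$labels, tolerance = 1e-6)

  # strict monotonicity: Spearman statistics are invariant to the chain
  for (nm in c("distance_cm", "polymer_concentration_wt_pct"))
    expect_identical(rank(p$dataset$features[, nm]), rank(ds$features[, nm]))
  expect_equal(
    spearman_rho(p$dataset$features[, "distance_cm"],
                 p$dataset$labels[, "average_diameter_nm"]),
    spearman_rho(ds$features[, "distance_cm"],
                 ds$labels[, "average_diameter_nm"]))
})

test_that("labels are never imputed and missing features are completed", {
  ds <- small_dataset(n = 80, seed = 32)
  ds$labels[c(3, 9), "drug_release_pct"] <- NA
  ds <- nanofiber_dataset(ds$features, ds$labels)
  ds <- inject_missingness(ds, 60, seed = 5)
  p <- preprocess_pipeline(ds)
  expect_false(anyNA(p$dataset$features))
  expect_true(all(is.na(p$dataset$labels[c(3, 9), "drug_release_pct"])))
  # observed feature cells pass through the chain untouched
  obs <- !ds$missing_mask
  back <- transform_invert(p$state, p$dataset$features)
  expect_equal(back[obs], ds$features[obs], tolerance = 1e-6)
})

test_that("transform state serializes to JSON and re-applies at machine precision", {
  ds <- small_dataset(n = 50, seed = 33)
  p <- preprocess_pipeline(ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_state(p$state, path)
  st <- read_transform_state(path)
  expect_equal(transform_apply(st, ds$features),
               transform_apply(p$state, ds$features), tolerance = 1e-12)
})
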