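test_that("80/20 split is exact, disjoint, exhaustive and seeded", {
  sp <- split_dataset(100, seed = 42)
  expect_identical(length(sp$train), 80L)
  expect_identical(length(sp$test), 20L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)

  expect_identical(split_dataset(50, seed = 7), split_dataset(50, seed = 7))
  expect_false(identical(split_dataset(50, seed = 7)$test,
                         split_dataset(50, seed = 8)$test))
  expect_error(split_dataset(4), "too few rows")
})

test_that("SVR degenerate and invariance properties", {
  set.seed(601)
  x <- matrix(stats::runif(80 * 3), ncol = 3)
  colnames(x) <- c("f1", "f2", "f3")
  hp <- list(gamma = 1.16007, C = 30.52169, epsilon = 1.23861e-3)

  # constant label -> constant predictions within the epsilon tube
  m <- train_svr(x, rep(0.4, 80), hp)
  expect_true(all(abs(predict(m, x) - 0.4) <= hp$epsilon + 1e-9))

  y <- 0.3 + 0.5 * x[, 1] - 0.2 * x[, 2]^2
  m1 <- train_svr(x, y, hp)
  xt <- matrix(stats::runif(40 * 3), ncol = 3)

  # training-row permutation invariance (to solver precision)
  pp <- sample(nrow(x))
  m2 <- train_svr(x[pp, ], y[pp], hp)
  expect_lt(max(abs(predict(m1, xt) - predict(m2, xt))), 1e-3)

  # duplicating every row leaves predictions essentially unchanged
  m3 <- train_svr(rbind(x, x), c(y, y), hp)
  expect_lt(max(abs(predict(m1, xt) - predict(m3, xt))), 5e-3)

  x2 <- x
  x2[1, 1] <- NaN
  expect_error(train_svr(x2, y, hp), "non-finite")
})

test_that("artifact-based prediction equals the reference solver's", {
  set.seed(602)
  x <- matrix(stats::runif(60 * 4), ncol = 4)
  colnames(x) <- paste0("f", 1:4)
  y <- sin(2 * x[, 1]) + 0.5 * x[, 3]
  hp <- list(gamma = 3.49121, C = 12.33292, epsilon = 1.60926e-5)
  m <- train_svr(x, y, hp)
  ref <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                    gamma = hp$gamma, cost = hp$C, epsilon = hp$epsilon,
                    scale = FALSE)
  xt <- matrix(stats::runif(30 * 4), ncol = 4)
  expect_equal(predict(m, xt), unname(as.numeric(predict(ref, xt))),
               tolerance = 1e-10)
})

test_that("a noiseless smooth surface is fitted with high training accuracy", {
  set.seed(603)
  x <- matrix(stats::runif(500 * 5), ncol = 5)
  colnames(x) <- paste0("f", 1:5)
  y <- 0.5 - 0.3 * (x[, 1] - 0.4)^2 - 0.2 * (x[, 2] - 0.6)^2 + 0.1 * x[, 3]
  hp <- list(gamma = 3.49121, C = 12.33292, epsilon = 1.60926e-5)
  m <- train_svr(x, y, hp)
  pred <- predict(m, x)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.9)
})

test_that("evaluation metrics match hand arithmetic and a brute-force oracle", {
  set.seed(604)
  x <- matrix(stats::runif(30 * 2), ncol = 2)
  colnames(x) <- c("f1", "f2")
  y <- x[, 1]
  hp <- list(gamma = 1, C = 10, epsilon = 1e-4)
  m <- train_svr(x, y, hp)

  # perfect predictions -> all zeros
  pred <- predict(m, x)
  perfect <- evaluate_surrogate(m, x, pred)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)

  # errors {3, 4}: MAE 3.5, MSE 12.5, RMSE 3.53553
  two <- x[1:2, ]
  p2 <- predict(m, two)
  met <- evaluate_surrogate(m, two, p2 + c(3, 4))
  expect_equal(met$mae, 3.5)
  expect_equal(met$mse, 12.5)
  expect_equal(met$rmse, sqrt(12.5))
  expect_equal(round(met$rmse, 5), 3.53553)

  # rmse = sqrt(mse) and mae <= rmse on random evaluations; brute-force check
  for (i in 1:20) {
    yy <- stats::rnorm(15)
    mm <- evaluate_surrogate(m, x[1:15, ], yy)
    e <- yy - predict(m, x[1:15, ])
    expect_equal(mm$mae, sum(abs(e)) / 15, tolerance = 1e-12)
    expect_equal(mm$mse, sum(e^2) / 15, tolerance = 1e-12)
    expect_equal(mm$rmse, sqrt(mm$mse), tolerance = 1e-9)
    expect_lte(mm$mae, mm$rmse + 1e-12)
  }
  expect_error(evaluate_surrogate(m, x[0, , drop = FALSE], numeric(0)),
               "empty test set")
})

test_that("metrics are reported in original label units via the inverse chain", {
  ds <- small_dataset(n = 150, seed = 61)
  p <- preprocess_pipeline(ds)
  fit <- fit_surrogates(p, raw_labels = ds$labels)
  for (lab in names(fit$metrics)) {
    m <- fit$metrics[[lab]]
    expect_lte(m$mae, m$rmse + 1e-9)
    expect_equal(m$rmse, sqrt(m$mse), tolerance = 1e-9)
    # in label units the diameter errors are tens of nm, not fractions
    rng <- diff(range(ds$labels[, lab]))
    expect_lt(m$rmse, rng)
  }
  expect_identical(fit$metrics[[1]]$n,
                   length(fit$splits[[1]]$test))
})

test_that("surrogates survive a JSON round trip at machine precision", {
  ds <- small_dataset(n = 60, seed = 62)
  p <- preprocess_pipeline(ds)
  fit <- fit_surrogates(p, raw_labels = ds$labels)
  m <- fit$models$drug_release_pct
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(m, path)
  m2 <- read_surrogate(path)
  xt <- matrix(stats::runif(20 * length(m$feature_set)), ncol = length(m$feature_set))
  colnames(xt) <- m$feature_set
  expect_equal(predict(m, xt), predict(m2, xt), tolerance = 1e-12)
  expect_equal(predict(m, xt, units = "original"),
               predict(m2, xt, units = "original"), tolerance = 1e-12)
})
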