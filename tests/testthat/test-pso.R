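test_that("PSO drives a 5-D sphere below 1e-4 with the published coefficients", {
  sphere <- function(x) sum((x - 0.5)^2)
  res <- pso_minimize(sphere, rep(0, 5), rep(1, 5), pso_config(seed = 71))
  expect_lt(res$f_best, 1e-4)
  expect_true(all(abs(res$x_best - 0.5) < 0.05))
  # best-ever bookkeeping is monotone non-increasing
  expect_true(all(diff(res$history) <= 0))
})

test_that("PSO is deterministic given the seed and rejects bad objectives", {
  f <- function(x) sum(x^2) + sum(cos(5 * x))
  r1 <- pso_minimize(f, rep(-1, 3), rep(1, 3), pso_config(seed = 5))
  r2 <- pso_minimize(f, rep(-1, 3), rep(1, 3), pso_config(seed = 5))
  expect_identical(r1, r2)
  r3 <- pso_minimize(f, rep(-1, 3), rep(1, 3), pso_config(seed = 6))
  expect_false(identical(r1$x_best, r3$x_best))

  expect_error(
    pso_minimize(function(x) NaN, c(0, 0), c(1, 1),
                 pso_config(n_iters = 2, seed = 1)),
    "non-finite")
})

test_that("the swarm-best particle is a fixed point of the update rule", {
  # with omega = 0 and c1 = 0, velocity is c2*r2*(gbest - x): the particle
  # sitting at gbest never moves while it stays the best
  positions <- list()
  f <- function(x) {
    positions[[length(positions) + 1L]] <<- x
    sum((x - 0.3)^2)
  }
  cfg <- pso_config(c1 = 0, c2 = 2, omega = 0, n_particles = 4, n_iters = 1,
                    seed = 9)
  pso_minimize(f, rep(0, 2), rep(1, 2), cfg)
  mat <- do.call(rbind, positions)
  init <- mat[1:4, , drop = FALSE]
  best0 <- which.min(apply(init, 1, function(x) sum((x - 0.3)^2)))
  # the swarm-best particle's position is unchanged by the update,
  # the others all moved
  expect_identical(mat[4 + best0, ], init[best0, ])
  for (j in setdiff(1:4, best0))
    expect_false(identical(mat[4 + j, ], init[j, ]))
})

test_that("inverse design recovers a planted optimum through the full chain", {
  tr <- noiseless_truth()
  g <- generate_dataset(synthetic_config(n_rows = 1200, seed = 77,
                                         mode = "surface", truth = tr,
                                         n_missing = 0))
  p <- preprocess_pipeline(g$dataset)
  fit <- fit_surrogates(p, raw_labels = g$dataset$labels)
  o <- optimize_label(fit$models$average_diameter_nm,
                      cfg = pso_config(seed = 3))
  expect_identical(o$direction, "minimize")
  err <- recovery_errors(o, true_optimum(g$truth, "average_diameter_nm"))
  expect_lt(stats::median(err), 0.1)

  # optima always lie inside the original-unit bounds
  sc <- nanofiber_schema()
  for (f in names(o$x_opt)) {
    i <- match(f, sc$name)
    expect_gte(o$x_opt[[f]], sc$lower[i] - 1e-6)
    expect_lte(o$x_opt[[f]], sc$upper[i] + 1e-6)
  }
  # history on the label scale is monotone non-increasing for minimization
  expect_true(all(diff(o$history) <= 1e-12))

  # maximizing equals minimizing the negated surrogate under the same seed
  mdl <- fit$models$encapsulation_efficiency_pct
  o_max <- optimize_label(mdl, cfg = pso_config(seed = 4))
  neg <- function(x) -predict(mdl, matrix(x, nrow = 1))
  o_min <- pso_minimize(neg, rep(0, length(mdl$feature_set)),
                        rep(1, length(mdl$feature_set)), pso_config(seed = 4))
  expect_equal(unname(o_max$x_opt_scaled), o_min$x_best)
  expect_true(all(diff(o_max$history) >= -1e-12))
})

test_that("optimal-range aggregation is the per-feature min/max", {
  ref <- published_reference()$optima
  per_label <- lapply(label_names(), function(lab)
    stats::setNames(ref[, lab], rownames(ref)))
  names(per_label) <- label_names()
  tab <- aggregate_optimal_ranges(per_label)

  # reported distance optima {15.0380, 13.0735, 14.1093, 19.5443}
  expect_equal(tab$range_min[tab$feature == "distance_cm"], 13.0735)
  expect_equal(tab$range_max[tab$feature == "distance_cm"], 19.5443)
  # reported dielectric optima {14.8257, 65.1107, 5.3971, 25.8070}
  expect_equal(tab$range_min[tab$feature == "dielectric_constant"], 5.3971)
  expect_equal(tab$range_max[tab$feature == "dielectric_constant"], 65.1107)
  # study-time rows are excluded
  expect_identical(nrow(tab), 10L)
  expect_false(any(grepl("time", tab$feature)))

  # brute-force min/max oracle on random optima; zero width for identical ones
  set.seed(702)
  rand <- lapply(label_names(), function(lab) {
    v <- stats::runif(12)
    names(v) <- rownames(ref)
    v
  })
  names(rand) <- label_names()
  tab2 <- aggregate_optimal_ranges(rand)
  for (f in tab2$feature) {
    vals <- vapply(rand, function(v) v[[f]], numeric(1))
    expect_equal(tab2$range_min[tab2$feature == f], min(vals))
    expect_equal(tab2$range_max[tab2$feature == f], max(vals))
  }
  same <- rand
  for (lab in names(same)) same[[lab]] <- rand[[1]]
  tab3 <- aggregate_optimal_ranges(same)
  expect_equal(tab3$range_min, tab3$range_max)

  expect_error(aggregate_optimal_ranges(rand[1:3]), "completeness")
})
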