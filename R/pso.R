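#' Particle-swarm configuration
#'
#' Defaults are the published swarm coefficients obtained by trial-and-error
#' calibration: a low cognitive weight C1 = 0.4862, a dominant social weight
#' C2 = 2.5067 and a negative inertia Omega = -0.2887 (particles readily
#' reverse direction, which counteracts premature convergence). Swarm size
#' 50 and 200 iterations with zero initial velocity are package defaults.
#'
#' @param c1 Cognitive coefficient (pull toward a particle's own best).
#' @param c2 Social coefficient (pull toward the swarm best).
#' @param omega Inertia weight.
#' @param n_particles Swarm size (>= 2).
#' @param n_iters Iterations (>= 1).
#' @param seed Integer seed.
#' @return A \code{pso_config} list.
#' @export
pso_config <- function(c1 = 0.4862, c2 = 2.5067, omega = -0.2887,
                       n_particles = 50L, n_iters = 200L, seed = 1L) {
  stopifnot(n_particles >= 2L, n_iters >= 1L)
  structure(list(c1 = c1, c2 = c2, omega = omega,
                 n_particles = as.integer(n_particles),
                 n_iters = as.integer(n_iters), seed = as.integer(seed)),
            class = "pso_config")
}

#' Particle-swarm minimization over a box
#'
#' Standard global-best PSO: per dimension,
#' \eqn{v \leftarrow \omega v + c_1 r_1 (p - x) + c_2 r_2 (g - x)},
#' \eqn{x \leftarrow x + v}, with \eqn{r_1, r_2} uniform per dimension and
#' positions clipped to the bounds. Positions are initialized uniformly in
#' the box, velocities at zero. Deterministic given the seed.
#'
#' @param objective Function mapping a numeric vector to a finite scalar.
#' @param lower,upper Numeric bounds per dimension.
#' @param cfg A [pso_config()].
#' @return List: \code{x_best}, \code{f_best}, \code{history}
#'   (best-ever objective per iteration, non-increasing).
#' @export
pso_minimize <- function(objective, lower, upper, cfg = pso_config()) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  d <- length(lower)
  np <- cfg$n_particles
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  lo <- matrix(lower, np, d, byrow = TRUE)
  hi <- matrix(upper, np, d, byrow = TRUE)
  x <- lo + matrix(stats::runif(np * d), np, d) * (hi - lo)
  v <- matrix(0, np, d)

  eval_all <- function(xm) {
    f <- apply(xm, 1L, objective)
    if (any(!is.finite(f)))
      stop("optimization error: non-finite objective value", call. = FALSE)
    f
  }
  f <- eval_all(x)
  pbest <- x
  pbest_f <- f
  g <- which.min(f)
  gbest <- x[g, ]
  gbest_f <- f[g]
  history <- numeric(cfg$n_iters)

  for (it in seq_len(cfg$n_iters)) {
    r1 <- matrix(stats::runif(np * d), np, d)
    r2 <- matrix(stats::runif(np * d), np, d)
    v <- cfg$omega * v + cfg$c1 * r1 * (pbest - x) +
      cfg$c2 * r2 * (matrix(gbest, np, d, byrow = TRUE) - x)
    x <- pmin(pmax(x + v, lo), hi)
    f <- eval_all(x)
    improved <- f < pbest_f
    pbest[improved, ] <- x[improved, , drop = FALSE]
    pbest_f[improved] <- f[improved]
    g <- which.min(pbest_f)
    if (pbest_f[g] < gbest_f) {
      gbest <- pbest[g, ]
      gbest_f <- pbest_f[g]
    }
    history[it] <- gbest_f
  }
  list(x_best = gbest, f_best = gbest_f, history = history)
}

#' Inverse design for one label
#'
#' Runs PSO over the scaled [0,1] cube restricted to the label's feature
#' set, with the surrogate prediction as objective (negated when
#' maximizing), and maps the best position back to original units through
#' the stored transform chain. Direction defaults to the study's goals:
#' minimize the fiber diameter, maximize the other three responses.
#'
#' @param model A \code{fiber_svr} with a stored transform state.
#' @param direction \code{"minimize"} or \code{"maximize"}; default looked
#'   up from [label_schema()].
#' @param cfg A [pso_config()].
#' @return Object of class \code{optimization_result}: \code{label},
#'   \code{direction}, \code{x_opt} (named, original units),
#'   \code{x_opt_scaled}, \code{predicted_value} (original label units),
#'   \code{history} (best objective per iteration, on the search scale).
#' @export
optimize_label <- function(model, direction = NULL, cfg = pso_config()) {
  stopifnot(inherits(model, "fiber_svr"))
  if (is.null(model$sv)) stop("state error: untrained model", call. = FALSE)
  lab <- model$label
  if (is.null(direction)) {
    lsc <- label_schema()
    direction <- lsc$direction[match(lab, lsc$name)]
  }
  direction <- match.arg(direction, c("minimize", "maximize"))
  sgn <- if (direction == "maximize") -1 else 1
  d <- length(model$feature_set)
  obj <- function(x) sgn * predict(model, matrix(x, nrow = 1))
  res <- pso_minimize(obj, rep(0, d), rep(1, d), cfg)
  x_scaled <- stats::setNames(res$x_best, model$feature_set)
  x_opt <- x_scaled
  pred <- sgn * res$f_best
  if (!is.null(model$transform)) {
    x_opt <- transform_invert(model$transform,
                              matrix(x_scaled, nrow = 1,
                                     dimnames = list(NULL, model$feature_set)))
    x_opt <- stats::setNames(as.numeric(x_opt), model$feature_set)
    pred <- as.numeric(transform_invert(model$transform, sgn * res$f_best,
                                        cols = lab))
  }
  structure(list(label = lab, direction = direction, x_opt = x_opt,
                 x_opt_scaled = x_scaled, predicted_value = pred,
                 history = sgn * res$history),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> %s (%s): predicted %.4f\n",
              x$label, x$direction, x$predicted_value))
  print(round(x$x_opt, 4))
  invisible(x)
}

#' Aggregate per-label optima into per-feature optimal ranges
#'
#' For each of the 10 fixed features, the range is the strict min/max of
#' that feature's value across the four per-label optima; study-time
#' features are excluded (they differ by study design and admit no joint
#' optimum). Both endpoints are attained by at least one label's optimum.
#'
#' @param results List of four \code{optimization_result}s (or named numeric
#'   optimum vectors), one per label.
#' @return Data frame of class \code{optimal_range_table}: \code{feature},
#'   \code{range_min}, \code{range_max}.
#' @export
aggregate_optimal_ranges <- function(results) {
  labs <- label_names()
  vecs <- lapply(results, function(r)
    if (inherits(r, "optimization_result")) r$x_opt else r)
  have <- if (!is.null(names(results))) names(results)
          else vapply(results, function(r) r$label, character(1))
  absent <- setdiff(labs, have)
  if (length(absent))
    stop("completeness error: missing label(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  fixed <- fixed_features()
  rng <- t(vapply(fixed, function(f) {
    vals <- vapply(vecs, function(v) v[[f]], numeric(1))
    c(min(vals), max(vals))
  }, numeric(2)))
  structure(data.frame(feature = fixed, range_min = rng[, 1L],
                       range_max = rng[, 2L], stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("optimal_range_table", "data.frame"))
}
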