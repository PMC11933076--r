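#' Quantile-anchored marginal sampler
#'
#' Draws a value from the piecewise-linear inverse CDF through
#' (0, min), (0.25, q1), (0.5, q2), (0.75, q3), (1, max). This reproduces a
#' column's published five-number summary exactly in the large-sample limit
#' while never leaving [min, max].
#'
#' @param anchors Numeric \code{c(min, q1, q2, q3, max)}, non-decreasing.
#' @param u Probabilities in [0, 1] (vectorized).
#' @return Sampled values, same length as \code{u}.
#' @export
sample_marginal <- function(anchors, u) {
  stopifnot(length(anchors) == 5L, !is.unsorted(anchors))
  if (any(u < 0 | u > 1)) stop("u outside [0, 1]", call. = FALSE)
  stats::approx(x = c(0, 0.25, 0.5, 0.75, 1), y = anchors, xout = u,
                ties = "ordered")$y
}

#' Planted response surfaces with known optima
#'
#' Defines, per label, a quadratic surface over three active features with a
#' closed-form optimum strictly inside the feature bounds, so that
#' end-to-end optimum recovery is testable. Defaults place the optima in the
#' regions the electrospinning literature reports: the diameter bowl bottoms
#' out near 15 cm needle-collector distance, 1.52 g/cm3 polymer density and
#' 9 wt% polymer concentration; the anticancer peak sits at high polymer
#' density with DOX near 3.18 wt%; encapsulation peaks near moderate polymer
#' concentration, dielectric constant 40 and 23 kV; release peaks near
#' 6.618 wt% concentration, 14.109 cm and 1 mL/h.
#'
#' Each surface is \eqn{base \pm \sum_i c_i ((x_i - x^*_i)/(ub_i - lb_i))^2}
#' (\code{+} for a bowl, \code{-} for a peak) plus an optional linear
#' background (zero by default so the optimum stays interior).
#'
#' @return An object of class \code{synthetic_truth}: named list per label
#'   with fields \code{kind} ("bowl"/"peak"), \code{active}, \code{x_star},
#'   \code{curvature}, \code{base}, \code{background}, \code{noise_sd},
#'   \code{clip} (label bounds).
#' @export
default_truth <- function() {
  a <- default_anchors()
  rng <- function(nm) a[[nm]][5L] - a[[nm]][1L]
  surf <- function(label, kind, active, x_star, curvature, base, noise_sd) {
    list(kind = kind, active = active,
         x_star = stats::setNames(x_star, active),
         curvature = stats::setNames(curvature, active),
         base = base,
         background = stats::setNames(numeric(length(active)), active),
         noise_sd = noise_sd,
         clip = c(a[[label]][1L], a[[label]][5L]))
  }
  structure(list(
    average_diameter_nm = surf(
      "average_diameter_nm", "bowl",
      c("distance_cm", "polymer_density_g_cm3", "polymer_concentration_wt_pct"),
      c(15, 1.52, 9), c(450, 350, 300), base = 60,
      noise_sd = 0.04 * rng("average_diameter_nm")),
    encapsulation_efficiency_pct = surf(
      "encapsulation_efficiency_pct", "peak",
      c("polymer_concentration_wt_pct", "dielectric_constant", "voltage_kv"),
      c(7.2, 40, 23), c(60, 45, 40), base = 95,
      noise_sd = 0.04 * rng("encapsulation_efficiency_pct")),
    drug_release_pct = surf(
      "drug_release_pct", "peak",
      c("polymer_concentration_wt_pct", "distance_cm", "flow_rate_ml_h"),
      c(6.618, 14.109, 1.0), c(50, 40, 35), base = 97,
      noise_sd = 0.04 * rng("drug_release_pct")),
    anticancer_activity_pct = surf(
      "anticancer_activity_pct", "peak",
      c("polymer_density_g_cm3", "polymer_concentration_wt_pct",
        "dox_concentration_wt_pct"),
      c(1.50, 5, 3.18), c(50, 40, 35), base = 88,
      noise_sd = 0.04 * rng("anticancer_activity_pct"))
  ), class = "synthetic_truth")
}

#' Evaluate a planted surface (noiseless) at feature values
#'
#' @param truth A \code{synthetic_truth}.
#' @param label Label name.
#' @param features Matrix or data frame with (at least) the surface's active
#'   feature columns, original units.
#' @param clip Clip the result to the label bounds (default \code{TRUE}).
#' @return Numeric vector of surface values in label units.
#' @export
surface_value <- function(truth, label, features, clip = TRUE) {
  tr <- truth[[label]]
  if (is.null(tr)) stop("unknown label: ", label, call. = FALSE)
  a <- default_anchors()
  features <- as.matrix(as.data.frame(features)[, tr$active, drop = FALSE])
  dev2 <- 0
  bg <- 0
  for (f in tr$active) {
    scale <- a[[f]][5L] - a[[f]][1L]
    dev2 <- dev2 + tr$curvature[[f]] * ((features[, f] - tr$x_star[[f]]) / scale)^2
    bg <- bg + tr$background[[f]] * features[, f]
  }
  sgn <- if (tr$kind == "bowl") 1 else -1
  v <- tr$base + sgn * dev2 + bg
  if (clip) v <- pmin(pmax(v, tr$clip[1L]), tr$clip[2L])
  unname(v)
}

#' Closed-form optimum of a planted surface
#'
#' Returns the stored optimum location (no search): the minimizer for a bowl
#' surface, the maximizer for a peak.
#'
#' @param truth A \code{synthetic_truth}.
#' @param label Label name.
#' @return Named numeric vector over the surface's active features,
#'   original units.
#' @export
true_optimum <- function(truth, label) {
  tr <- truth[[label]]
  if (is.null(tr)) stop("unknown label: ", label, call. = FALSE)
  tr$x_star
}

#' Synthetic-generation configuration
#'
#' @param n_rows Number of records (default 200, a realistic size for a
#'   literature-mined formulation table).
#' @param seed Integer seed; one seed drives feature draws, label noise and
#'   missingness through independent substreams.
#' @param mode \code{"marginal"} (labels drawn from their own anchors,
#'   independent of features) or \code{"surface"} (labels computed from the
#'   planted response surfaces plus Gaussian noise, clipped to label bounds).
#' @param anchors Named list of five-number anchors; default
#'   [default_anchors()].
#' @param truth Planted surfaces; default [default_truth()].
#' @param n_missing Number of fixed-feature cells masked at random
#'   (default 126, the count removed/imputed in the source dataset).
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_rows = 200L, seed = 1L,
                             mode = c("surface", "marginal"),
                             anchors = default_anchors(),
                             truth = default_truth(),
                             n_missing = 126L) {
  mode <- match.arg(mode)
  n_rows <- as.integer(n_rows)
  n_missing <- as.integer(n_missing)
  stopifnot(n_rows > 0L, n_missing >= 0L)
  n_fixed_cells <- n_rows * length(fixed_features())
  if (n_missing > n_fixed_cells)
    stop(sprintf("config error: n_missing (%d) exceeds fixed-feature cells (%d)",
                 n_missing, n_fixed_cells), call. = FALSE)
  structure(list(n_rows = n_rows, seed = as.integer(seed), mode = mode,
                 anchors = anchors, truth = truth, n_missing = n_missing),
            class = "synthetic_config")
}

# Independent substream seeds derived from one master seed.
substream_seeds <- function(seed, n = 3L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Generate a literature-like synthetic formulation dataset
#'
#' Features are drawn independently per column through the anchored inverse
#' CDF ([sample_marginal()]); only the marginals are calibrated — the
#' published statistics identify no dependence structure, so none is
#' invented. Labels are either drawn the same way (\code{mode = "marginal"})
#' or computed from the planted surfaces with additive Gaussian noise and
#' clipped to the label bounds (\code{mode = "surface"}). Missingness is then
#' injected MCAR into fixed-feature cells. Deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @return List with elements \code{dataset} (a [nanofiber_dataset()]) and
#'   \code{truth} (the planted [default_truth()]-style object, returned
#'   verbatim).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- substream_seeds(config$seed, 3L)
  n <- config$n_rows
  schema <- nanofiber_schema()
  lsc <- label_schema()

  set.seed(seeds[1L])
  features <- vapply(schema$name, function(nm)
    sample_marginal(config$anchors[[nm]], stats::runif(n)), numeric(n))
  if (n == 1L) features <- matrix(features, 1, dimnames = list(NULL, schema$name))

  set.seed(seeds[2L])
  if (config$mode == "marginal") {
    labels <- vapply(lsc$name, function(nm)
      sample_marginal(config$anchors[[nm]], stats::runif(n)), numeric(n))
  } else {
    labels <- vapply(lsc$name, function(nm) {
      tr <- config$truth[[nm]]
      v <- surface_value(config$truth, nm, features, clip = FALSE) +
        stats::rnorm(n, 0, tr$noise_sd)
      pmin(pmax(v, tr$clip[1L]), tr$clip[2L])
    }, numeric(n))
  }
  if (n == 1L) labels <- matrix(labels, 1, dimnames = list(NULL, lsc$name))

  ds <- nanofiber_dataset(features, labels)
  if (config$n_missing > 0L)
    ds <- inject_missingness(ds, config$n_missing, seeds[3L])
  list(dataset = ds, truth = config$truth)
}

#' Mask fixed-feature cells completely at random
#'
#' Exactly \code{n_missing} distinct fixed-feature cells are chosen
#' uniformly without replacement and set to the absent state; study-time
#' features and labels are never masked. Deterministic given \code{seed}.
#'
#' @param ds A [nanofiber_dataset()].
#' @param n_missing Number of cells to mask (default 126).
#' @param seed Integer seed.
#' @return The dataset with an updated missing mask.
#' @export
inject_missingness <- function(ds, n_missing = 126L, seed = 1L) {
  stopifnot(inherits(ds, "nanofiber_dataset"))
  n_missing <- as.integer(n_missing)
  fixed <- fixed_features()
  cells <- nrow(ds$features) * length(fixed)
  if (n_missing > cells)
    stop(sprintf("config error: n_missing (%d) exceeds fixed-feature cells (%d)",
                 n_missing, cells), call. = FALSE)
  if (n_missing == 0L) return(ds)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(cells, n_missing)
  rows <- ((idx - 1L) %% nrow(ds$features)) + 1L
  cols <- match(fixed, colnames(ds$features))[((idx - 1L) %/% nrow(ds$features)) + 1L]
  features <- ds$features
  mask <- ds$missing_mask
  features[cbind(rows, cols)] <- NA_real_
  mask[cbind(rows, cols)] <- TRUE
  nanofiber_dataset(features, ds$labels, mask)
}
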