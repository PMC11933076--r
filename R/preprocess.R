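#' Fit a two-parameter Box-Cox transform to one column
#'
#' The shift is 0 when the column minimum is positive, otherwise
#' \code{1e-6 - min} (the smallest perturbation preserving positivity —
#' several columns of the formulation table have minimum 0). The exponent
#' \eqn{\lambda} maximizes the Box-Cox profile log-likelihood
#' \eqn{-\frac{n}{2}\log\hat\sigma^2(z_\lambda) + (\lambda-1)\sum\log y}
#' on the shifted values.
#'
#' @param column Numeric vector; \code{NA}s (missing cells) are ignored.
#' @param lambda_range Search interval for \eqn{\lambda}.
#' @return List \code{(shift, lambda)}.
#' @export
fit_box_cox <- function(column, lambda_range = c(-5, 5)) {
  y <- column[!is.na(column)]
  if (length(y) < 3L)
    stop("degenerate column: fewer than 3 observed values", call. = FALSE)
  if (diff(range(y)) == 0)
    stop("degenerate column: all observed values equal", call. = FALSE)
  shift <- if (min(y) > 0) 0 else 1e-6 - min(y)
  y <- y + shift
  logy <- log(y)
  n <- length(y)
  prof_ll <- function(lambda) {
    z <- box_cox_forward(y, lambda = lambda, shift = 0)
    s2 <- sum((z - mean(z))^2) / n
    -n / 2 * log(s2) + (lambda - 1) * sum(logy)
  }
  opt <- stats::optimize(prof_ll, lambda_range, maximum = TRUE, tol = 1e-6)
  list(shift = shift, lambda = opt$maximum)
}

#' Box-Cox forward and inverse transforms
#'
#' Forward: \eqn{((x + shift)^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0},
#' \eqn{\log(x + shift)} for \eqn{\lambda = 0}. Inverse undoes both steps;
#' out-of-domain inputs (where \eqn{\lambda z + 1 \le 0}) are clamped to the
#' domain boundary so the inverse stays finite on surrogate extrapolations.
#'
#' @param x Numeric vector.
#' @param lambda Box-Cox exponent.
#' @param shift Pre-transform shift.
#' @return Transformed values.
#' @export
box_cox_forward <- function(x, lambda, shift = 0) {
  y <- x + shift
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' @rdname box_cox_forward
#' @param z Transformed values.
#' @export
box_cox_inverse <- function(z, lambda, shift = 0) {
  y <- if (abs(lambda) < 1e-12) exp(z)
       else pmax(lambda * z + 1, .Machine$double.eps)^(1 / lambda)
  y - shift
}

#' SoftImpute matrix completion
#'
#' Iterative soft-thresholded SVD: missing cells start at their column
#' means; each sweep computes the SVD of the current completion, shrinks the
#' singular values by \code{lambda_nuclear} (nuclear-norm proximal step) and
#' overwrites only the missing cells with the shrunken reconstruction, until
#' the relative Frobenius change of the imputed entries falls below
#' \code{tol}. The regularized objective
#' \eqn{\frac12\|P_{obs}(X - Z)\|_F^2 + \lambda\|Z\|_*}
#' is recorded each sweep; it is non-increasing.
#'
#' @param x Numeric matrix with \code{NA} at missing cells.
#' @param lambda_nuclear Singular-value shrinkage; default 0.1 times the
#'   largest singular value of the mean-filled matrix.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Sweep cap.
#' @return List of class \code{imputation_result}: \code{completed},
#'   \code{lambda_nuclear}, \code{n_iter}, \code{converged},
#'   \code{final_delta}, \code{objective} (per-sweep trace).
#' @export
soft_impute <- function(x, lambda_nuclear = NULL, tol = 1e-5, max_iter = 500L) {
  x <- as.matrix(x)
  miss <- is.na(x)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("imputation error: fully-missing column(s): ",
         paste(colnames(x)[all_missing], collapse = ", "), call. = FALSE)
  if (!any(miss)) {
    return(structure(list(completed = x, lambda_nuclear = lambda_nuclear,
                          n_iter = 0L, converged = TRUE, final_delta = 0,
                          objective = numeric()),
                     class = "imputation_result"))
  }
  mu <- colMeans(x, na.rm = TRUE)
  z <- x
  for (j in seq_len(ncol(z))) z[miss[, j], j] <- mu[j]
  if (is.null(lambda_nuclear))
    lambda_nuclear <- 0.1 * svd(z, nu = 0, nv = 0)$d[1L]

  objective <- numeric(0)
  delta <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sv <- svd(z)
    d_thr <- pmax(sv$d - lambda_nuclear, 0)
    z_thr <- sv$u %*% (d_thr * t(sv$v))
    obj <- 0.5 * sum((x[!miss] - z_thr[!miss])^2) + lambda_nuclear * sum(d_thr)
    objective <- c(objective, obj)
    old_miss <- z[miss]
    new_miss <- z_thr[miss]
    denom <- sqrt(sum(old_miss^2))
    delta <- if (denom > 0) sqrt(sum((new_miss - old_miss)^2)) / denom
             else sqrt(sum(new_miss^2))
    z[miss] <- new_miss
    if (delta < tol || iter >= max_iter) break
  }
  structure(list(completed = z, lambda_nuclear = lambda_nuclear,
                 n_iter = iter, converged = delta < tol,
                 final_delta = delta, objective = objective),
            class = "imputation_result")
}

#' Min-max scaling and its inverse
#'
#' \eqn{x_{scaled} = (x - x_{min})/(x_{max} - x_{min})}; the anchors map to
#' exactly 0 and 1.
#'
#' @param x Numeric vector.
#' @param x_min,x_max Scaling anchors, \code{x_max > x_min}.
#' @return Scaled values (or originals for the inverse).
#' @export
min_max_scale <- function(x, x_min, x_max) {
  if (x_max <= x_min) stop("degenerate column: x_max <= x_min", call. = FALSE)
  (x - x_min) / (x_max - x_min)
}

#' @rdname min_max_scale
#' @export
inverse_min_max <- function(x, x_min, x_max) {
  if (x_max <= x_min) stop("degenerate column: x_max <= x_min", call. = FALSE)
  x * (x_max - x_min) + x_min
}

#' Full preprocessing chain
#'
#' Per column (features and labels): Box-Cox toward normality; then
#' SoftImpute completion of the feature matrix (labels are never imputed —
#' rows missing a label are simply unavailable to that label's model); then
#' min-max scaling of every column to [0, 1]. Imputed cells are clamped to
#' the observed range of their column, so the scaling anchors — and with
#' them the inverse-design search cube — never leave physically observed
#' values. The returned transform state makes the whole chain invertible,
#' so surrogate predictions and optimizer positions can be mapped back to
#' original units.
#'
#' @param ds A [nanofiber_dataset()].
#' @param lambda_nuclear,tol,max_iter Passed to [soft_impute()].
#' @return List: \code{dataset} (transformed [nanofiber_dataset()], features
#'   complete in [0,1]), \code{state} (a \code{transform_state}),
#'   \code{imputation} (the [soft_impute()] result).
#' @export
preprocess_pipeline <- function(ds, lambda_nuclear = NULL, tol = 1e-5,
                                max_iter = 500L) {
  stopifnot(inherits(ds, "nanofiber_dataset"))
  cols <- c(colnames(ds$features), colnames(ds$labels))
  raw <- cbind(ds$features, ds$labels)

  state <- lapply(cols, function(nm) {
    bc <- fit_box_cox(raw[, nm])
    c(bc, list(x_min = NA_real_, x_max = NA_real_, fitted = FALSE))
  })
  names(state) <- cols

  bc_mat <- raw
  for (nm in cols)
    bc_mat[, nm] <- box_cox_forward(raw[, nm], state[[nm]]$lambda,
                                    state[[nm]]$shift)

  fcols <- colnames(ds$features)
  imput <- soft_impute(bc_mat[, fcols, drop = FALSE],
                       lambda_nuclear = lambda_nuclear, tol = tol,
                       max_iter = max_iter)
  completed <- imput$completed
  # imputation must not extend a column's support: clamp imputed cells to
  # the observed range so scaling anchors (and hence the optimizer's search
  # cube) stay inside physically observed values
  for (nm in fcols) {
    obs <- bc_mat[!ds$missing_mask[, nm], nm]
    completed[, nm] <- pmin(pmax(completed[, nm], min(obs)), max(obs))
  }
  imput$completed <- completed
  bc_mat[, fcols] <- completed

  out <- bc_mat
  for (nm in cols) {
    v <- bc_mat[, nm]
    state[[nm]]$x_min <- min(v, na.rm = TRUE)
    state[[nm]]$x_max <- max(v, na.rm = TRUE)
    state[[nm]]$fitted <- TRUE
    out[, nm] <- min_max_scale(v, state[[nm]]$x_min, state[[nm]]$x_max)
  }
  state <- structure(state, class = "transform_state")
  # the transformed dataset keeps the original mask as a record of which
  # feature cells were imputed, so it bypasses the raw-dataset constructor
  # (whose invariant ties the mask to NA cells)
  tds <- structure(
    list(features = out[, fcols, drop = FALSE],
         labels = out[, colnames(ds$labels), drop = FALSE],
         missing_mask = ds$missing_mask, schema = ds$schema,
         label_schema = ds$label_schema),
    class = "nanofiber_dataset")
  list(dataset = tds, state = state, imputation = imput)
}

#' Apply or invert a fitted transform chain on selected columns
#'
#' @param state A \code{transform_state} from [preprocess_pipeline()].
#' @param m Matrix (or vector for a single column) in original units
#'   (\code{transform_apply}) or on the scaled [0,1] scale
#'   (\code{transform_invert}).
#' @param cols Column names; defaults to \code{colnames(m)}.
#' @return Matrix/vector of the same shape on the other scale.
#' @export
transform_apply <- function(state, m, cols = colnames(m)) {
  .transform_map(state, m, cols, inverse = FALSE)
}

#' @rdname transform_apply
#' @export
transform_invert <- function(state, m, cols = colnames(m)) {
  .transform_map(state, m, cols, inverse = TRUE)
}

.transform_map <- function(state, m, cols, inverse) {
  if (is.null(cols)) stop("column names required", call. = FALSE)
  vec <- is.null(dim(m))
  if (vec) {
    # a bare vector is one column of values when a single column is named,
    # otherwise one row across the named columns
    m <- if (length(cols) == 1L) matrix(m, ncol = 1, dimnames = list(NULL, cols))
         else matrix(m, nrow = 1, dimnames = list(NULL, cols))
  }
  out <- m
  for (j in seq_along(cols)) {
    st <- state[[cols[j]]]
    if (is.null(st) || !isTRUE(st$fitted))
      stop("transform not fitted for column: ", cols[j], call. = FALSE)
    out[, j] <- if (inverse) {
      box_cox_inverse(inverse_min_max(m[, j], st$x_min, st$x_max),
                      st$lambda, st$shift)
    } else {
      min_max_scale(box_cox_forward(m[, j], st$lambda, st$shift),
                    st$x_min, st$x_max)
    }
  }
  if (vec) {
    if (length(cols) == 1L) out[, 1L] else out[1L, ]
  } else out
}

#' Serialize / restore a transform state as JSON
#'
#' @param state A \code{transform_state}.
#' @param path File path.
#' @export
write_transform_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_state
#' @export
read_transform_state <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(st, class = "transform_state")
}
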