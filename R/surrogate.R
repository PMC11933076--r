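#' Published per-label SVR hyperparameters
#'
#' Final (gamma, C, epsilon) of the trained epsilon-SVR for each label.
#' These apply on the preprocessed [0,1] scale — the epsilon values
#' (down to 6.4e-5) only make sense for a compressed response. The kernel
#' is radial-basis, \eqn{K(x,x') = \exp(-\gamma\|x-x'\|^2)}; a gamma
#' parameter only exists for that family.
#'
#' @return Named list per label with \code{gamma}, \code{C}, \code{epsilon}.
#' @export
default_hyperparams <- function() {
  list(
    average_diameter_nm          = list(gamma = 41.50438, C = 32.19417, epsilon = 6.44520e-5),
    encapsulation_efficiency_pct = list(gamma = 1.16007,  C = 30.52169, epsilon = 1.23861e-3),
    drug_release_pct             = list(gamma = 3.49121,  C = 12.33292, epsilon = 1.60926e-5),
    anticancer_activity_pct      = list(gamma = 0.85080,  C = 41.04649, epsilon = 0.08052)
  )
}

#' Random 80/20 train/test split
#'
#' @param n Number of rows (or a [nanofiber_dataset()]).
#' @param test_fraction Fraction held out; test size is
#'   \code{round(test_fraction * n)}.
#' @param seed Integer seed (default 42).
#' @return List with integer index vectors \code{train} and \code{test}:
#'   disjoint, exhaustive.
#' @export
split_dataset <- function(n, test_fraction = 0.2, seed = 42L) {
  if (inherits(n, "nanofiber_dataset")) n <- nrow(n$features)
  n <- as.integer(n)
  if (n < 5L) stop("too few rows: need n >= 5", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_test <- round(test_fraction * n)
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Train an epsilon-SVR surrogate for one label
#'
#' Radial-basis-kernel support-vector regression on preprocessed ([0,1])
#' features. The fitted support vectors, dual coefficients and bias are
#' extracted as plain arrays so prediction is self-contained (and the model
#' JSON-serializable); training is delegated to [e1071::svm()].
#'
#' @param x Numeric matrix of scaled features (rows = samples), no missing
#'   values; columns are the label's feature set.
#' @param y Numeric vector, scaled label.
#' @param hp List with \code{gamma}, \code{C}, \code{epsilon}.
#' @param label Label name (metadata).
#' @param state Optional \code{transform_state}; when present, predictions
#'   can be mapped back to original label units.
#' @return Object of class \code{fiber_svr}.
#' @export
train_svr <- function(x, y, hp, label = NULL, state = NULL) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("numeric error: non-finite values in training data", call. = FALSE)
  stopifnot(all(c("gamma", "C", "epsilon") %in% names(hp)))
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                    gamma = hp$gamma, cost = hp$C, epsilon = hp$epsilon,
                    scale = FALSE, fitted = FALSE)
  structure(list(
    label = label,
    hyperparams = hp[c("gamma", "C", "epsilon")],
    feature_set = colnames(x),
    sv = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    n_train = nrow(x),
    transform = state
  ), class = "fiber_svr")
}

#' Predict from a fitted surrogate
#'
#' Evaluates \eqn{f(x) = \sum_i \alpha_i \exp(-\gamma\|x - sv_i\|^2) - \rho}
#' directly from the stored artifacts.
#'
#' @param object A \code{fiber_svr}.
#' @param newdata Matrix (or vector) of scaled features in the model's
#'   feature-set order.
#' @param units \code{"scaled"} (default) or \code{"original"} (inverse
#'   transform applied; requires the stored transform state).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.fiber_svr <- function(object, newdata, units = c("scaled", "original"),
                              ...) {
  units <- match.arg(units)
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  sv <- object$sv
  d2 <- outer(rowSums(newdata^2), rowSums(sv^2), "+") -
    2 * newdata %*% t(sv)
  d2[d2 < 0] <- 0
  pred <- as.numeric(exp(-object$hyperparams$gamma * d2) %*% object$coefs -
                       object$rho)
  if (units == "original") {
    if (is.null(object$transform))
      stop("no transform state stored with this model", call. = FALSE)
    pred <- as.numeric(transform_invert(object$transform, pred,
                                        cols = object$label))
  }
  pred
}

#' @export
print.fiber_svr <- function(x, ...) {
  cat(sprintf(
    "<fiber_svr> label=%s  features=%d  SVs=%d/%d  gamma=%g C=%g epsilon=%g\n",
    x$label %||% "?", length(x$feature_set), length(x$coefs), x$n_train,
    x$hyperparams$gamma, x$hyperparams$C, x$hyperparams$epsilon))
  invisible(x)
}

#' @export
coef.fiber_svr <- function(object, ...) {
  list(support_vectors = object$sv, dual_coefs = object$coefs,
       bias = object$rho)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a surrogate with MAE / MSE / RMSE
#'
#' \eqn{MAE = \frac1n\sum|y_i - f(x_i)|},
#' \eqn{MSE = \frac1n\sum(y_i - f(x_i))^2}, \eqn{RMSE = \sqrt{MSE}}.
#' When the model carries a transform state and \code{truth_units =
#' "original"}, predictions are inverse-transformed so the metrics are in
#' original label units (nm or percent).
#'
#' @param model A \code{fiber_svr}.
#' @param x Scaled test features (nonempty).
#' @param y True label values, in the units given by \code{truth_units}.
#' @param truth_units \code{"original"} (default when a transform is stored)
#'   or \code{"scaled"}.
#' @return Object of class \code{evaluation_metrics}: list with \code{mae},
#'   \code{mse}, \code{rmse}, \code{n}.
#' @export
evaluate_surrogate <- function(model, x, y,
                               truth_units = if (is.null(model$transform))
                                 "scaled" else "original") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0L || length(y) == 0L)
    stop("evaluation error: empty test set", call. = FALSE)
  pred <- predict(model, x, units = truth_units)
  e <- y - pred
  m <- list(mae = mean(abs(e)), mse = mean(e^2), rmse = sqrt(mean(e^2)),
            n = length(e))
  structure(m, class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("MAE %.5f  MSE %.5f  RMSE %.5f  (n=%d)\n",
              x$mae, x$mse, x$rmse, x$n))
  invisible(x)
}

#' Fit all four label surrogates on a preprocessed dataset
#'
#' For each label: keep the rows where the label is observed, split 80/20,
#' train on the label's feature set with its published hyperparameters and
#' evaluate on the held-out rows in original label units.
#'
#' @param prep Result of [preprocess_pipeline()].
#' @param hyperparams Per-label hyperparameter list
#'   (default [default_hyperparams()]).
#' @param split_seed Seed for the 80/20 split (default 42).
#' @param test_fraction Held-out fraction.
#' @param raw_labels Optional matrix of label values in original units,
#'   aligned to \code{prep$dataset}; used for original-unit metrics. When
#'   omitted, metrics are computed by inverse-transforming the scaled labels.
#' @return Object of class \code{fiber_surrogates}: per-label \code{models}
#'   and \code{metrics}, plus the split indices.
#' @export
fit_surrogates <- function(prep, hyperparams = default_hyperparams(),
                           split_seed = 42L, test_fraction = 0.2,
                           raw_labels = NULL) {
  ds <- prep$dataset
  labs <- colnames(ds$labels)
  models <- list()
  metrics <- list()
  splits <- list()
  for (lab in labs) {
    feats <- feature_set(lab)
    keep <- which(!is.na(ds$labels[, lab]))
    sp <- split_dataset(length(keep), test_fraction, split_seed)
    tr <- keep[sp$train]; te <- keep[sp$test]
    mdl <- train_svr(ds$features[tr, feats, drop = FALSE],
                     ds$labels[tr, lab],
                     hyperparams[[lab]], label = lab, state = prep$state)
    y_true <- if (!is.null(raw_labels)) raw_labels[te, lab]
              else as.numeric(transform_invert(prep$state,
                                               ds$labels[te, lab], cols = lab))
    metrics[[lab]] <- evaluate_surrogate(mdl, ds$features[te, feats, drop = FALSE],
                                         y_true, truth_units = "original")
    models[[lab]] <- mdl
    splits[[lab]] <- list(train = tr, test = te)
  }
  structure(list(models = models, metrics = metrics, splits = splits,
                 split_seed = split_seed, test_fraction = test_fraction),
            class = "fiber_surrogates")
}

#' @export
print.fiber_surrogates <- function(x, ...) {
  cat("<fiber_surrogates> epsilon-SVR per label (RBF kernel)\n")
  for (lab in names(x$models)) {
    m <- x$metrics[[lab]]
    cat(sprintf("  %-30s MAE %10.4f  MSE %12.4f  RMSE %10.4f\n",
                lab, m$mae, m$mse, m$rmse))
  }
  invisible(x)
}

#' @export
summary.fiber_surrogates <- function(object, ...) {
  df <- do.call(rbind, lapply(names(object$metrics), function(lab) {
    m <- object$metrics[[lab]]
    data.frame(label = lab, mae = m$mae, mse = m$mse, rmse = m$rmse,
               n_test = m$n, n_sv = length(object$models[[lab]]$coefs),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Serialize a surrogate to JSON and restore it
#'
#' Stores support vectors, dual coefficients, bias, hyperparameters and the
#' transform state, sufficient to reproduce predictions at machine
#' precision.
#'
#' @param model A \code{fiber_svr}.
#' @param path File path.
#' @export
write_surrogate <- function(model, path) {
  obj <- unclass(model)
  obj$transform <- if (!is.null(model$transform)) unclass(model$transform)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sv <- as.matrix(obj$sv)
  obj$coefs <- as.numeric(obj$coefs)
  if (!is.null(obj$transform))
    obj$transform <- structure(lapply(obj$transform, as.list),
                               class = "transform_state")
  structure(obj, class = "fiber_svr")
}
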