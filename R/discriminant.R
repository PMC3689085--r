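#' @noRd
new_discriminant_model <- function(mode, class_ids, means, covs, n_c, priors,
                                   pooled_cov, N, d, feature_names,
                                   include_logdet = TRUE, ridge_lambda = 0,
                                   prior_mode = "counts",
                                   update_policy = "none") {
  model <- structure(
    list(mode = mode, class_ids = class_ids, means = means, covs = covs,
         n_c = as.numeric(n_c), priors = as.numeric(priors),
         pooled_cov = pooled_cov, N = as.numeric(N), d = as.integer(d),
         feature_names = feature_names, include_logdet = include_logdet,
         ridge_lambda = ridge_lambda, prior_mode = prior_mode,
         update_policy = update_policy, cache = NULL),
    class = "discriminant_model")
  if (abs(sum(model$priors) - 1) > 1e-8) abort("class priors must sum to 1")
  rebuild_cache(model)
}

ridged <- function(sigma, lambda) {
  if (lambda <= 0) return(sigma)
  d <- nrow(sigma)
  sigma + diag(lambda * sum(diag(sigma)) / d, d)
}

chol_or_fail <- function(sigma, what) {
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) {
    abort(sprintf(
      "covariance of %s is numerically singular (consider ridge_lambda > 0)",
      what))
  }
  R
}

# Score caches hold the upper Cholesky factor and log-determinant of every
# covariance the scorer uses. `classes = NULL` rebuilds everything;
# otherwise only the named class entries (QDA) or the pooled entry (LDA).
rebuild_cache <- function(model, classes = NULL) {
  if (model$mode == "lda") {
    R <- chol_or_fail(ridged(model$pooled_cov, model$ridge_lambda),
                      "the pooled within-class matrix")
    model$cache <- list(chol = list(R), logdet = 2 * sum(log(diag(R))))
  } else {
    if (is.null(model$cache) || is.null(classes)) {
      model$cache <- list(chol = vector("list", length(model$class_ids)),
                          logdet = numeric(length(model$class_ids)))
      classes <- seq_along(model$class_ids)
    }
    for (i in classes) {
      R <- chol_or_fail(ridged(model$covs[[i]], model$ridge_lambda),
                        sprintf("class '%s'", model$class_ids[i]))
      model$cache$chol[[i]] <- R
      model$cache$logdet[i] <- 2 * sum(log(diag(R)))
    }
  }
  model
}

#' Fit a Gaussian discriminant classifier (LDA/QDA)
#'
#' Estimates, per motion class, the pattern count, mean vector and
#' covariance matrix of the window feature vectors, plus the pooled
#' within-class covariance. Covariances use the maximum-likelihood divisor
#' `n` (not `n - 1`) and the pooled matrix is the count-weighted average of
#' the per-class ML covariances: with this normalisation the incremental
#' self-enhancing recursions and a batch refit agree exactly. An
#' `unbiased = TRUE` option (divisor `n - 1`, pooled weights
#' `(n_i - 1)/(n - C)`) is available for static baselines only; do not
#' stream updates into such a model.
#'
#' @param features A feature tibble (label column plus feature columns), or
#'   any data frame shaped that way.
#' @param mode `"lda"` or `"qda"`; defaults to `config$classifier_mode`.
#' @param config An [emg_config()] providing `include_logdet`,
#'   `ridge_lambda` and `prior_mode`.
#' @param unbiased Use `n - 1` covariance normalisation (static baselines
#'   only; default `FALSE`).
#' @return A `discriminant_model`.
#' @export
fit_discriminant <- function(features, mode = NULL, config = emg_config(),
                             unbiased = FALSE) {
  mode <- mode %||% config$classifier_mode
  mode <- match.arg(mode, c("lda", "qda"))
  if (!"label" %in% names(features)) abort("`features` needs a `label` column")
  fcols <- feature_cols(features)
  if (length(fcols) < 1) abort("no feature columns found")
  X <- as.matrix(features[fcols])
  if (any(!is.finite(X))) abort("feature matrix contains non-finite values")
  labels <- as.character(features$label)
  class_ids <- sort(unique(labels))
  d <- ncol(X)
  n_c <- numeric(length(class_ids))
  means <- vector("list", length(class_ids))
  covs <- vector("list", length(class_ids))
  for (i in seq_along(class_ids)) {
    Xi <- X[labels == class_ids[i], , drop = FALSE]
    n <- nrow(Xi)
    if (n < 2) {
      abort(sprintf("class '%s' has %d pattern(s); need at least 2",
                    class_ids[i], n))
    }
    mu <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mu)
    S <- crossprod(Xc)
    n_c[i] <- n
    means[[i]] <- mu
    covs[[i]] <- S / (if (unbiased) n - 1 else n)
  }
  N <- sum(n_c)
  pooled <- if (unbiased) {
    Reduce(`+`, Map(function(s, n) (n - 1) / (N - length(class_ids)) * s,
                    covs, n_c))
  } else {
    Reduce(`+`, Map(function(s, n) n / N * s, covs, n_c))
  }
  priors <- if (config$prior_mode == "uniform") {
    rep(1 / length(class_ids), length(class_ids))
  } else {
    n_c / N
  }
  new_discriminant_model(
    mode = mode, class_ids = class_ids, means = means, covs = covs,
    n_c = n_c, priors = priors, pooled_cov = pooled, N = N, d = d,
    feature_names = fcols, include_logdet = config$include_logdet,
    ridge_lambda = config$ridge_lambda, prior_mode = config$prior_mode,
    update_policy = config$update_policy)
}

#' Discriminant scores for feature vectors
#'
#' Evaluates, for each class `i`,
#' `g_i(x) = log p(w_i) - (x - mu_i)' Sigma^{-1} (x - mu_i) / 2`
#' with `Sigma` the pooled within-class covariance (LDA) or the
#' class-specific covariance (QDA); in QDA mode the Bayes-optimal
#' `-log|Sigma_i|/2` term is added when the model was built with
#' `include_logdet = TRUE`. Quadratic forms are computed from a cached
#' Cholesky factorisation, never an explicit inverse.
#'
#' @param model A `discriminant_model`.
#' @param x Numeric vector of length `d`, or an `n x d` matrix / data frame
#'   of feature rows.
#' @return An `n x C` matrix of scores (columns named by class).
#' @export
discriminant_scores <- function(model, x) {
  stopifnot(inherits(model, "discriminant_model"))
  X <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(X) != model$d) {
    abort(sprintf("feature dimension %d does not match model dimension %d",
                  ncol(X), model$d))
  }
  if (any(!is.finite(X))) abort("feature values must be finite")
  C <- length(model$class_ids)
  out <- matrix(0, nrow(X), C, dimnames = list(NULL, model$class_ids))
  tX <- t(X)
  qda_logdet <- model$mode == "qda" && model$include_logdet
  for (i in seq_len(C)) {
    R <- if (model$mode == "lda") model$cache$chol[[1]] else model$cache$chol[[i]]
    u <- backsolve(R, tX - model$means[[i]], transpose = TRUE)
    q <- if (is.matrix(u)) colSums(u * u) else sum(u * u)
    g <- log(model$priors[i]) - q / 2
    if (qda_logdet) g <- g - model$cache$logdet[i] / 2
    out[, i] <- g
  }
  out
}

#' Classify feature vectors with a fitted discriminant model
#'
#' Assigns each row the class with the highest discriminant score; exact
#' ties go to the lowest class index (classes are kept in sorted order).
#'
#' @inheritParams discriminant_scores
#' @return Character vector of predicted class labels.
#' @export
classify <- function(model, x) {
  sc <- discriminant_scores(model, x)
  model$class_ids[max.col(sc, ties.method = "first")]
}

#' @param object A `discriminant_model`.
#' @param newdata Feature rows: matrix, numeric vector, or a feature tibble
#'   (its feature columns are selected by name).
#' @param ... Unused.
#' @rdname classify
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[intersect(object$feature_names,
                                           names(newdata))])
  }
  classify(object, newdata)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s, %d classes, d = %d, N = %g\n",
              toupper(x$mode), length(x$class_ids), x$d, x$N))
  cat(sprintf("  update policy: %s; priors: %s; ridge: %g\n",
              x$update_policy, x$prior_mode, x$ridge_lambda))
  invisible(x)
}

#' Tidy per-class summary of a discriminant model
#'
#' @param x A `discriminant_model`.
#' @param ... Unused.
#' @return A tibble with one row per class: pattern count, prior, mean
#'   vector length and total covariance variance (trace).
#' @method tidy discriminant_model
#' @export
tidy.discriminant_model <- function(x, ...) {
  tibble(
    class = x$class_ids,
    n = x$n_c,
    prior = x$priors,
    mean_length = vapply(x$means, function(m) sqrt(sum(m^2)), 0),
    cov_trace = vapply(x$covs, function(s) sum(diag(s)), 0))
}

#' One-row summary of a discriminant model
#'
#' @param x A `discriminant_model`.
#' @param ... Unused.
#' @return A one-row tibble: mode, class count, feature dimension, total
#'   pattern count and update policy.
#' @method glance discriminant_model
#' @export
glance.discriminant_model <- function(x, ...) {
  tibble(mode = x$mode, n_classes = length(x$class_ids), d = x$d,
         total_n = x$N, update_policy = x$update_policy)
}
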