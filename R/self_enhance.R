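#' Incremental update of a class mean from one new pattern
#'
#' `mu_new = (n * mu + z) / (n + 1)`: the exact arithmetic mean of the
#' original `n` patterns plus `z`.
#'
#' @param mean Current class mean (d-vector).
#' @param n Current class pattern count.
#' @param z New feature vector.
#' @return Updated mean vector.
#' @export
update_mean <- function(mean, n, z) (n * mean + z) / (n + 1)

#' Rank-one scatter correction for one new pattern
#'
#' `C_k = n/(n + 1) * (z - mu)(z - mu)'`, the exact increment of the class
#' scatter matrix when `z` joins a class with count `n` and mean `mu`:
#' the scatter about the updated mean of the augmented point set equals
#' `S + C_k`. Symmetric, positive semidefinite, rank at most one.
#'
#' @inheritParams update_mean
#' @return A `d x d` matrix.
#' @export
correction_matrix <- function(mean, n, z) {
  v <- z - mean
  (n / (n + 1)) * tcrossprod(v)
}

#' Incremental update of a class (ML) covariance
#'
#' `Sigma_new = n/(n + 1) * Sigma + C_k/(n + 1)`; equals the ML covariance
#' (divisor `n + 1`) of the augmented class when `C_k` comes from
#' [correction_matrix()] about the pre-update mean.
#'
#' @param cov Current class ML covariance.
#' @param n Current class pattern count.
#' @param ck Correction matrix from [correction_matrix()].
#' @return Updated covariance matrix.
#' @export
update_class_cov <- function(cov, n, ck) (n * cov + ck) / (n + 1)

#' Incremental update of the pooled within-class covariance
#'
#' `Sigma_W_new = N/(N + 1) * Sigma_W + C_k/(N + 1)` with `N` the total
#' pattern count across classes; equals the count-weighted pooled ML
#' covariance of the augmented data.
#'
#' @param pooled Current pooled covariance.
#' @param total_n Current total pattern count `N`.
#' @param ck Correction matrix from [correction_matrix()].
#' @return Updated pooled covariance matrix.
#' @export
update_pooled_cov <- function(pooled, total_n, ck) {
  (total_n * pooled + ck) / (total_n + 1)
}

#' One self-enhancing classification step
#'
#' Classifies `z` with the current model, then updates the parameters of
#' the predicted class `k` according to `policy`:
#' \describe{
#'   \item{`"none"`}{no update; the decision stream is identical to the
#'     static classifier.}
#'   \item{`"m"`}{mean of class `k` only.}
#'   \item{`"c"`}{covariance only: the class covariance (QDA) or the pooled
#'     covariance (LDA), with the rank-one correction computed about the
#'     current (un-updated) mean.}
#'   \item{`"mc"`}{both: the correction is computed about the pre-update
#'     mean, the covariance is updated, then the mean.}
#' }
#' Under any updating policy the class count `n_k` and total count `N`
#' increment, and counts-based priors are refreshed. Other classes are
#' untouched, the feature `z` is not retained, and ground truth is never
#' seen: the update uses the model's own prediction.
#'
#' @param model A fitted `discriminant_model`.
#' @param z Feature vector of length `d`.
#' @param policy `"none"`, `"m"`, `"c"` or `"mc"`; defaults to the policy
#'   recorded in the model.
#' @return A list: `predicted` (class label), `model` (updated model),
#'   `trace_ck` (trace of the applied correction matrix; `NA` when no
#'   covariance was touched).
#' @export
enhance_step <- function(model, z, policy = NULL) {
  policy <- policy %||% model$update_policy
  policy <- match.arg(policy, c("none", "m", "c", "mc"))
  z <- as.numeric(z)
  predicted <- classify(model, z)
  if (policy == "none") {
    return(list(predicted = predicted, model = model, trace_ck = NA_real_))
  }
  k <- match(predicted, model$class_ids)
  n_k <- model$n_c[k]
  trace_ck <- NA_real_
  if (policy %in% c("c", "mc")) {
    ck <- correction_matrix(model$means[[k]], n_k, z)
    trace_ck <- sum(diag(ck))
    if (model$mode == "qda") {
      model$covs[[k]] <- update_class_cov(model$covs[[k]], n_k, ck)
      model <- rebuild_cache(model, classes = k)
    } else {
      model$pooled_cov <- update_pooled_cov(model$pooled_cov, model$N, ck)
      model <- rebuild_cache(model)
    }
  }
  if (policy %in% c("m", "mc")) {
    model$means[[k]] <- update_mean(model$means[[k]], n_k, z)
  }
  model$n_c[k] <- n_k + 1
  model$N <- model$N + 1
  if (model$prior_mode == "counts") model$priors <- model$n_c / model$N
  list(predicted = predicted, model = model, trace_ck = trace_ck)
}

#' Turn a feature table or matrix into a one-window-at-a-time iterator
#'
#' [run_stream()] deliberately accepts only an iterator, so that streaming
#' retains nothing beyond the model parameters and the current window. This
#' helper wraps an in-memory feature source for convenience.
#'
#' @param x A numeric matrix (rows = windows) or a feature tibble.
#' @return A function that returns the next feature row, or `NULL` when
#'   exhausted.
#' @export
feature_iterator <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[feature_cols(x)])
  x <- as.matrix(x)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > nrow(x)) return(NULL)
    x[i, ]
  }
}

#' Stream windows through the self-enhancing classifier
#'
#' Applies [enhance_step()] to each window in temporal order. The engine
#' consumes a one-window-at-a-time iterator (see [feature_iterator()]);
#' passing a materialised matrix is an error, which keeps the storage
#' contract explicit: only the model parameters and the current window are
#' held in memory.
#'
#' @param model A fitted `discriminant_model`.
#' @param stream A function returning the next feature vector or `NULL`.
#' @param policy Update policy (see [enhance_step()]); defaults to the
#'   model's recorded policy.
#' @param snapshot_at Optional integer vector of window indices; after
#'   processing each listed index a copy of the model is stored (used for
#'   per-cycle drift diagnostics).
#' @return A list of class `emg_stream`: `decisions` (character vector),
#'   `model` (final model, with `update_policy` set to `policy`), `events`
#'   (tibble: `window_index`, `predicted`, `trace_ck`), `snapshots` (named
#'   list of models).
#' @export
run_stream <- function(model, stream, policy = NULL, snapshot_at = NULL) {
  stopifnot(inherits(model, "discriminant_model"))
  policy <- policy %||% model$update_policy
  policy <- match.arg(policy, c("none", "m", "c", "mc"))
  if (!is.function(stream)) {
    abort(paste0("`stream` must be a one-window-at-a-time iterator ",
                 "function; wrap in-memory features with feature_iterator()"))
  }
  model$update_policy <- policy
  cap <- 1024L
  decisions <- character(cap)
  traces <- numeric(cap)
  snapshots <- list()
  snap_set <- as.integer(snapshot_at)
  i <- 0L
  repeat {
    z <- stream()
    if (is.null(z)) break
    i <- i + 1L
    if (i > cap) {
      cap <- cap * 2L
      length(decisions) <- cap
      length(traces) <- cap
    }
    step <- tryCatch(
      enhance_step(model, z, policy),
      error = function(e) {
        abort(sprintf("self-enhancing update failed at window %d: %s",
                      i, conditionMessage(e)))
      })
    model <- step$model
    decisions[i] <- step$predicted
    traces[i] <- step$trace_ck
    if (i %in% snap_set) snapshots[[as.character(i)]] <- model
  }
  decisions <- decisions[seq_len(i)]
  traces <- traces[seq_len(i)]
  structure(
    list(decisions = decisions, model = model,
         events = tibble(window_index = seq_len(i), predicted = decisions,
                         trace_ck = traces),
         snapshots = snapshots),
    class = "emg_stream")
}

#' @export
print.emg_stream <- function(x, ...) {
  cat(sprintf("<emg_stream> %d decisions, policy %s, %d snapshots\n",
              length(x$decisions), x$model$update_policy,
              length(x$snapshots)))
  invisible(x)
}
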