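ra_pct <- function(truth, predicted) 100 * mean(truth == predicted)

method_label <- function(mode, policy) {
  base <- toupper(mode)
  if (policy == "none") return(base)
  if (policy == "mc") return(paste0("SE", base))
  paste0("SE", base, "(", toupper(policy), ")")
}

#' Evaluate one classifier configuration on a labelled feature table
#'
#' Splits the feature windows into training cycles (`cycle <=
#' train_cycles`) and testing cycles, fits the discriminant on the training
#' windows, streams the testing windows in temporal order through the
#' self-enhancing engine under `policy` (policy `"none"` reproduces the
#' static classifier), and scores the decision stream against the true
#' labels. Ground truth is only ever seen by the scorer: the stream engine
#' receives unlabelled feature vectors.
#'
#' @param features A feature tibble from [extract_features()] (or
#'   [read_features()]).
#' @param mode `"lda"` or `"qda"`.
#' @param policy Update policy (see [enhance_step()]).
#' @param train_cycles Number of initial cycles used for training.
#' @param config An [emg_config()].
#' @param snapshots Keep a model snapshot at the end of every testing cycle
#'   (needed for [drift_diagnostics()]; default `TRUE` for updating
#'   policies).
#' @return An `emg_eval` object: decision table, overall/per-cycle/
#'   cumulative/per-class/per-trial recognition accuracy (RA, in percent),
#'   confusion matrix, and the trained plus final models.
#' @export
evaluate_features <- function(features, mode, policy = "none",
                              train_cycles, config = emg_config(),
                              snapshots = policy != "none") {
  mode <- match.arg(mode, c("lda", "qda"))
  policy <- match.arg(policy, c("none", "m", "c", "mc"))
  train <- features[features$cycle <= train_cycles, , drop = FALSE]
  test <- features[features$cycle > train_cycles, , drop = FALSE]
  if (nrow(train) == 0) abort("no training windows")
  if (nrow(test) == 0) abort("no testing windows")
  test <- test[order(test$window_index), , drop = FALSE]
  test_cycles <- sort(unique(test$cycle))
  expected <- seq(train_cycles + 1, max(test$cycle))
  missing <- setdiff(expected, test_cycles)
  if (length(missing) > 0) {
    abort(sprintf("testing cycle %d contains no windows", missing[1]))
  }
  model0 <- fit_discriminant(train, mode = mode, config = config)
  X <- as.matrix(test[feature_cols(test)])
  if (policy == "none") {
    decisions <- classify(model0, X)
    model_final <- model0
    snaps <- list()
  } else {
    snap_at <- if (snapshots) cumsum(table(factor(test$cycle, test_cycles)))
               else NULL
    st <- run_stream(model0, feature_iterator(X), policy = policy,
                     snapshot_at = snap_at)
    decisions <- st$decisions
    model_final <- st$model
    snaps <- st$snapshots
    if (snapshots) names(snaps) <- test_cycles[match(
      as.integer(names(snaps)), as.integer(snap_at))]
  }
  dec <- tibble(window_index = test$window_index, cycle = test$cycle,
                truth = test$label, predicted = decisions)
  res <- score_stream(dec, class_ids = model0$class_ids)
  structure(
    c(res,
      list(mode = mode, policy = policy, method = method_label(mode, policy),
           feature_kind = attr(features, "feature_kind"),
           train_cycles = train_cycles, model_train = model0,
           model_final = model_final, snapshots = snaps)),
    class = "emg_eval")
}

# All RA metrics from a decision table; also usable on its own as a
# re-scoring of any decision stream.
score_stream <- function(dec, class_ids = sort(unique(dec$truth)),
                         cycles_per_trial = 5L) {
  cyc <- sort(unique(dec$cycle))
  per_cycle <- vapply(cyc, function(cy) {
    s <- dec$cycle == cy
    ra_pct(dec$truth[s], dec$predicted[s])
  }, 0)
  n_cyc <- vapply(cyc, function(cy) sum(dec$cycle == cy), 0)
  hits <- vapply(cyc, function(cy) {
    s <- dec$cycle == cy
    sum(dec$truth[s] == dec$predicted[s])
  }, 0)
  cumulative <- 100 * cumsum(hits) / cumsum(n_cyc)
  trial_id <- (seq_along(cyc) - 1) %/% cycles_per_trial + 1
  per_trial <- vapply(unique(trial_id), function(tr) {
    s <- dec$cycle %in% cyc[trial_id == tr]
    ra_pct(dec$truth[s], dec$predicted[s])
  }, 0)
  per_class <- vapply(class_ids, function(cl) {
    s <- dec$truth == cl
    ra_pct(dec$truth[s], dec$predicted[s])
  }, 0)
  confusion <- table(factor(dec$truth, class_ids),
                     factor(dec$predicted, class_ids))
  list(decisions = dec,
       overall_ra = ra_pct(dec$truth, dec$predicted),
       per_cycle_ra = tibble(cycle = cyc, ra = per_cycle),
       cumulative_ra = tibble(cycle = cyc, ra = cumulative),
       per_trial_ra = tibble(trial = unique(trial_id), ra = per_trial),
       per_class_ra = tibble(class = class_ids, ra = unname(per_class)),
       confusion = confusion)
}

#' Evaluate a full acquisition protocol on a recording
#'
#' Convenience wrapper: extract features from an annotated recording, then
#' run [evaluate_features()] with the protocol's training/testing split.
#'
#' @param record An annotated [emg_record()].
#' @param mode `"lda"` or `"qda"`.
#' @param policy Update policy.
#' @param feature_kind `"ar"` or `"fc"`.
#' @param train_cycles Number of training cycles.
#' @param config An [emg_config()].
#' @param ... Passed to [evaluate_features()].
#' @return An `emg_eval` object.
#' @export
evaluate_protocol <- function(record, mode, policy = "none",
                              feature_kind = c("fc", "ar"), train_cycles,
                              config = emg_config(), ...) {
  feature_kind <- match.arg(feature_kind)
  features <- extract_features(record, kind = feature_kind, config = config)
  evaluate_features(features, mode = mode, policy = policy,
                    train_cycles = train_cycles, config = config, ...)
}

#' @export
print.emg_eval <- function(x, ...) {
  cat(sprintf("<emg_eval> %s + %s: overall RA %.2f%% over %d windows (%d cycles)\n",
              x$method, toupper(x$feature_kind), x$overall_ra,
              nrow(x$decisions), nrow(x$per_cycle_ra)))
  invisible(x)
}

#' Per-testing-cycle accuracy of an evaluation
#'
#' @param x An `emg_eval`.
#' @param ... Unused.
#' @return Tibble: `cycle`, `ra` (per-cycle RA, percent), `cumulative_ra`
#'   (mean RA over testing cycles up to and including `cycle`).
#' @method tidy emg_eval
#' @export
tidy.emg_eval <- function(x, ...) {
  dplyr::left_join(x$per_cycle_ra,
                   dplyr::rename(x$cumulative_ra, cumulative_ra = "ra"),
                   by = "cycle")
}

#' One-row summary of an evaluation
#'
#' @param x An `emg_eval`.
#' @param ... Unused.
#' @return One-row tibble: method, feature kind, overall RA, window count.
#' @method glance emg_eval
#' @export
glance.emg_eval <- function(x, ...) {
  tibble(method = x$method, mode = x$mode, policy = x$policy,
         feature_kind = x$feature_kind, overall_ra = x$overall_ra,
         n_windows = nrow(x$decisions),
         n_test_cycles = nrow(x$per_cycle_ra))
}

#' Cosine of the angle between two vectors
#'
#' `cos = (v0 . vi) / (|v0| |vi|)`, used to track the rotation of class
#' mean vectors and covariance principal axes away from their training
#' values.
#'
#' @param v0,vi Nonzero numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_angle <- function(v0, vi) {
  n0 <- sqrt(sum(v0^2)); ni <- sqrt(sum(vi^2))
  if (n0 == 0 || ni == 0) abort("cosine_angle is undefined for a zero vector")
  max(-1, min(1, sum(v0 * vi) / (n0 * ni)))
}

#' Classifier-parameter drift diagnostics across testing cycles
#'
#' For each per-cycle model snapshot and each class: the length of the
#' class mean vector, the lengths of the first two principal axes of the
#' class covariance (square roots of the two largest eigenvalues), the
#' cosine of the angle between the current and training mean vectors, and
#' the absolute cosines between current and training principal axes
#' (eigenvector signs are arbitrary, so axis cosines are reported as
#' absolute values). For an LDA model an extra `(pooled)` row tracks the
#' pooled within-class matrix. Eigenvalues are taken in descending order;
#' exact ties keep the eigensolver's basis order.
#'
#' @param snapshots Named list of per-cycle models (names = testing cycle),
#'   e.g. the `snapshots` element of an `emg_eval` or [run_stream()]
#'   result.
#' @param training_model The model fitted on the training cycles.
#' @return A tibble: `cycle`, `class`, `mean_length`, `axis1_length`,
#'   `axis2_length`, `mean_cos`, `axis1_cos`, `axis2_cos`.
#' @export
drift_diagnostics <- function(snapshots, training_model) {
  stopifnot(inherits(training_model, "discriminant_model"))
  ref_eig <- lapply(training_model$covs, function(s) eigen(s, symmetric = TRUE))
  ref_pool <- if (!is.null(training_model$pooled_cov)) {
    eigen(training_model$pooled_cov, symmetric = TRUE)
  }
  one <- function(cycle, model) {
    rows <- lapply(seq_along(model$class_ids), function(i) {
      ei <- eigen(model$covs[[i]], symmetric = TRUE)
      tibble(
        cycle = cycle, class = model$class_ids[i],
        mean_length = sqrt(sum(model$means[[i]]^2)),
        axis1_length = sqrt(max(ei$values[1], 0)),
        axis2_length = sqrt(max(ei$values[2], 0)),
        mean_cos = cosine_angle(training_model$means[[i]], model$means[[i]]),
        axis1_cos = abs(cosine_angle(ref_eig[[i]]$vectors[, 1],
                                     ei$vectors[, 1])),
        axis2_cos = abs(cosine_angle(ref_eig[[i]]$vectors[, 2],
                                     ei$vectors[, 2])))
    })
    if (model$mode == "lda") {
      ei <- eigen(model$pooled_cov, symmetric = TRUE)
      rows <- c(rows, list(tibble(
        cycle = cycle, class = "(pooled)",
        mean_length = NA_real_,
        axis1_length = sqrt(max(ei$values[1], 0)),
        axis2_length = sqrt(max(ei$values[2], 0)),
        mean_cos = NA_real_,
        axis1_cos = abs(cosine_angle(ref_pool$vectors[, 1], ei$vectors[, 1])),
        axis2_cos = abs(cosine_angle(ref_pool$vectors[, 2], ei$vectors[, 2])))))
    }
    dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(Map(one, as.integer(names(snapshots)), snapshots))
}

#' Paired t-test between two per-subject accuracy vectors
#'
#' Classic paired t on the differences (`df = n - 1`, two-sided), the
#' statistic used to compare an enhanced classifier with its static
#' counterpart across subjects. Raw p-values are reported without
#' multiplicity correction.
#'
#' @param a,b Equal-length numeric vectors (length >= 2), one entry per
#'   subject.
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p`.
#' @export
paired_ra_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("need two equal-length vectors with at least 2 entries")
  }
  d <- a - b
  if (sd(d) == 0) {
    abort("all paired differences are equal; the t statistic is undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble(mean_diff = mean(d), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
}

#' Compare classifier/policy/feature combinations over simulated subjects
#'
#' Simulates `n_subjects` independent recordings (one seed each) under a
#' common protocol and drift setting, evaluates every requested
#' combination of classifier mode, update policy and feature kind on each,
#' and summarises per-subject and mean/sd recognition accuracy plus paired
#' t-tests of every self-enhancing variant against its static counterpart.
#'
#' @param n_subjects Number of simulated subjects.
#' @param protocol A [protocol_spec()]; its seed anchors the per-subject
#'   seeds (`seed`, `seed + 1`, ...).
#' @param drift A [drift_spec()].
#' @param modes,policies,kinds Character vectors defining the method grid.
#' @param config An [emg_config()].
#' @return An `emg_comparison`: `results` (one row per subject x method),
#'   `summary` (mean/sd per method), `t_tests` (enhanced vs static).
#' @export
compare_methods <- function(n_subjects = 5, protocol = protocol_spec(1),
                            drift = calibrated_drift(),
                            modes = c("lda", "qda"),
                            policies = c("none", "mc"),
                            kinds = c("ar", "fc"),
                            config = emg_config()) {
  seeds <- protocol$seed + seq_len(n_subjects) - 1L
  rows <- list()
  for (s in seq_len(n_subjects)) {
    rec <- simulate_recording(protocol, drift = drift, seed = seeds[s])
    for (kind in kinds) {
      feats <- extract_features(rec, kind = kind, config = config)
      for (mode in modes) {
        for (policy in policies) {
          ev <- evaluate_features(feats, mode = mode, policy = policy,
                                  train_cycles = protocol$train_cycles,
                                  config = config, snapshots = FALSE)
          rows[[length(rows) + 1L]] <- tibble(
            subject = s, seed = seeds[s], feature_kind = kind,
            mode = mode, policy = policy,
            method = method_label(mode, policy),
            overall_ra = ev$overall_ra)
        }
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$feature_kind, .data$mode, .data$policy,
                    .data$method) |>
    dplyr::summarise(mean_ra = mean(.data$overall_ra),
                     sd_ra = sd(.data$overall_ra), .groups = "drop")
  tt <- list()
  if ("none" %in% policies && n_subjects >= 2) {
    for (kind in kinds) for (mode in modes) {
      stat <- results[results$feature_kind == kind & results$mode == mode &
                        results$policy == "none", ]
      for (policy in setdiff(policies, "none")) {
        enh <- results[results$feature_kind == kind & results$mode == mode &
                         results$policy == policy, ]
        res <- tryCatch(
          paired_ra_test(enh$overall_ra[order(enh$subject)],
                         stat$overall_ra[order(stat$subject)]),
          error = function(e) tibble(mean_diff = NA_real_, t = NA_real_,
                                     df = NA_real_, p = NA_real_))
        tt[[length(tt) + 1L]] <- dplyr::bind_cols(
          tibble(feature_kind = kind,
                 comparison = paste(method_label(mode, policy), "vs",
                                    method_label(mode, "none"))),
          res)
      }
    }
  }
  structure(list(results = results, summary = summary,
                 t_tests = dplyr::bind_rows(tt)),
            class = "emg_comparison")
}

#' @export
print.emg_comparison <- function(x, ...) {
  cat("<emg_comparison>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  if (nrow(x$t_tests) > 0) {
    cat("paired t-tests (enhanced vs static):\n")
    print(as.data.frame(x$t_tests), row.names = FALSE)
  }
  invisible(x)
}

#' @param x An `emg_comparison`.
#' @param ... Unused.
#' @rdname compare_methods
#' @method tidy emg_comparison
#' @export
tidy.emg_comparison <- function(x, ...) x$results

#' @rdname compare_methods
#' @method glance emg_comparison
#' @export
glance.emg_comparison <- function(x, ...) x$summary
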