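# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# A minimal annotated recording: `segs` is a list of c(onset, offset, label,
# cycle); the signal is standard normal noise.
make_record <- function(n_samples, n_channels = 1, fs = 1000, segs = NULL,
                        seed = 1) {
  set.seed(seed)
  data <- matrix(rnorm(n_samples * n_channels), n_samples, n_channels)
  segments <- if (!is.null(segs)) {
    tibble::tibble(
      onset_s = vapply(segs, function(s) as.numeric(s[[1]]), 0),
      offset_s = vapply(segs, function(s) as.numeric(s[[2]]), 0),
      label = vapply(segs, function(s) as.character(s[[3]]), ""),
      cycle = vapply(segs, function(s) as.integer(s[[4]]), 0L))
  }
  emg_record(data, fs = fs, segments = segments)
}

# Labelled Gaussian feature tibble: one cluster per class, `n_per` rows per
# (class, cycle). `shift` moves class means apart.
make_gaussian_features <- function(n_class = 2, d = 2, n_per = 10,
                                   cycles = 1:2, shift = 5, sd = 1,
                                   seed = 1) {
  set.seed(seed)
  rows <- list()
  idx <- 0L
  for (cy in cycles) {
    for (cl in seq_len(n_class)) {
      X <- matrix(rnorm(n_per * d, mean = shift * cl, sd = sd), n_per, d)
      colnames(X) <- paste0("f", seq_len(d))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(cycle = cy,
                       window_index = idx + seq_len(n_per),
                       start_s = as.numeric(idx + seq_len(n_per)),
                       label = sprintf("c%d", cl)),
        tibble::as_tibble(X))
      idx <- idx + n_per
    }
  }
  dplyr::bind_rows(rows)
}

# Independent dense-algebra scorer: explicit solve(), no Cholesky cache.
score_oracle <- function(model, x) {
  vapply(seq_along(model$class_ids), function(i) {
    sigma <- if (model$mode == "lda") model$pooled_cov else model$covs[[i]]
    if (model$ridge_lambda > 0) {
      sigma <- sigma + diag(model$ridge_lambda * sum(diag(sigma)) / nrow(sigma),
                            nrow(sigma))
    }
    v <- x - model$means[[i]]
    g <- log(model$priors[i]) - 0.5 * drop(t(v) %*% solve(sigma, v))
    if (model$mode == "qda" && model$include_logdet) {
      g <- g - 0.5 * determinant(sigma, logarithm = TRUE)$modulus
    }
    as.numeric(g)
  }, 0)
}

# Batch ML statistics of a labelled matrix, grouped by `labels`.
batch_ml_fit <- function(X, labels, class_ids = sort(unique(labels))) {
  stats <- lapply(class_ids, function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mu)
    list(n = nrow(Xi), mean = mu, cov = crossprod(Xc) / nrow(Xi))
  })
  names(stats) <- class_ids
  N <- sum(vapply(stats, `[[`, 0, "n"))
  pooled <- Reduce(`+`, lapply(stats, function(s) s$n / N * s$cov))
  list(stats = stats, pooled = pooled, N = N)
}

rel_err <- function(a, b) {
  denom <- max(abs(b), 1e-12)
  max(abs(a - b)) / denom
}
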