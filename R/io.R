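#' Rest-period sentinel label
#'
#' Annotation segments covering the relaxation intervals between contractions
#' carry this label. Rest segments are never windowed or classified: the
#' motion-class vocabulary contains active contractions only.
#' @export
REST_LABEL <- "rest"

# Format doubles at 17 significant digits (exact IEEE round-trip) so text
# files reproduce every bit on re-read; other column types pass through.
format_full_precision <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

#' Run configuration for the EMG pattern-recognition pipeline
#'
#' Collects every tunable of the windowing, feature-extraction and
#' classification stages in one validated list.
#'
#' @param window_ms Analysis-window length in milliseconds (default 200).
#' @param increment_ms Window increment in milliseconds (default 25); the
#'   classifier emits one decision per increment.
#' @param ar_order Order of the Burg autoregressive model (default 6).
#' @param n_fc Number of Fourier-derived cepstral coefficients kept per
#'   channel (default 7).
#' @param fc_epsilon Additive guard inside the log of the magnitude spectrum
#'   so empty bins stay finite (default 1e-12).
#' @param classifier_mode `"lda"` (pooled covariance) or `"qda"`
#'   (class-specific covariances).
#' @param update_policy Self-enhancement policy: `"none"`, `"m"` (means
#'   only), `"c"` (covariances only) or `"mc"` (both).
#' @param include_logdet Include the `-log|Sigma_i|/2` term in QDA scores
#'   (textbook Bayes-optimal form; default `TRUE`).
#' @param ridge_lambda Ridge regularisation of covariances, as a fraction of
#'   the mean eigenvalue added to the diagonal (default 0 = none).
#' @param prior_mode `"counts"` (class priors proportional to pattern
#'   counts) or `"uniform"`.
#' @param seed Optional integer seed recorded alongside the configuration.
#'
#' @return An object of class `emg_config` (a named list).
#' @export
emg_config <- function(window_ms = 200, increment_ms = 25, ar_order = 6,
                       n_fc = 7, fc_epsilon = 1e-12,
                       classifier_mode = c("lda", "qda"),
                       update_policy = c("none", "m", "c", "mc"),
                       include_logdet = TRUE, ridge_lambda = 0,
                       prior_mode = c("counts", "uniform"), seed = NULL) {
  classifier_mode <- match.arg(classifier_mode)
  update_policy <- match.arg(update_policy)
  prior_mode <- match.arg(prior_mode)
  if (!(increment_ms > 0 && window_ms >= increment_ms)) {
    abort("`window_ms` must be >= `increment_ms` and `increment_ms` > 0.")
  }
  if (ar_order < 1) abort("`ar_order` must be >= 1.")
  if (n_fc < 1) abort("`n_fc` must be >= 1.")
  if (ridge_lambda < 0) abort("`ridge_lambda` must be >= 0.")
  structure(
    list(window_ms = window_ms, increment_ms = increment_ms,
         ar_order = ar_order, n_fc = n_fc, fc_epsilon = fc_epsilon,
         classifier_mode = classifier_mode, update_policy = update_policy,
         include_logdet = include_logdet, ridge_lambda = ridge_lambda,
         prior_mode = prior_mode, seed = seed),
    class = "emg_config"
  )
}

#' Construct a multi-channel EMG recording
#'
#' Bundles a sample matrix, its sampling rate and an annotation track into a
#' validated `emg_record`. Annotations are half-open intervals
#' `[onset_s, offset_s)` in seconds; rest periods carry [REST_LABEL] and are
#' excluded from windowing.
#'
#' @param data Numeric matrix, `n_samples x n_channels`, finite values.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional channel names; defaults to `ch1, ch2, ...`.
#' @param segments Data frame with columns `onset_s`, `offset_s`, `label`,
#'   `cycle` (may be `NULL` for an unannotated recording).
#'
#' @return An `emg_record`: list with elements `data`, `fs`,
#'   `channel_names`, `segments` (a tibble).
#' @export
emg_record <- function(data, fs, channel_names = NULL, segments = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    abort(sprintf("signal contains a non-finite value at row %d, channel %d",
                  bad[1], bad[2]))
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(data)))
  if (length(channel_names) != ncol(data)) {
    abort("`channel_names` length must equal the number of channels.")
  }
  colnames(data) <- channel_names
  segments <- validate_segments(segments, n_samples = nrow(data), fs = fs)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 segments = segments),
            class = "emg_record")
}

validate_segments <- function(segments, n_samples, fs) {
  if (is.null(segments)) {
    return(tibble(onset_s = numeric(), offset_s = numeric(),
                  label = character(), cycle = integer()))
  }
  segments <- as_tibble(segments)
  need <- c("onset_s", "offset_s", "label", "cycle")
  if (!all(need %in% names(segments))) {
    abort(paste0("annotation track must have columns: ",
                 paste(need, collapse = ", ")))
  }
  segments$label <- as.character(segments$label)
  segments$cycle <- as.integer(segments$cycle)
  if (any(!is.finite(segments$onset_s)) || any(!is.finite(segments$offset_s))) {
    abort("annotation onsets/offsets must be finite.")
  }
  if (any(segments$offset_s <= segments$onset_s)) {
    abort("every annotation segment must satisfy offset_s > onset_s.")
  }
  dur <- n_samples / fs
  if (any(segments$onset_s < 0) || any(segments$offset_s > dur + 1e-9)) {
    abort(sprintf(
      "annotation segment outside the recorded time range [0, %g] s", dur))
  }
  if (any(segments$cycle < 0)) abort("cycle indices must be non-negative.")
  segments <- segments[order(segments$onset_s), , drop = FALSE]
  act <- segments[segments$label != REST_LABEL, , drop = FALSE]
  if (nrow(act) > 1) {
    if (any(act$onset_s[-1] < act$offset_s[-nrow(act)] - 1e-9)) {
      abort("non-rest annotation segments must not overlap.")
    }
  }
  segments
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  n_act <- sum(x$segments$label != REST_LABEL)
  cat(sprintf("  %d annotation segments (%d active, %d rest)\n",
              nrow(x$segments), n_act, nrow(x$segments) - n_act))
  invisible(x)
}

#' Write / read an EMG recording as delimited text
#'
#' The signal file is a TSV with a first header line `#fs=<Hz>`, then one
#' column per channel and one row per sample. Annotations go to a sidecar
#' TSV with columns `onset_s`, `offset_s`, `label`, `cycle`. Numbers are
#' written at 17 significant digits (exact IEEE round-trip), so
#' `read_signal()` after `write_signal()` reproduces the samples exactly.
#'
#' @param record An [emg_record()].
#' @param path Signal TSV path.
#' @param annotation_path Annotation TSV path (optional on write; omit to
#'   skip the annotation file).
#' @return `write_signal()` returns `record` invisibly; `read_signal()`
#'   returns an `emg_record`.
#' @export
write_signal <- function(record, path, annotation_path = NULL) {
  stopifnot(inherits(record, "emg_record"))
  writeLines(sprintf("#fs=%.17g", record$fs), path)
  readr::write_tsv(format_full_precision(as_tibble(record$data)), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  if (!is.null(annotation_path)) {
    readr::write_tsv(format_full_precision(record$segments), annotation_path,
                     progress = FALSE)
  }
  invisible(record)
}

#' @param vocabulary Optional character vector of allowed motion-class
#'   labels; annotation labels outside it (other than [REST_LABEL]) are
#'   rejected.
#' @rdname write_signal
#' @export
read_signal <- function(path, annotation_path = NULL, vocabulary = NULL) {
  header <- readLines(path, n = 2L)
  if (length(header) < 1 || !grepl("^#fs=", header[1])) {
    abort(sprintf("'%s': expected first line '#fs=<Hz>', found '%s'",
                  path, if (length(header) >= 1) header[1] else ""))
  }
  fs <- as.numeric(sub("^#fs=", "", header[1]))
  if (!is.finite(fs) || fs <= 0) abort("invalid sampling rate in signal header")
  if (length(header) < 2) abort("signal file has no channel header row")
  ch_names <- strsplit(header[2], "\t", fixed = TRUE)[[1]]
  nch <- length(ch_names)
  # base scan(): correctly rounded double parsing, so written values
  # round-trip bit-exactly
  vals <- tryCatch(
    scan(path, what = double(), skip = 2L, sep = "\t", quiet = TRUE),
    error = function(e) NULL)
  if (is.null(vals) || length(vals) %% nch != 0) {
    locate_bad_cell(path, skip = 2L, n_fields = nch)
  }
  dat <- matrix(vals, ncol = nch, byrow = TRUE)
  segments <- NULL
  if (!is.null(annotation_path)) {
    segments <- as_tibble(utils::read.delim(
      annotation_path, sep = "\t",
      colClasses = c("numeric", "numeric", "character", "integer")))
    if (!is.null(vocabulary)) {
      bad <- setdiff(unique(segments$label), c(vocabulary, REST_LABEL))
      if (length(bad) > 0) {
        abort(paste0("annotation labels outside the class vocabulary: ",
                     paste(bad, collapse = ", ")))
      }
    }
  }
  emg_record(dat, fs = fs, channel_names = ch_names, segments = segments)
}

# Pinpoint the first unparseable or ragged cell of a delimited numeric file
# and raise a located error.
locate_bad_cell <- function(path, skip, n_fields, text = NULL) {
  lines <- text %||% readLines(path)
  if (skip > 0) lines <- lines[-seq_len(skip)]
  for (r in seq_along(lines)) {
    cells <- strsplit(lines[r], "\t", fixed = TRUE)[[1]]
    if (length(cells) != n_fields) {
      abort(sprintf("row %d has %d fields, expected %d",
                    r, length(cells), n_fields))
    }
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & toupper(cells) != "NA")
    if (length(bad) > 0) {
      abort(sprintf("malformed numeric cell at row %d, column %d ('%s')",
                    r, bad[1], cells[bad[1]]))
    }
  }
  abort("failed to parse numeric data")
}

#' Write / read a labelled window feature table
#'
#' One row per analysis window: `cycle`, `window_index`, `start_s`, `label`,
#' followed by the feature columns. Two comment lines record the feature
#' kind and channel count so the table round-trips with its metadata.
#'
#' @param features A feature tibble from [extract_features()].
#' @param path File path (TSV).
#' @return `write_features()` returns `features` invisibly;
#'   `read_features()` returns the feature tibble with its `feature_kind`
#'   and `n_channels` attributes restored.
#' @export
write_features <- function(features, path) {
  kind <- attr(features, "feature_kind") %||% "unknown"
  nch <- attr(features, "n_channels") %||% NA_integer_
  writeLines(c(sprintf("#kind=%s", kind), sprintf("#channels=%d", nch)), path)
  readr::write_tsv(format_full_precision(as_tibble(features)), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2 || !grepl("^#kind=", hdr[1]) || !grepl("^#channels=", hdr[2])) {
    abort(sprintf("'%s' is not a feature table (missing #kind/#channels header)",
                  path))
  }
  raw <- readLines(path)[-(1:2)]
  if (length(raw) == 0) abort("feature table has no header row")
  cols <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  if (length(raw) > 1) {
    ncols <- lengths(strsplit(raw[-1], "\t", fixed = TRUE))
    if (any(ncols != length(cols))) {
      bad <- which(ncols != length(cols))[1]
      abort(sprintf(
        "inconsistent column count at data row %d (%d fields, expected %d)",
        bad, ncols[bad], length(cols)))
    }
  }
  meta <- c("cycle", "window_index", "start_s", "label")
  if (!identical(cols[1:4], meta)) {
    abort(paste0("feature table must start with columns: ",
                 paste(meta, collapse = ", ")))
  }
  what <- c(list(integer(), integer(), double(), character()),
            rep(list(double()), length(cols) - 4))
  parsed <- if (length(raw) > 1) {
    tryCatch(
      scan(text = raw[-1], what = what, sep = "\t", quiet = TRUE),
      error = function(e) {
        # fall through to a located error
        for (r in seq_along(raw[-1])) {
          cells <- strsplit(raw[-1][r], "\t", fixed = TRUE)[[1]]
          num <- suppressWarnings(as.numeric(cells[-4]))
          bad <- which(is.na(num) & toupper(cells[-4]) != "NA")
          if (length(bad) > 0) {
            col <- ifelse(bad[1] >= 4, bad[1] + 1, bad[1])
            abort(sprintf("malformed cell at row %d, column %d", r, col))
          }
        }
        abort(conditionMessage(e))
      })
  } else {
    lapply(what, function(w) w)
  }
  names(parsed) <- cols
  tab <- as_tibble(parsed)
  fcols <- setdiff(cols, meta)
  if (nrow(tab) > 0 && any(!is.finite(as.matrix(tab[fcols])))) {
    abort("feature table contains non-finite values")
  }
  new_feature_set(tab, kind = sub("^#kind=", "", hdr[1]),
                  n_channels = as.integer(sub("^#channels=", "", hdr[2])))
}

new_feature_set <- function(tab, kind, n_channels) {
  out <- as_tibble(tab)
  attr(out, "feature_kind") <- kind
  attr(out, "n_channels") <- n_channels
  class(out) <- c("emg_features", class(out))
  out
}

#' Column names of the feature block of a feature tibble
#' @param features A feature tibble.
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(features) {
  setdiff(names(features), c("cycle", "window_index", "start_s", "label"))
}

# ---- model serialization ----------------------------------------------------

#' Save / load a fitted discriminant model
#'
#' The container is self-describing JSON holding, per class, the pattern
#' count, mean vector, scatter matrix, ML covariance and prior, plus the
#' pooled within-class covariance, total pattern count, classifier mode and
#' update policy. Matrices are stored row-major with explicit dimensions and
#' full (round-trip) numeric precision, so `load_model(save_model(m))`
#' reproduces every parameter exactly.
#'
#' @param model A `discriminant_model` from [fit_discriminant()].
#' @param path File path (JSON).
#' @return `save_model()` returns `model` invisibly; `load_model()` the
#'   reconstructed model (score caches are rebuilt).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "discriminant_model"))
  num_out <- function(x) sprintf("%.17g", as.numeric(x))
  mat_out <- function(m) list(dim = dim(m), values = num_out(as.vector(t(m))))
  classes <- lapply(seq_along(model$class_ids), function(i) {
    list(class_id = model$class_ids[i],
         n = num_out(model$n_c[i]),
         mean = num_out(model$means[[i]]),
         scatter = mat_out(model$covs[[i]] * model$n_c[i]),
         cov = mat_out(model$covs[[i]]),
         prior = num_out(model$priors[i]))
  })
  obj <- list(
    format = "selfemg-discriminant-model",
    version = 1L,
    mode = model$mode,
    update_policy = model$update_policy,
    d = model$d,
    feature_names = model$feature_names,
    include_logdet = model$include_logdet,
    ridge_lambda = model$ridge_lambda,
    prior_mode = model$prior_mode,
    total_n = num_out(model$N),
    classes = classes,
    pooled_cov = if (is.null(model$pooled_cov)) NULL else mat_out(model$pooled_cov)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "selfemg-discriminant-model")) {
    abort(sprintf("'%s' is not a selfemg model container", path))
  }
  if (!identical(as.integer(obj$version), 1L)) {
    abort(sprintf("unsupported model container version: %s", obj$version))
  }
  need <- c("mode", "d", "total_n", "classes")
  miss <- need[!need %in% names(obj)]
  if (length(miss) > 0) {
    abort(paste0("model container missing fields: ", paste(miss, collapse = ", ")))
  }
  mat_in <- function(x) {
    matrix(as.numeric(unlist(x$values)), nrow = as.integer(unlist(x$dim)[1]),
           byrow = TRUE)
  }
  d <- as.integer(obj$d)
  fnames <- as.character(unlist(obj$feature_names))
  class_ids <- vapply(obj$classes, function(cl) as.character(cl$class_id), "")
  means <- lapply(obj$classes, function(cl) {
    setNames(as.numeric(unlist(cl$mean)), fnames)
  })
  covs <- lapply(obj$classes, function(cl) {
    m <- mat_in(cl$cov)
    dimnames(m) <- list(fnames, fnames)
    m
  })
  n_c <- vapply(obj$classes, function(cl) as.numeric(cl$n), 0)
  priors <- vapply(obj$classes, function(cl) as.numeric(cl$prior), 0)
  pooled <- if (is.null(obj$pooled_cov)) NULL else {
    m <- mat_in(obj$pooled_cov)
    dimnames(m) <- list(fnames, fnames)
    m
  }
  if (identical(obj$mode, "lda") && is.null(pooled)) {
    abort("model container in LDA mode is missing the pooled covariance")
  }
  model <- new_discriminant_model(
    mode = obj$mode, class_ids = class_ids, means = means, covs = covs,
    n_c = n_c, priors = priors, pooled_cov = pooled,
    N = as.numeric(obj$total_n), d = d,
    feature_names = as.character(unlist(obj$feature_names)),
    include_logdet = isTRUE(obj$include_logdet),
    ridge_lambda = as.numeric(obj$ridge_lambda %||% 0),
    prior_mode = obj$prior_mode %||% "counts",
    update_policy = obj$update_policy %||% "none")
  model
}
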