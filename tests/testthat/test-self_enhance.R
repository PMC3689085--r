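test_that("update_mean equals the batch mean of the augmented point set", {
  expect_equal(update_mean(c(1, 3), 2, c(4, 0)), c(2, 2))
  expect_equal(update_mean(c(2, -1), 7, c(2, -1)), c(2, -1))  # fixed point
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    d <- sample(1:5, 1)
    P <- matrix(rnorm(n * d), n, d)
    z <- rnorm(d)
    expect_equal(update_mean(colMeans(P), n, z), colMeans(rbind(P, z)),
                 tolerance = 1e-12)
  }
})

test_that("correction_matrix is the exact rank-one scatter increment", {
  expect_equal(correction_matrix(c(0, 0), 1, c(2, 0)),
               matrix(c(2, 0, 0, 0), 2))
  expect_equal(correction_matrix(c(1, 2), 5, c(1, 2)), matrix(0, 2, 2))
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    d <- sample(2:4, 1)
    P <- matrix(rnorm(n * d), n, d)
    z <- rnorm(d)
    mu <- colMeans(P)
    S <- crossprod(sweep(P, 2, mu))
    ck <- correction_matrix(mu, n, z)
    # PSD rank <= 1
    ev <- eigen(ck, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
    expect_lte(sum(ev > 1e-10 * max(ev, 1e-300)), 1)
    # S + C_k = scatter of the augmented set about its NEW mean
    aug <- rbind(P, z)
    S_new <- crossprod(sweep(aug, 2, colMeans(aug)))
    expect_equal(S + ck, S_new, tolerance = 1e-10)
  }
})

test_that("class covariance update matches the batch ML covariance", {
  # class points {(0,0),(2,0)}, z = (1,3)
  mu <- c(1, 0); n <- 2
  sigma <- matrix(c(1, 0, 0, 0), 2)
  ck <- correction_matrix(mu, n, c(1, 3))
  expect_equal(ck, matrix(c(0, 0, 0, 6), 2))
  upd <- update_class_cov(sigma, n, ck)
  expect_equal(upd, matrix(c(2 / 3, 0, 0, 2), 2))
  P <- rbind(c(0, 0), c(2, 0), c(1, 3))
  expect_equal(upd, crossprod(sweep(P, 2, colMeans(P))) / 3,
               tolerance = 1e-12)
  # C_k = 0 gives the pure n/(n+1) shrinkage
  expect_equal(update_class_cov(sigma, 4, matrix(0, 2, 2)), 0.8 * sigma)
})

test_that("pooled covariance update matches the batch pooled covariance", {
  # classes {(0,0),(2,0)} and {(5,5),(5,7)}: pooled ML = 0.5 I, N = 4
  pooled <- diag(0.5, 2)
  ck <- correction_matrix(c(1, 0), 2, c(1, 3))
  upd <- update_pooled_cov(pooled, 4, ck)
  expect_equal(upd, matrix(c(0.4, 0, 0, 1.6), 2))
  # brute force: ML-weighted pooled covariance of the augmented grouping
  c1 <- rbind(c(0, 0), c(2, 0), c(1, 3))
  c2 <- rbind(c(5, 5), c(5, 7))
  s1 <- crossprod(sweep(c1, 2, colMeans(c1))) / 3
  s2 <- crossprod(sweep(c2, 2, colMeans(c2))) / 2
  expect_equal(upd, (3 * s1 + 2 * s2) / 5, tolerance = 1e-12)
  # repeated z = mu_k updates telescope to N/(N+T) shrinkage
  sw <- pooled
  for (t in 1:7) sw <- update_pooled_cov(sw, 4 + t - 1, matrix(0, 2, 2))
  expect_equal(sw, 4 / 11 * pooled, tolerance = 1e-12)
})

test_that("policy none leaves the decision stream and model untouched", {
  feats <- make_gaussian_features(n_class = 3, d = 3, n_per = 10)
  m <- fit_discriminant(feats, mode = "qda")
  set.seed(43)
  X <- matrix(rnorm(90, mean = 8), 30, 3)
  st <- run_stream(m, feature_iterator(X), policy = "none")
  expect_identical(st$decisions, classify(m, X))
  expect_identical(st$model$covs, m$covs)
  expect_identical(st$model$means, m$means)
  expect_identical(st$model$n_c, m$n_c)
})

test_that("streamed MC parameters equal a batch refit on predicted labels", {
  set.seed(44)
  for (mode in c("lda", "qda")) {
    feats <- make_gaussian_features(n_class = 3, d = 4, n_per = 10, shift = 4)
    m0 <- fit_discriminant(feats, mode = mode)
    Xtr <- as.matrix(feats[feature_cols(feats)])
    T_ <- 40
    Xte <- matrix(rnorm(T_ * 4, mean = 4 * sample(1:3, T_, TRUE)), T_, 4)
    st <- run_stream(m0, feature_iterator(Xte), policy = "mc")
    ref <- batch_ml_fit(rbind(Xtr, Xte),
                        c(feats$label, st$decisions),
                        class_ids = m0$class_ids)
    for (i in seq_along(m0$class_ids)) {
      expect_lt(rel_err(st$model$means[[i]], ref$stats[[i]]$mean), 1e-8)
      if (mode == "qda") {
        expect_lt(rel_err(st$model$covs[[i]], ref$stats[[i]]$cov), 1e-8)
      }
      expect_equal(st$model$n_c[i], ref$stats[[i]]$n)
    }
    if (mode == "lda") {
      expect_lt(rel_err(st$model$pooled_cov, ref$pooled), 1e-8)
    }
    expect_equal(st$model$N, ref$N)
  }
})

test_that("policy M refits means only; policy C applies the recursions", {
  set.seed(45)
  feats <- make_gaussian_features(n_class = 2, d = 3, n_per = 8, shift = 4)
  m0 <- fit_discriminant(feats, mode = "qda")
  Xte <- matrix(rnorm(60, mean = 4 * sample(1:2, 20, TRUE)), 20, 3)

  stM <- run_stream(m0, feature_iterator(Xte), policy = "m")
  Xtr <- as.matrix(feats[feature_cols(feats)])
  ref <- batch_ml_fit(rbind(Xtr, Xte), c(feats$label, stM$decisions),
                      class_ids = m0$class_ids)
  for (i in 1:2) {
    expect_lt(rel_err(stM$model$means[[i]], ref$stats[[i]]$mean), 1e-8)
    expect_identical(stM$model$covs[[i]], m0$covs[[i]])  # untouched
  }

  # C policy: independent re-application of the recursions with fixed means
  stC <- run_stream(m0, feature_iterator(Xte), policy = "c")
  covs <- m0$covs; n_c <- m0$n_c
  mdl <- m0
  for (t in seq_len(nrow(Xte))) {
    z <- Xte[t, ]
    k <- match(classify(mdl, z), mdl$class_ids)
    ck <- (n_c[k] / (n_c[k] + 1)) * tcrossprod(z - mdl$means[[k]])
    covs[[k]] <- (n_c[k] * covs[[k]] + ck) / (n_c[k] + 1)
    n_c[k] <- n_c[k] + 1
    # rebuild a reference model reflecting the update (means fixed)
    mdl$covs <- covs
    mdl$n_c <- n_c
    mdl$N <- mdl$N + 1
    mdl$priors <- n_c / mdl$N
    mdl <- selfemg:::rebuild_cache(mdl)
  }
  for (i in 1:2) {
    expect_lt(rel_err(stC$model$covs[[i]], covs[[i]]), 1e-10)
    expect_identical(stC$model$means[[i]], m0$means[[i]])
  }
})

test_that("a step touches only the predicted class", {
  feats <- make_gaussian_features(n_class = 4, d = 3, n_per = 6, shift = 6)
  m <- fit_discriminant(feats, mode = "qda")
  z <- m$means[[2]] + 0.1
  step <- enhance_step(m, z, "mc")
  expect_identical(step$predicted, m$class_ids[2])
  for (i in c(1, 3, 4)) {
    expect_identical(step$model$means[[i]], m$means[[i]])
    expect_identical(step$model$covs[[i]], m$covs[[i]])
    expect_identical(step$model$n_c[i], m$n_c[i])
  }
  expect_equal(step$model$n_c[2], m$n_c[2] + 1)
})

test_that("counts stay monotone and consistent through a stream", {
  feats <- make_gaussian_features(n_class = 3, d = 2, n_per = 6, shift = 5)
  m <- fit_discriminant(feats, mode = "lda")
  set.seed(46)
  X <- matrix(rnorm(60, mean = 10), 30, 2)
  for (pol in c("m", "c", "mc")) {
    mdl <- m
    it <- feature_iterator(X)
    repeat {
      z <- it()
      if (is.null(z)) break
      old <- mdl$n_c
      mdl <- enhance_step(mdl, z, pol)$model
      expect_true(all(mdl$n_c >= old))
      expect_equal(sum(mdl$n_c), mdl$N)
    }
    expect_equal(mdl$N, m$N + 30)
  }
})

test_that("the stream engine requires an iterator and handles empty streams", {
  feats <- make_gaussian_features(n_class = 2, d = 2, n_per = 6)
  m <- fit_discriminant(feats, mode = "lda")
  expect_error(run_stream(m, matrix(0, 3, 2)), "iterator")
  st <- run_stream(m, function() NULL, policy = "mc")
  expect_length(st$decisions, 0)
  expect_identical(st$model$means, m$means)
  expect_equal(nrow(st$events), 0)
})

test_that("checkpoint/resume across save/load equals a single pass", {
  set.seed(47)
  feats <- make_gaussian_features(n_class = 3, d = 3, n_per = 8, shift = 4)
  for (mode in c("lda", "qda")) {
    m0 <- fit_discriminant(feats, mode = mode)
    X <- matrix(rnorm(120, mean = 4 * sample(1:3, 40, TRUE)), 40, 3)
    one <- run_stream(m0, feature_iterator(X), policy = "mc")
    half1 <- run_stream(m0, feature_iterator(X[1:17, ]), policy = "mc")
    path <- withr::local_tempfile(fileext = ".json")
    save_model(half1$model, path)
    resumed <- load_model(path)
    half2 <- run_stream(resumed, feature_iterator(X[18:40, ]), policy = "mc")
    expect_identical(c(half1$decisions, half2$decisions), one$decisions)
    expect_identical(half2$model$means, one$model$means)
    expect_identical(half2$model$covs, one$model$covs)
    expect_identical(half2$model$pooled_cov, one$model$pooled_cov)
    expect_identical(half2$model$n_c, one$model$n_c)
  }
})

test_that("self-enhancement is stable on a stationary stream", {
  # drift-free Gaussian stream: MC decisions should almost never diverge
  # from the static ones
  set.seed(48)
  feats <- make_gaussian_features(n_class = 3, d = 4, n_per = 50, shift = 3)
  m <- fit_discriminant(feats, mode = "qda")
  n <- 2000
  cls <- sample(1:3, n, TRUE)
  X <- matrix(rnorm(n * 4, mean = 3 * cls), n, 4)
  static <- classify(m, X)
  st <- run_stream(m, feature_iterator(X), policy = "mc")
  expect_gte(mean(static == st$decisions), 0.99)
})

test_that("a near-mean update barely moves an LDA boundary", {
  feats <- make_gaussian_features(n_class = 2, d = 2, n_per = 10, shift = 4)
  m <- fit_discriminant(feats, mode = "lda")
  step <- enhance_step(m, m$means[[1]], "mc")
  # z = mu_k: mean unchanged, pooled shrunk by N/(N+1)
  expect_equal(step$model$means[[1]], m$means[[1]], tolerance = 1e-12)
  expect_equal(step$model$pooled_cov, m$N / (m$N + 1) * m$pooled_cov,
               tolerance = 1e-12)
})
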