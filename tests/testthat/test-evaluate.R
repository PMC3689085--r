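test_that("widely separated classes are recognised perfectly", {
  feats <- make_gaussian_features(n_class = 3, d = 3, n_per = 15,
                                  cycles = 1:4, shift = 50)
  ev <- evaluate_features(feats, "qda", "none", train_cycles = 2)
  expect_equal(ev$overall_ra, 100)
  expect_true(all(ev$per_class_ra$ra == 100))
  ev2 <- evaluate_features(feats, "lda", "mc", train_cycles = 2)
  expect_equal(ev2$overall_ra, 100)
})

test_that("an independent re-scoring reproduces every metric", {
  feats <- make_gaussian_features(n_class = 3, d = 2, n_per = 12,
                                  cycles = 1:6, shift = 2.2)
  ev <- evaluate_features(feats, "qda", "mc", train_cycles = 2)
  dec <- ev$decisions
  # overall
  expect_equal(ev$overall_ra, 100 * mean(dec$truth == dec$predicted))
  # cumulative: the i-th value averages decisions over testing cycles 1..i
  cyc <- sort(unique(dec$cycle))
  for (i in seq_along(cyc)) {
    sel <- dec$cycle %in% cyc[seq_len(i)]
    expect_equal(ev$cumulative_ra$ra[i],
                 100 * mean(dec$truth[sel] == dec$predicted[sel]))
  }
  expect_equal(ev$cumulative_ra$ra[length(cyc)], ev$overall_ra)
  # confusion row sums are per-class truth counts
  expect_equal(unname(rowSums(ev$confusion)),
               unname(as.vector(table(factor(dec$truth,
                                             sort(unique(dec$truth)))))))
  # per-trial: trials are blocks of five testing cycles
  expect_equal(ev$per_trial_ra$ra[1],
               100 * mean((dec$truth == dec$predicted)[dec$cycle %in%
                                                         cyc[1:min(5, length(cyc))]]))
})

test_that("cumulative RA is prefix-consistent", {
  feats <- make_gaussian_features(n_class = 2, d = 2, n_per = 10,
                                  cycles = 1:6, shift = 2)
  full <- evaluate_features(feats, "lda", "mc", train_cycles = 2)
  trunc <- evaluate_features(feats[feats$cycle <= 4, ], "lda", "mc",
                             train_cycles = 2)
  expect_equal(full$cumulative_ra$ra[1:2], trunc$cumulative_ra$ra)
})

test_that("an empty testing cycle is reported as an error", {
  feats <- make_gaussian_features(n_class = 2, d = 2, n_per = 8, cycles = 1:5)
  gap <- feats[feats$cycle != 4, ]
  expect_error(evaluate_features(gap, "lda", "none", train_cycles = 2),
               "cycle 4 contains no windows")
})

test_that("the stream engine never sees labels", {
  feats <- make_gaussian_features(n_class = 2, d = 3, n_per = 5)
  it <- feature_iterator(feats)
  z <- it()
  expect_length(z, 3)
  expect_named(z, c("f1", "f2", "f3"))
})

test_that("cosine_angle matches closed forms and rejects zero vectors", {
  expect_equal(cosine_angle(c(2, 0), c(5, 0)), 1)
  expect_equal(cosine_angle(c(1, 0), c(0, 3)), 0)
  expect_equal(cosine_angle(c(1, 0), c(1, 1)), sqrt(2) / 2)
  expect_equal(cosine_angle(c(1, 2), -c(1, 2)), -1)
  expect_error(cosine_angle(c(0, 0), c(1, 1)), "zero vector")
})

test_that("drift diagnostics recover eigenstructure and detect identity", {
  feats <- make_gaussian_features(n_class = 2, d = 3, n_per = 12)
  m <- fit_discriminant(feats, mode = "qda")
  dg <- drift_diagnostics(list(`7` = m), m)
  expect_equal(unique(dg$cycle), 7L)
  expect_true(all(abs(dg$mean_cos - 1) < 1e-12))
  expect_true(all(abs(dg$axis1_cos - 1) < 1e-10))
  # axis lengths against an independent eigensolver route (SVD)
  for (i in 1:2) {
    sv <- svd(m$covs[[i]])$d
    row <- dg[dg$class == m$class_ids[i], ]
    expect_equal(row$axis1_length, sqrt(sv[1]), tolerance = 1e-10)
    expect_equal(row$axis2_length, sqrt(sv[2]), tolerance = 1e-10)
  }
})

test_that("isotropic covariances give equal, finite axis lengths", {
  m <- fit_discriminant(make_gaussian_features(n_class = 2, d = 3,
                                               n_per = 10),
                        mode = "qda")
  iso <- m
  iso$covs <- lapply(iso$covs, function(s) diag(2.25, 3))
  dg <- drift_diagnostics(list(`1` = iso), iso)
  cls <- dg[dg$class != "(pooled)", ]
  expect_equal(cls$axis1_length, rep(1.5, 2))
  expect_equal(cls$axis2_length, rep(1.5, 2))
  expect_true(all(cls$axis1_cos >= -1 & cls$axis1_cos <= 1))
})

test_that("paired t statistic matches the closed form", {
  out <- paired_ra_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$mean_diff, 2)
  swap <- paired_ra_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(swap$t, -out$t)
  expect_equal(swap$p, out$p)
  expect_error(paired_ra_test(c(1, 2, 3), c(0, 1, 2)),
               "differences are equal")
  expect_error(paired_ra_test(1, 1), "at least 2")
})

test_that("compare_methods produces the full grid deterministically", {
  p <- protocol_spec(1, n_classes = 3, n_channels = 2, n_cycles = 4,
                     train_cycles = 2, seed = 12)
  cmp <- compare_methods(n_subjects = 2, protocol = p,
                         drift = drift_spec(0.3), kinds = "fc",
                         policies = c("none", "m"))
  expect_equal(nrow(cmp$results), 2 * 2 * 2)  # subjects x modes x policies
  expect_equal(nrow(cmp$summary), 4)
  expect_equal(nrow(cmp$t_tests), 2)
  expect_setequal(unique(cmp$results$method),
                  c("LDA", "QDA", "SELDA(M)", "SEQDA(M)"))
  cmp2 <- compare_methods(n_subjects = 2, protocol = p,
                          drift = drift_spec(0.3), kinds = "fc",
                          policies = c("none", "m"))
  expect_identical(cmp$results$overall_ra, cmp2$results$overall_ra)
})

test_that("evaluation objects summarise and plot", {
  feats <- make_gaussian_features(n_class = 2, d = 2, n_per = 10,
                                  cycles = 1:4, shift = 3)
  ev <- evaluate_features(feats, "qda", "mc", train_cycles = 2)
  gl <- glance(ev)
  expect_equal(gl$overall_ra, ev$overall_ra)
  td <- tidy(ev)
  expect_named(td, c("cycle", "ra", "cumulative_ra"))
  expect_s3_class(autoplot(ev), "ggplot")
  dg <- drift_diagnostics(ev$snapshots, ev$model_train)
  expect_s3_class(plot_drift_diagnostics(dg), "ggplot")
})
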