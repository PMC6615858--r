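# Independent oracle: full Gaussian-Bayes posterior by direct density
# evaluation (explicit quadratic form and normalization), sharing no code
# with the discriminant-based classifier.
bayes_oracle <- function(x_train, y_train, x_test, shrinkage = 0) {
  y_train <- as.factor(y_train)
  lev <- levels(y_train)
  p <- ncol(x_train)
  ss <- matrix(0, p, p)
  mus <- list()
  for (cl in lev) {
    xi <- x_train[y_train == cl, , drop = FALSE]
    mus[[cl]] <- colMeans(xi)
    ss <- ss + crossprod(sweep(xi, 2, mus[[cl]]))
  }
  S <- ss / (nrow(x_train) - length(lev))
  if (shrinkage > 0)
    S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(p)
  dens <- sapply(lev, function(cl) {
    apply(x_test, 1, function(v) {
      d <- v - mus[[cl]]
      exp(-0.5 * drop(t(d) %*% solve(S) %*% d)) /
        sqrt((2 * pi)^p * det(S))
    })
  })
  dens <- matrix(dens, nrow(x_test), length(lev))
  dens / rowSums(dens)
}

test_that("LDA posteriors match direct Gaussian-Bayes density evaluation", {
  # fixed 4-class, 8-trial, 2-feature toy problem with integer coordinates
  x <- matrix(c(0, 0, 1, 0, 4, 0, 5, 1,
                0, 4, 1, 5, 4, 4, 5, 5), ncol = 2, byrow = TRUE)
  y <- rep(c("a", "b", "c", "d"), each = 2)
  xt <- matrix(c(0.5, 0.2, 4.2, 0.5, 2, 2, 0.1, 4.4), ncol = 2, byrow = TRUE)
  for (s in c(0, 0.1)) {
    model <- fit_lda(x, y, shrinkage = s)
    expect_equal(unname(predict_lda(model, xt)),
                 unname(bayes_oracle(x, y, xt, shrinkage = s)),
                 tolerance = 1e-8)
  }
})

test_that("LDA behaves correctly in limits and degenerate designs", {
  set.seed(3)
  # well-separated classes: held-out posterior of the true class -> 1
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 20), ncol = 2))
  y <- rep(c("a", "b"), each = 100)
  m <- fit_lda(x, y, shrinkage = 0.01)
  pr <- predict_lda(m, rbind(c(0, 0), c(20, 20)))
  expect_gt(pr[1, "a"], 0.999)
  expect_gt(pr[2, "b"], 0.999)
  # trial equidistant from two class means gets a 0.5/0.5 split
  x2 <- rbind(c(0, 0), c(0.1, 0), c(2, 0), c(2.1, 0), c(50, 50), c(50, 51))
  y2 <- c("a", "a", "b", "b", "c", "c")
  pr2 <- predict_lda(fit_lda(x2, y2, 0.1), matrix(c(1.05, 0), 1))
  expect_equal(unname(pr2[1, "a"]), unname(pr2[1, "b"]), tolerance = 1e-9)
  expect_lt(pr2[1, "c"], 1e-6)
  # duplicated features (perfect collinearity) still fit with shrinkage
  x3 <- cbind(x[, 1], x[, 1])
  expect_silent(fit_lda(x3, y, shrinkage = 0.1))
  expect_error(fit_lda(x3, y, shrinkage = 0), "shrinkage")
  # probabilities sum to 1
  pr3 <- predict_lda(m, matrix(rnorm(20), ncol = 2))
  expect_equal(rowSums(pr3), rep(1, 10))
  expect_error(predict_lda(m, matrix(0, 2, 3)), "dimension")
})

test_that("oversampling equalizes stimulus x position cells within folds only", {
  labels <- c(rep("a", 3), rep("b", 5), rep("a", 4), rep("b", 4))
  pos <- rep(1, 16)
  fold <- rep(c(1, 2), c(8, 8))
  aug <- stratify_oversample(labels, pos, fold, seed = 1)
  # fold 1 cells {3, 5} -> both 5 (2 duplicates added)
  expect_length(aug[[1]], 10)
  expect_equal(sum(labels[aug[[1]]] == "a"), 5)
  expect_equal(sum(labels[aug[[1]]] == "b"), 5)
  # fold 2 already balanced: unchanged
  expect_equal(aug[[2]], 9:16)
  # indices never cross folds
  expect_true(all(aug[[1]] %in% 1:8) && all(aug[[2]] %in% 9:16))
  expect_error(stratify_oversample(c("a", "a", "b"), c(1, 2, 1), c(1, 1, 1)),
               "empty")
})

test_that("shuffled labels decode at chance and real structure decodes above it", {
  ep <- make_session(n_events = 320, seed = 21)
  # destroy the label-signal relation
  ep_sh <- ep
  set.seed(99)
  ep_sh$trials$color_angle <- sample(ep$trials$color_angle)
  ct <- crossvalidated_confusion(ep_sh, "color", cv_scheme(n_folds = 2, seed = 4))
  tc <- accuracy_timecourse(ct)
  se <- sqrt(0.125 * 0.875 / 320)
  expect_lt(abs(mean(tc$values) - 0.125), 3 * se)
  # rows sum to 1 at every time point
  rs <- apply(ct$probs, c(1, 2), sum)
  expect_true(all(abs(rs - 1) < 1e-9))
  # intact labels: strong information in the response window
  ct2 <- crossvalidated_confusion(ep, "color", cv_scheme(n_folds = 2, seed = 4))
  tc2 <- accuracy_timecourse(ct2)
  expect_gt(max(tc2$values), 0.8)
  expect_lt(abs(mean(tc2$values[tc2$time < 0]) - 0.125), 3 * se)
  expect_error(crossvalidated_confusion(subset_epochs(ep, epochs = 1:10),
                                        "color", cv_scheme(n_folds = 10)),
               "n_folds")
})

test_that("class relabeling permutes confusion rows and columns identically", {
  ep <- make_session(n_events = 240, seed = 31, noise_sd = 0.1)
  ct <- crossvalidated_confusion(ep, "color", cv_scheme(n_folds = 2, seed = 6))
  # relabel classes by a fixed circular shift of 90 degrees
  ep2 <- ep
  ep2$trials$color_angle <- (ep$trials$color_angle + 90) %% 360
  ct2 <- crossvalidated_confusion(ep2, "color", cv_scheme(n_folds = 2, seed = 6))
  pi_map <- match((ct$classes + 90) %% 360, ct2$classes)
  for (t in c(1, 35, 60))
    expect_equal(ct2$probs[t, pi_map, pi_map], ct$probs[t, , ],
                 tolerance = 1e-10)
})

test_that("unit subsampling enumerates or caps combinations and averages", {
  ep <- make_session(n_events = 160, seed = 41, n_units = 6)
  # exactly 5 channels: single combination equals direct decoding
  ep5 <- subset_epochs(ep, channels = 1:5)
  direct <- crossvalidated_confusion(ep5, "color", cv_scheme(n_folds = 2, seed = 2))
  sub <- subsample_units(ep5, feature = "color",
                         scheme = cv_scheme(n_folds = 2, seed = 2))
  expect_equal(attr(sub, "n_combos"), 1)
  expect_equal(sub$probs, direct$probs, tolerance = 1e-12)
  # 6 channels -> C(6,5) = 6 enumerated combinations
  sub6 <- subsample_units(ep, feature = "color",
                          scheme = cv_scheme(n_folds = 2, seed = 2))
  expect_equal(attr(sub6, "n_combos"), 6)
  expect_error(subsample_units(subset_epochs(ep, channels = 1:4)),
               "at least 5")
})

test_that("subsampling caps at 40 seed-reproducible distinct combinations", {
  ep <- make_session(n_events = 120, seed = 43, n_units = 12, noise_sd = 0.4)
  s1 <- subsample_units(ep, feature = "color",
                        scheme = cv_scheme(n_folds = 2, seed = 3), seed = 8)
  s2 <- subsample_units(ep, feature = "color",
                        scheme = cv_scheme(n_folds = 2, seed = 3), seed = 8)
  expect_equal(attr(s1, "n_combos"), 40)
  expect_identical(s1$probs, s2$probs)
})

test_that("12-to-8 class interpolation respects the torus geometry", {
  tt <- c(0, 10)
  # uniform tensor stays uniform
  u <- confusion_tensor(array(1 / 12, c(2, 12, 12)), tt, (0:11) * 30)
  u8 <- interpolate_confusion(u)
  expect_equal(dim(u8$probs), c(2, 8, 8))
  expect_true(all(abs(u8$probs - 1 / 8) < 1e-12))
  # smooth circular kernel evaluated on the 12-grid interpolates to the
  # kernel evaluated on the 8-grid
  f <- function(d) 0.2 + exp(2 * (cos(d * pi / 180) - 1))
  m12 <- circulant_confusion(f, 12)
  c12 <- confusion_tensor(array(rep(t(m12), each = 2), c(2, 12, 12)),
                          tt, (0:11) * 30)
  c8 <- interpolate_confusion(c12)
  m8 <- circulant_confusion(f, 8)
  expect_equal(matrix(c8$probs[1, , ], 8, 8), unclass(m8),
               ignore_attr = TRUE, tolerance = 0.04)
  expect_error(interpolate_confusion(random_confusion(K = 8)), "12-class")
})

test_that("hit-rate timecourse is the diagonal mean with chance 1/K", {
  ident <- confusion_tensor(array(rep(diag(8), each = 3), c(3, 8, 8)),
                            c(0, 10, 20), (0:7) * 45)
  expect_true(all(accuracy_timecourse(ident)$values == 1))
  unif <- confusion_tensor(array(1 / 8, c(3, 8, 8)), c(0, 10, 20), (0:7) * 45)
  tcu <- accuracy_timecourse(unif)
  expect_true(all(tcu$values == 0.125))
  expect_equal(tcu$chance, 0.125)
  rc <- random_confusion(n_time = 4, K = 6, seed = 5)
  tc <- accuracy_timecourse(rc)
  manual <- sapply(1:4, function(t) mean(diag(matrix(rc$probs[t, , ], 6, 6))))
  expect_equal(tc$values, manual)
})

test_that("oversampling confined to folds does not leak: pure noise stays at chance", {
  tr <- generate_stimulus_stream(stimulus_config("B"), 960, seed = 81)
  pop <- population_config("N", n_units = 4, tuning_shape = "untuned",
                           amplitude = 0, noise_sd = 1)
  ep <- simulate_tuned_responses(tr, pop, seed = 82)
  scheme <- cv_scheme(n_folds = 2, stratify_by_sequence_position = TRUE,
                      oversample = TRUE, seed = 9)
  tc <- accuracy_timecourse(crossvalidated_confusion(ep, "color", scheme))
  se <- sqrt(0.125 * 0.875 / 960)
  expect_lt(abs(mean(tc$values) - 0.125), 3 * se)
})
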