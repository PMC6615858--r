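test_that("distance collapse averages confusion cells by circular offset", {
  # identity matrix: all mass at offset 0
  ident <- diag(8)
  attr(ident, "classes") <- (0:7) * 45
  tc <- collapse_to_tuning(ident)
  expect_equal(tc$distances, c(-135, -90, -45, 0, 45, 90, 135, 180))
  expect_equal(tc$probs[tc$distances == 0], 1)
  expect_true(all(tc$probs[tc$distances != 0] == 0))
  # circulant matrix built from a kernel returns the kernel exactly
  f <- function(d) 0.05 + 0.2 * exp(2 * (cos(d * pi / 180) - 1))
  m <- circulant_confusion(f, 8)
  tcm <- collapse_to_tuning(m)
  expect_equal(tcm$probs, f(tcm$distances) / sum(f(circ_diff((0:7) * 45, 0))),
               tolerance = 1e-12)
  # random matrix: equals independently coded group-by-offset means
  set.seed(4)
  r <- matrix(runif(64), 8)
  attr(r, "classes") <- (0:7) * 45
  tcr <- collapse_to_tuning(r)
  for (k in seq_along(tcr$distances)) {
    d <- tcr$distances[k]
    acc <- c()
    for (i in 1:8) for (j in 1:8)
      if (circ_diff((j - 1) * 45, (i - 1) * 45) == d) acc <- c(acc, r[i, j])
    expect_equal(tcr$probs[k], mean(acc))
  }
  # probability conservation: weighted offset sums equal the matrix total
  counts <- vapply(tcr$distances, function(d)
    sum(circ_diff(outer((0:7) * 45, (0:7) * 45, function(j, i)
      circ_diff(j, i)), 0) == d), numeric(1))
  expect_equal(sum(tcr$probs * 8), sum(r))
})

test_that("bimodality index follows its defining formula and conventions", {
  # symmetric toy curve [0.30, 0.15, 0.05, 0.10, 0.20] at 0..180 by 45
  tc <- list(distances = c(-135, -90, -45, 0, 45, 90, 135, 180),
             probs = c(0.10, 0.05, 0.15, 0.30, 0.15, 0.05, 0.10, 0.20))
  bi <- bimodality_index(tc)
  expect_equal(bi$value, (0.20 - 0.10) / (0.30 - 0.05))
  expect_equal(bi$value, 0.4)
  # monotonically decaying (unimodal) curve: negative index
  cosbump <- list(distances = tc$distances,
                  probs = 0.1 + 0.2 * exp(2 * (cos(tc$distances * pi / 180) - 1)))
  expect_lt(bimodality_index(cosbump)$value, 0)
  # flat curve: 0 by convention
  flat <- list(distances = tc$distances, probs = rep(0.125, 8))
  expect_equal(bimodality_index(flat)$value, 0)
  # affine rescaling leaves the index unchanged
  resc <- list(distances = tc$distances, probs = 3 * tc$probs + 0.05)
  expect_equal(bimodality_index(resc)$value, 0.4)
  # asymmetric 135/-135 entries are averaged
  asym <- tc; asym$probs[tc$distances == -135] <- 0.06
  expect_equal(bimodality_index(asym)$value, (0.20 - 0.08) / (0.30 - 0.05))
  expect_error(bimodality_index(list(distances = c(0, 90), probs = c(1, 0))),
               "offsets")
})

test_that("group bimodality test is one-sided against zero", {
  expect_lt(bimodality_group_test(c(0.2, 0.3, 0.25, 0.18))$p, 0.01)
  expect_gt(bimodality_group_test(c(-0.2, -0.1, -0.3, 0.01))$p, 0.5)
  z <- bimodality_group_test(rep(0, 5))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
  expect_error(bimodality_group_test(c(0.1, 0.2)), "at least 3")
})

test_that("similarity is explained by bimodality differences when constructed so", {
  bi <- c(a = 0, b = 0.05, c = 0.6, d = 0.7)
  pairs <- utils::combn(names(bi), 2, simplify = FALSE)
  sims <- data.frame(
    entity1 = vapply(pairs, `[`, "", 1),
    entity2 = vapply(pairs, `[`, "", 2))
  # similarity exactly affine in -|delta BI| (lm warns about the
  # perfect fit; the warning is expected here)
  sims$r <- 0.9 - 1.2 * abs(bi[sims$entity1] - bi[sims$entity2])
  res <- suppressWarnings(similarity_vs_bimodality_regression(sims, bi))
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$slope, -1.2, tolerance = 1e-12)
  # degenerate: all differences equal
  bi2 <- c(a = 0, b = 0.1)
  sims2 <- data.frame(entity1 = c("a", "a", "b"), entity2 = c("b", "b", "a"),
                      r = c(0.5, 0.4, 0.6))
  expect_warning(res2 <- similarity_vs_bimodality_regression(sims2, bi2),
                 "degenerate")
  expect_true(res2$degenerate)
})

test_that("single-channel tuning aligns preferred stimuli and detects axis tuning", {
  # unimodal channels with random preferred directions: aligned average
  # peaks at 0, no positive bimodality
  ep_uni <- make_session(n_events = 320, seed = 61, shape = "unimodal",
                         noise_sd = 0.3)
  res_uni <- single_channel_tuning(ep_uni, "color")
  expect_gt(length(res_uni$selected), 0)
  expect_equal(res_uni$curve$distances[which.max(res_uni$curve$probs)], 0)
  expect_lt(mean(res_uni$bimodality), 0.05)
  # axis-tuned channels: second peak at 180 degrees, group p small
  ep_bi <- make_session(n_events = 320, seed = 62, shape = "bimodal",
                        feature = "motion", noise_sd = 0.3)
  res_bi <- single_channel_tuning(ep_bi, "motion")
  pk180 <- res_bi$curve$probs[res_bi$curve$distances == 180]
  pk135 <- mean(res_bi$curve$probs[abs(res_bi$curve$distances) == 135])
  expect_gt(pk180, pk135)
  expect_lt(res_bi$group_p, 0.05)
  expect_gt(mean(res_bi$bimodality), 0.2)
})

test_that("untuned channels are rejected by the ANOVA screen at about the nominal rate", {
  ep <- make_session(n_events = 2400, seed = 63, shape = "untuned",
                     n_units = 40, noise_sd = 0.3)
  res <- single_channel_tuning(ep, "color")
  # selection rate should be near alpha = 0.05 (binomial 3-sigma band)
  expect_lte(length(res$selected), 40 * 0.05 + 3 * sqrt(40 * 0.05 * 0.95))
})
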