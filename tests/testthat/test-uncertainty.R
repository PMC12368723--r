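# Monte Carlo perturbation: distributional law, uncertainty reports,
# RBF surfaces, robustness scoring.

test_that("zero perturbation is the identity", {
  x <- as.numeric(reference_input())
  expect_equal(unname(perturb_input(x, sigma = 0, seed = 1)), x)
  rep0 <- mc_uncertainty(
    list(rt = function(df) df$x1 * 10, cr = function(df) df$x2,
         cost = function(df) df$x3 + df$x4),
    samples = as.data.frame(as.list(stats::setNames(x, paste0("x", 1:14)))),
    cfg = perturbation_config(sigmas = 0, replicates = 50, seed = 2))
  expect_true(all(rep0$ci_width == 0))
  expect_true(all(rep0$rel_uncertainty == 0))
})

test_that("empirical perturbation sd matches sigma * |x| within 3%", {
  x <- as.numeric(reference_input())
  set.seed(31)
  draws <- t(replicate(10000, perturb_input(x, sigma = 0.2, clip = FALSE)))
  sds <- apply(draws, 2, stats::sd)
  expect_true(all(abs(sds - 0.2 * x) / (0.2 * x) < 0.03))
  means <- colMeans(draws)
  expect_true(all(abs(means - x) / x < 0.02))
  # with clipping all outputs stay inside the sampling box
  b <- input_bounds()
  clipped <- t(replicate(500, perturb_input(x, sigma = 0.5, clip = TRUE)))
  expect_true(all(t(clipped) >= b$min & t(clipped) <= b$max))
  # per-feature weights scale the noise
  w <- c(2, rep(0, 13))
  dw <- t(replicate(5000, perturb_input(x, sigma = 0.1, w = w, clip = FALSE)))
  expect_equal(stats::sd(dw[, 1]), 2 * 0.1 * x[1], tolerance = 0.05)
  expect_true(all(dw[, -1] == rep(x[-1], each = 5000)))
})

test_that("relative uncertainty matches the Gaussian closed form", {
  # identity model on x1 with x1 = 10 and sd 1: predictions ~ N(10, 1),
  # so the 95% percentile CI width is 2 * 1.96 and rel. uncertainty
  # 100 * 3.92 / 10 = 39.2%
  models <- list(rt = function(df) df$x1, cr = function(df) df$x1,
                 cost = function(df) df$x1)
  s <- as.data.frame(as.list(stats::setNames(c(10, rep(1, 13)),
                                             paste0("x", 1:14))))
  rep1 <- mc_uncertainty(models, s,
                         perturbation_config(sigmas = 0.1, replicates = 500,
                                             clip = FALSE, seed = 3))
  expect_equal(rep1$rel_uncertainty[rep1$metric == "rt"], 39.2,
               tolerance = 0.08)
  # identical seeds give identical reports
  rep2 <- mc_uncertainty(models, s,
                         perturbation_config(sigmas = 0.1, replicates = 500,
                                             clip = FALSE, seed = 3))
  expect_identical(rep1, rep2)
  # CI brackets the replicate mean
  expect_true(all(rep1$ci_lower <= rep1$mean & rep1$mean <= rep1$ci_upper))
})

test_that("near-zero baselines yield missing relative uncertainty", {
  models <- list(rt = function(df) df$x1 - 10, cr = function(df) df$x1,
                 cost = function(df) df$x1)
  s <- as.data.frame(as.list(stats::setNames(c(10, rep(1, 13)),
                                             paste0("x", 1:14))))
  rep1 <- mc_uncertainty(models, s,
                         perturbation_config(sigmas = 0.1, replicates = 100,
                                             clip = FALSE, seed = 4))
  rt_row <- rep1[rep1$metric == "rt", ]
  expect_true(is.na(rt_row$rel_uncertainty))
  expect_gt(rt_row$ci_width, 0)
})

test_that("RBF sensitivity surfaces interpolate node values exactly", {
  flat <- list(rt = function(df) rep(7, nrow(df)))
  grid <- list(x5 = c(0.002, 0.01, 0.05), x3 = c(0.1, 0.5, 1.5))
  s0 <- sensitivity_surface(flat, grid, sigma = 0.3,
                            cfg = perturbation_config(replicates = 50, seed = 5),
                            dense_n = 10)
  expect_true(all(s0$nodes$value == 0))
  expect_lt(max(abs(s0$dense$value)), 1e-9)
  # smooth synthetic model: node reproduction and refinement stability
  smooth <- list(rt = function(df) 5 + 40 * df$x5 + df$x3^2)
  s1 <- sensitivity_surface(smooth, grid, sigma = 0.2,
                            cfg = perturbation_config(replicates = 400, seed = 6),
                            dense_n = 9)
  # interpolant is exact at the nodes (match dense points on node coords)
  for (i in seq_len(nrow(s1$nodes))) {
    at <- s1$dense[abs(s1$dense$x5 - s1$nodes$x5[i]) < 1e-12 &
                   abs(s1$dense$x3 - s1$nodes$x3[i]) < 1e-12, ]
    if (nrow(at)) expect_equal(at$value, s1$nodes$value[i], tolerance = 1e-6)
  }
  expect_error(sensitivity_surface(smooth, list(x5 = 0.01, x3 = 0.5),
                                   sigma = 0.2), "degenerate")
})

test_that("grid refinement changes a smooth sensitivity field by < 5% RMS", {
  smooth <- list(rt = function(df) 5 + 40 * df$x5 + df$x3^2)
  cfgp <- perturbation_config(replicates = 4000, seed = 7)
  g1 <- list(x5 = seq(0.002, 0.08, length.out = 5),
             x3 = seq(0.1, 1.8, length.out = 5))
  g2 <- list(x5 = seq(0.002, 0.08, length.out = 9),
             x3 = seq(0.1, 1.8, length.out = 9))
  s1 <- sensitivity_surface(smooth, g1, sigma = 0.2, cfg = cfgp, dense_n = 12)
  s2 <- sensitivity_surface(smooth, g2, sigma = 0.2, cfg = cfgp, dense_n = 12)
  rms <- sqrt(mean((s1$dense$value - s2$dense$value)^2))
  expect_lt(rms / sqrt(mean(s2$dense$value^2)), 0.05)
})

test_that("robustness scoring is null at sigma 0 and ranks flat models first", {
  strategies <- data.frame(name = c("a", "b"),
                           x3 = c(0.5, 0.5), x5 = c(0.01, 0.01),
                           x6 = c(0.02, 0.02))
  models <- list(rt = function(df) 3 + 100 * df$x5, cr = function(df) 0.9 + 0 * df$x1,
                 cost = function(df) 400 + 0 * df$x1)
  r0 <- assess_robustness(strategies, models, sigma = 0, replicates = 20,
                          seed = 8)
  expect_true(all(unlist(r0[, grep("_pct", names(r0))]) == 0))
  expect_true(all(r0$combined_score == 0))
  # identical strategies score identically under the same seed
  r1 <- assess_robustness(strategies, models, sigma = 0.2, replicates = 30,
                          seed = 9)
  expect_equal(r1$combined_score[1], r1$combined_score[2])
  # flat-response strategy beats one at a steep RT region
  steep <- data.frame(name = c("flat", "steep"),
                      x3 = c(0.5, 0.5), x5 = c(0.119, 0.003),
                      x6 = c(0.02, 0.02))
  grad_models <- list(
    rt = function(df) 3 + 1000 * pmax(0, 0.0121 - df$x5),
    cr = function(df) rep(0.9, nrow(df)),
    cost = function(df) rep(400, nrow(df)))
  r2 <- assess_robustness(steep, grad_models, sigma = 0.2, replicates = 40,
                          seed = 10)
  expect_lt(r2$combined_score[r2$name == "flat"],
            r2$combined_score[r2$name == "steep"])
  expect_equal(r2$rank[r2$name == "flat"], 1)
})
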