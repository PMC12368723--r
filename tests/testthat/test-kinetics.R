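# Kinetics engine: rate law, integration accuracy, conservation laws,
# and RT/CR extraction.

test_that("mass-action rates match hand evaluation", {
  mech <- canonical_mechanism()
  zero <- setNames(numeric(12), mech$species)
  expect_equal(unname(rate_vector(zero, mech, canonical_k(rep(1, 14)))),
               rep(0, 9))
  # r1 = k1 * roh * H+ = 0.5 * 2 * 3 = 3.0
  conc <- zero; conc["roh"] <- 2; conc["H"] <- 3
  k <- setNames(numeric(9), c("k1", "k2", "k3", "k4", "k5", "k6", "k7",
                              "k8f", "k8r"))
  k["k1"] <- 0.5
  expect_equal(unname(rate_vector(conc, mech, k)["r1"]), 3.0)
  # r2 = k2 * ren * H+ * Cl- = 0.1 * 1 * 2 * 0.5 = 0.1
  conc2 <- zero; conc2["ren"] <- 1; conc2["H"] <- 2; conc2["Cl"] <- 0.5
  k2 <- k; k2["k1"] <- 0; k2["k2"] <- 0.1
  expect_equal(unname(rate_vector(conc2, mech, k2)["r2"]), 0.1)
  expect_error(rate_vector(zero - 1, mech, k), "negative")
})

test_that("toy first-order decay matches the closed form", {
  toy <- toy_mechanism()
  cfg <- kinetics_config(t_end = 10, t_first = 0.1, grid_size = 50,
                         rtol = 1e-10, atol = 1e-14)
  traj <- simulate_mechanism(toy, c(A = 1), c(kA = 1), cfg)
  expect_lt(abs(traj$conc[nrow(traj$conc), "A"] - exp(-10)), 1e-8)
  expect_lt(max(abs(traj$conc[, "A"] - exp(-traj$time))), 1e-7)
  # mass balance A + B = 1
  expect_lt(max(abs(rowSums(traj$conc) - 1)), 1e-9)
})

test_that("no catalyst means no carbonylation product", {
  x <- as.numeric(reference_input())
  x[5] <- 0
  inp <- simulation_input(x, perturbed = TRUE)
  traj <- simulate_batch(inp, cfg = kinetics_config(grid_size = 80))
  expect_true(all(traj$conc[, "ibu"] == 0))
  expect_true(all(traj$conc[, c("pd2", "pd3", "pd4")] == 0))
})

test_that("Pd, aryl-backbone, and chlorine conservation hold on random inputs", {
  set.seed(101)
  X <- sample_inputs(sampling_config(n_samples = 10, seed = 101))
  for (i in seq_len(nrow(X))) {
    x <- as.numeric(X[i, ])
    traj <- simulate_batch(simulation_input(x), cfg = kinetics_config(grid_size = 100))
    cc <- traj$conc
    pd <- rowSums(cc[, c("pd1", "pd2", "pd3", "pd4")])
    expect_lt(max(abs(pd - x[5])) / x[5], 1e-6)
    aryl <- rowSums(cc[, c("roh", "ren", "rcl", "pd3", "pd4", "ibu")]) +
      2 * cc[, "ester"]
    expect_lt(max(abs(aryl - x[1])) / x[1], 1e-6)
    cl <- cc[, "Cl"] + cc[, "rcl"] + 2 * cc[, "pd1"] + cc[, "pd3"] + cc[, "pd4"]
    expect_lt(max(abs(cl - (x[2] + 2 * x[5]))) / (x[2] + 2 * x[5]), 1e-6)
    expect_true(all(cc >= 0))
  }
})

test_that("short-horizon trajectories agree with the fixed-step RK4 oracle", {
  x <- as.numeric(reference_input())
  t_out <- seq(5, 60, by = 5)
  traj <- simulate_mechanism(canonical_mechanism(), canonical_y0(x),
                             canonical_k(x), kinetics_config(),
                             times = c(0, t_out))
  oracle <- rk4_oracle(canonical_y0(x), canonical_k(x), t_out, dt = 1e-3)
  scale <- max(abs(oracle))
  expect_lt(max(abs(traj$conc[-1, colnames(oracle)] - oracle)) / scale, 1e-6)
})

test_that("halving solver tolerances barely moves RT and CR", {
  set.seed(7)
  X <- sample_inputs(sampling_config(n_samples = 20, seed = 77))
  cfg1 <- kinetics_config()
  cfg2 <- kinetics_config(rtol = cfg1$rtol / 2, atol = cfg1$atol / 2)
  for (i in seq_len(nrow(X))) {
    inp <- simulation_input(as.numeric(X[i, ]))
    m1 <- extract_metrics(simulate_batch(inp, cfg = cfg1), inp, cfg1)
    m2 <- extract_metrics(simulate_batch(inp, cfg = cfg2), inp, cfg2)
    expect_lt(abs(m1$rt_h - m2$rt_h) / m1$rt_h, 0.005)
    expect_lt(abs(m1$cr - m2$cr), 0.001)
  }
})

test_that("RT extraction matches the closed-form plateau crossing", {
  cfg <- kinetics_config()
  tt <- ibuopt:::time_grid(cfg)
  tau <- 3600
  make_traj <- function(cib) {
    structure(list(time = tt,
                   conc = matrix(cib, ncol = 1,
                                 dimnames = list(NULL, "ibu")),
                   species = "ibu"),
              class = "kin_trajectory")
  }
  # saturating exponential: theta = 0.99 crossing at tau * ln(100)
  m <- extract_metrics(make_traj(0.5 * (1 - exp(-tt / tau))), input = 1, cfg)
  expect_false(m$censored)
  expect_equal(m$rt_h, tau * log(100) / 3600, tolerance = 0.02)
  expect_equal(m$cr, 0.99 * 0.5, tolerance = 1e-3)
  # identically zero product: censored at the horizon
  m0 <- extract_metrics(make_traj(rep(0, length(tt))), input = 1, cfg)
  expect_true(m0$censored)
  expect_equal(m0$rt_h, cfg$t_end / 3600)
  expect_equal(m0$cr, 0)
  # plateau from t = 0: RT is the first grid time
  mp <- extract_metrics(make_traj(rep(0.4, length(tt))), input = 1, cfg)
  expect_equal(mp$rt_h, tt[1] / 3600)
  expect_equal(mp$cr, 0.4)
  expect_error(extract_metrics(make_traj(rep(0.4, length(tt))), input = 0, cfg),
               "positive")
})

test_that("simulation inputs are validated against bounds and positivity", {
  b <- input_bounds()
  expect_error(simulation_input(rep(1, 13)), "14")
  expect_error(simulation_input(b$min * 0.5), "bounds")
  x <- b$min * 2
  x[3] <- -x[3]
  expect_error(simulation_input(x, perturbed = TRUE), "positive")
  expect_s3_class(simulation_input(b$min * 0.5, perturbed = TRUE),
                  "simulation_input")
  expect_equal(as.numeric(reference_input()), b$min * 10)
})

test_that("trajectories export to tidy long format", {
  traj <- simulate_batch(reference_input(), cfg = kinetics_config(grid_size = 20))
  df <- trajectory_to_df(traj)
  expect_equal(nrow(df), 21 * 12)
  expect_named(df, c("time_s", "species", "concentration"))
  expect_equal(df$concentration[df$species == "ibu"],
               unname(traj$conc[, "ibu"]))
})
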