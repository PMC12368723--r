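# Independent oracles and shared fixtures for the test suite.

# ---- fixed-step RK4 integrator with a hand-written canonical RHS ------------
# Deliberately independent of the package's mechanism matrices: the nine
# reaction rates are spelled out term by term.

canonical_rhs_oracle <- function(y, k, co = 1.0) {
  r1 <- k[["k1"]] * y[["roh"]] * y[["H"]]
  r2 <- k[["k2"]] * y[["ren"]] * y[["H"]] * y[["Cl"]]
  r3 <- k[["k3"]] * y[["rcl"]] * y[["H2O"]]
  r4 <- k[["k4"]] * y[["pd1"]] * y[["H2O"]]^2
  r5 <- k[["k5"]] * y[["rcl"]] * y[["pd2"]]
  r6 <- k[["k6"]] * y[["pd3"]] * co
  r7 <- k[["k7"]] * y[["pd4"]] * y[["H2O"]]
  r8f <- k[["k8f"]] * y[["ibu"]] * y[["roh"]] * y[["H"]]
  r8r <- k[["k8r"]] * y[["ester"]] * y[["H2O"]] * y[["H"]]
  c(roh   = -r1 - r8f + r8r,
    ren   = r1 - r2 + r3,
    rcl   = r2 - r3 - r5,
    ibu   = r7 - r8f + r8r,
    ester = r8f - r8r,
    H     = -r2 + r3 + 2 * r4 + r7,
    Cl    = -r2 + r3 + 2 * r4 + r7,
    H2O   = r1 - r3 - r4 - r7 + r8f - r8r,
    pd1   = -r4,
    pd2   = r4 - r5 + r7,
    pd3   = r5 - r6,
    pd4   = r6 - r7)
}

# t_out must be (close to) multiples of dt
rk4_oracle <- function(y0, k, t_out, dt, co = 1.0) {
  y <- y0
  out <- matrix(NA_real_, length(t_out), length(y0),
                dimnames = list(NULL, names(y0)))
  target_steps <- round(t_out / dt)
  done <- 0L
  for (j in seq_along(t_out)) {
    while (done < target_steps[j]) {
      k1 <- canonical_rhs_oracle(y, k, co)
      k2 <- canonical_rhs_oracle(y + dt / 2 * k1, k, co)
      k3 <- canonical_rhs_oracle(y + dt / 2 * k2, k, co)
      k4 <- canonical_rhs_oracle(y + dt * k3, k, co)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      done <- done + 1L
    }
    out[j, ] <- y
  }
  out
}

canonical_y0 <- function(x) {
  c(roh = x[[1]], ren = 0, rcl = 0, ibu = 0, ester = 0,
    H = x[[3]], Cl = x[[2]], H2O = x[[4]],
    pd1 = x[[5]], pd2 = 0, pd3 = 0, pd4 = 0)
}

canonical_k <- function(x) {
  stats::setNames(as.numeric(x)[6:14],
                  c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8f", "k8r"))
}

# ---- brute-force Shapley oracle over all coalitions -------------------------
# Value function: cover-weighted conditional expectation through the tree
# (the same semantics TreeSHAP computes in closed form).

tree_expected_value <- function(td, x, S) {
  per_tree <- function(rows) {
    rec <- function(id) {
      row <- rows[rows$ID == id, ]
      if (row$Feature == "Leaf") return(row$Gain)
      if (row$Feature %in% S) {
        branch <- if (x[[row$Feature]] < row$Split) row$Yes else row$No
        return(rec(branch))
      }
      cy <- rows$Cover[rows$ID == row$Yes]
      cn <- rows$Cover[rows$ID == row$No]
      (cy * rec(row$Yes) + cn * rec(row$No)) / (cy + cn)
    }
    rec(rows$ID[rows$Node == 0])
  }
  sum(vapply(split(td, td$Tree), per_tree, 0))
}

brute_force_shapley <- function(booster, x, features) {
  td <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  p <- length(features)
  phi <- stats::setNames(numeric(p), features)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (i in seq_len(p)) {
    others <- features[-i]
    sub_o <- expand.grid(rep(list(c(FALSE, TRUE)), p - 1))
    for (r in seq_len(nrow(sub_o))) {
      S <- others[unlist(sub_o[r, ])]
      s <- length(S)
      wgt <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[i] <- phi[i] + wgt *
        (tree_expected_value(td, x, c(S, features[i])) -
         tree_expected_value(td, x, S))
    }
  }
  phi
}

# ---- shared fixtures (built once per suite) ---------------------------------

.fixtures <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- generate_dataset(sampling_config(n_samples = 400,
                                                     seed = 20260921L))
  }
  .fixtures$ds
}

fixture_models <- function() {
  if (is.null(.fixtures$models)) {
    df <- as.data.frame(fixture_dataset())
    hp <- hyperparameters(depth = 6, learning_rate = 0.15,
                          l2_leaf_reg = 3, iterations = 300)
    .fixtures$models <- list(
      rt = train_surrogate(df, "y1", hp, seed = 1),
      cr = train_surrogate(df, "y2", hp, seed = 1),
      cost = train_surrogate(df, "y3", hp, seed = 1))
  }
  .fixtures$models
}

# toy single-step mechanism A -> B with first-order rate kA * A
toy_mechanism <- function() {
  mechanism_spec(
    species = c("A", "B"),
    constant_species = NULL,
    rate_constants = c(kA = "1/s"),
    reactions = list(list(name = "decay", rate_constant = "kA",
                          orders = list(A = 1),
                          stoichiometry = list(A = -1, B = 1))))
}
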