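# Kinetics engine: design-variable bounds, stiff integration of the
# mass-action ODE system, and extraction of the process metrics RT / CR.

#' Design-variable bounds for the ibuprofen synthesis input space
#'
#' The 14 design variables are the five initial concentrations (substrate
#' alcohol `roh`, chloride, hydronium, water, catalyst precursor L2PdCl2)
#' and the nine rate constants k1..k7, k8f, k8r.  Each range spans two
#' orders of magnitude: the minimum is 0.1x and the maximum 10x the
#' reference value of the underlying reactor model.
#'
#' @return A data frame with columns `variable` (x1..x14), `role`,
#'   `min`, `max`, `unit`.
#' @export
input_bounds <- function() {
  data.frame(
    variable = paste0("x", 1:14),
    role = c("c0(roh)", "c0(Cl-)", "c0(H+)", "c0(H2O)", "c0(L2PdCl2)",
             "k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8f", "k8r"),
    min = c(0.01, 0.02, 0.02, 0.3, 0.00121,
            7.45e-4, 1.25e-3, 1.60e-4, 1.5e-2, 0.159, 2.14e-2, 9.52e-2,
            5e-2, 1e-3),
    max = c(1.0, 2.0, 2.0, 30, 0.121,
            7.45e-2, 1.25e-1, 1.60e-2, 1.5, 15.9, 2.14, 9.52, 5, 1e-1),
    unit = c(rep("mol/m^3", 5),
             "m^3/(s*mol)", "m^6/(s*mol^2)", "m^3/(s*mol)", "m^6/(s*mol^2)",
             "m^3/(s*mol)", "m^3/(s*mol)", "m^3/(s*mol)",
             "m^6/(s*mol^2)", "m^6/(s*mol^2)"),
    stringsAsFactors = FALSE
  )
}

#' Reference design point (10x the lower bounds)
#'
#' The bounds span 0.1x to 10x the reactor model's reference values, so
#' the reference point sits at 10x the minima.  It is used to hold
#' non-decision variables fixed during optimization and as the anchor for
#' short-horizon integrator validation.
#'
#' @return Named numeric vector x1..x14.
#' @export
reference_input <- function() {
  b <- input_bounds()
  simulation_input(setNames(b$min * 10, b$variable))
}

#' Construct a validated simulation input vector
#'
#' @param x Numeric vector of length 14 (named x1..x14 or positional):
#'   initial concentrations x1..x5 in mol/m^3 and rate constants x6..x14.
#' @param perturbed If `TRUE`, values may lie outside the sampling bounds
#'   or on the zero boundary (used for perturbation and limiting-case
#'   studies); otherwise all components must be strictly positive and
#'   within bounds.
#' @return Named numeric vector of class `simulation_input`.
#' @export
simulation_input <- function(x, perturbed = FALSE) {
  vars <- paste0("x", 1:14)
  if (length(x) != 14) stop("simulation input must have 14 components")
  if (!is.null(names(x))) {
    if (!setequal(names(x), vars)) stop("input names must be x1..x14")
    x <- x[vars]
  } else names(x) <- vars
  x <- as.numeric(x)
  names(x) <- vars
  if (any(!is.finite(x)) || any(x < 0) || (!perturbed && any(x == 0)))
    stop("all simulation input components must be strictly positive")
  if (!perturbed) {
    b <- input_bounds()
    # minor tolerance for round-tripped values
    out <- x < b$min * (1 - 1e-9) | x > b$max * (1 + 1e-9)
    if (any(out))
      stop("input outside sampling bounds (use perturbed = TRUE to allow): ",
           paste(vars[out], collapse = ", "))
  }
  structure(x, class = "simulation_input", perturbed = perturbed)
}

#' Integration and metric-extraction settings for the kinetics engine
#'
#' @param t_end Batch horizon in seconds (default 259200 s = 72 h, the
#'   upper bound of industrially admissible reaction times).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param grid_size Number of output grid points; the grid is `0` followed
#'   by `grid_size` log-spaced times from `t_first` to `t_end`.
#' @param t_first First positive output time (s).
#' @param theta Plateau fraction: RT is the earliest time at which the
#'   product reaches `theta` times its terminal concentration.
#' @param eps_ibu Minimum terminal product concentration (mol/m^3) below
#'   which the run is censored (RT set to the horizon).
#' @param clip_tol Concentrations below this value are clipped to zero on
#'   output (guard against tiny negative solver excursions).
#' @return A list of class `kinetics_config`.
#' @export
kinetics_config <- function(t_end = 259200, rtol = 1e-8, atol = 1e-12,
                            grid_size = 300, t_first = 1, theta = 0.99,
                            eps_ibu = 1e-9, clip_tol = 1e-12) {
  stopifnot(t_end > 0, theta > 0, theta < 1, grid_size >= 2,
            t_first > 0, t_first < t_end)
  structure(list(t_end = t_end, rtol = rtol, atol = atol,
                 grid_size = grid_size, t_first = t_first, theta = theta,
                 eps_ibu = eps_ibu, clip_tol = clip_tol),
            class = "kinetics_config")
}

time_grid <- function(cfg) {
  c(0, exp(seq(log(cfg$t_first), log(cfg$t_end), length.out = cfg$grid_size)))
}

#' Per-reaction mass-action rates at a given composition
#'
#' rate_j = k_j * prod_s conc_s^order_js, with constant-concentration
#' species taken from the mechanism.
#'
#' @param conc Named nonnegative concentrations (mol/m^3) for all
#'   integrated species of `mech`.
#' @param mech A `mechanism_spec`.
#' @param k Named rate constants covering `mech`'s rate-constant
#'   references, or a `simulation_input` (whose x6..x14 map to
#'   k1..k7, k8f, k8r).
#' @return Named per-reaction rates, mol/(m^3 s).
#' @export
rate_vector <- function(conc, mech, k) {
  stopifnot(inherits(mech, "mechanism_spec"))
  if (inherits(k, "simulation_input")) k <- rate_constants_from_input(k)
  if (any(conc < 0)) stop("negative concentration passed to rate_vector")
  conc <- conc[mech$species]
  if (any(is.na(conc))) stop("concentration vector must cover all integrated species")
  full <- c(conc, mech$constant_species)
  kj <- k[mech$rate_constant_ref]
  if (any(is.na(kj))) stop("missing rate constants: ",
                           paste(setdiff(mech$rate_constant_ref, names(k)), collapse = ", "))
  # log-space product handles order-0 species; exp(-745) underflows to 0
  lc <- ifelse(full > 0, log(full), -745)
  rates <- as.vector(kj * exp(mech$orders %*% lc))
  setNames(rates, mech$reaction_names)
}

# map the canonical input vector onto rate-constant names
rate_constants_from_input <- function(input) {
  setNames(as.numeric(input)[6:14],
           c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8f", "k8r"))
}

# initial state of the canonical batch: substrate, ions, water, precursor
initial_state_from_input <- function(input, mech) {
  y0 <- setNames(numeric(length(mech$species)), mech$species)
  x <- as.numeric(input)
  y0["roh"] <- x[1]; y0["Cl"] <- x[2]; y0["H"] <- x[3]
  y0["H2O"] <- x[4]; y0["pd1"] <- x[5]
  y0
}

# pack the mechanism + rate constants into the static C parameter block
pack_parms <- function(mech, k) {
  kj <- unname(k[mech$rate_constant_ref])
  p <- c(length(mech$species),
         length(mech$species) + length(mech$constant_species),
         nrow(mech$orders),
         unname(mech$constant_species),
         kj,
         as.vector(t(mech$orders)),
         as.vector(t(mech$stoich)))
  if (length(p) > 4096) stop("mechanism too large for the compiled engine")
  c(p, numeric(4096 - length(p)))
}

#' Integrate a mass-action mechanism from a given initial state
#'
#' Stiff-capable adaptive integration (lsoda, compiled right-hand side)
#' of dc/dt = S' r(c) with dense output on a log-spaced grid.
#'
#' @param mech A `mechanism_spec`.
#' @param conc0 Named initial concentrations for the integrated species
#'   (missing species start at 0).
#' @param k Named rate constants.
#' @param cfg A `kinetics_config`.
#' @param times Optional explicit output grid (seconds, strictly
#'   increasing, starting at 0) overriding the configured log-spaced
#'   grid; useful for validation against fixed-step references.
#' @return A `kin_trajectory`: list with `time` (s) and `conc`
#'   (time x species matrix, mol/m^3, clipped at zero below `clip_tol`).
#' @export
simulate_mechanism <- function(mech, conc0, k, cfg = kinetics_config(),
                               times = NULL) {
  stopifnot(inherits(mech, "mechanism_spec"), inherits(cfg, "kinetics_config"))
  y0 <- setNames(numeric(length(mech$species)), mech$species)
  y0[names(conc0)] <- conc0
  if (is.null(times)) times <- time_grid(cfg)
  stopifnot(times[1] == 0, all(diff(times) > 0))
  out <- tryCatch(
    deSolve::ode(y = y0, times = times, func = "massaction_derivs",
                 parms = pack_parms(mech, k), dllname = "ibuopt",
                 initfunc = "massaction_init", method = "lsoda",
                 rtol = cfg$rtol, atol = cfg$atol, maxsteps = 50000),
    warning = function(w) stop("integrator failure: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (nrow(out) < length(times))
    stop("integrator failure: step-size collapse before t_end")
  conc <- out[, mech$species, drop = FALSE]
  conc[conc < cfg$clip_tol] <- 0
  structure(list(time = times, conc = conc, species = mech$species),
            class = "kin_trajectory")
}

#' Simulate the canonical ibuprofen batch for one design point
#'
#' Initial condition: roh = x1, Cl- = x2, H+ = x3, H2O = x4, pd1 = x5,
#' all intermediates and products 0, CO held constant; rate constants
#' k1..k7, k8f, k8r = x6..x14.
#'
#' @param input A `simulation_input` (or coercible numeric vector).
#' @param mech A `mechanism_spec`; defaults to the shipped canonical
#'   mechanism.
#' @param cfg A `kinetics_config`.
#' @return A `kin_trajectory`.
#' @export
simulate_batch <- function(input, mech = NULL, cfg = kinetics_config()) {
  if (!inherits(input, "simulation_input"))
    input <- simulation_input(input, perturbed = TRUE)
  if (is.null(mech)) mech <- canonical_mechanism()
  tryCatch(
    simulate_mechanism(mech,
                       conc0 = initial_state_from_input(input, mech),
                       k = rate_constants_from_input(input),
                       cfg = cfg),
    error = function(e) {
      e$simulation_input <- as.numeric(input)
      stop(e)
    })
}

# cache the parsed canonical mechanism per session
.mech_cache <- new.env(parent = emptyenv())

#' The canonical ibuprofen mechanism shipped with the package
#' @return A `mechanism_spec` (parsed once and cached).
#' @export
canonical_mechanism <- function() {
  if (is.null(.mech_cache$mech))
    .mech_cache$mech <- load_mechanism(default_mechanism_path())
  .mech_cache$mech
}

#' Extract reaction time and conversion rate from a trajectory
#'
#' RT is the earliest time at which the product concentration reaches
#' `theta` (default 0.99) of its terminal value, located by linear
#' interpolation between grid points and reported in hours.  CR is the
#' product concentration at RT divided by the initial substrate
#' concentration x1.  Runs whose terminal product concentration falls
#' below `eps_ibu` are censored: RT is set to the horizon.
#'
#' @param traj A `kin_trajectory` covering `[0, t_end]`.
#' @param input The `simulation_input` that produced it (x1 is the
#'   initial substrate concentration), or a plain numeric x1.
#' @param cfg The `kinetics_config` used for the simulation.
#' @param product Product species name.
#' @return List with `rt_h`, `cr`, `censored`.
#' @export
extract_metrics <- function(traj, input, cfg = kinetics_config(),
                            product = "ibu") {
  stopifnot(inherits(traj, "kin_trajectory"))
  x1 <- if (length(input) > 1) as.numeric(input)[1] else as.numeric(input)
  if (!is.finite(x1) || x1 <= 0) stop("initial substrate concentration must be positive")
  cib <- traj$conc[, product]
  tt <- traj$time
  c_end <- cib[length(cib)]
  if (c_end < cfg$eps_ibu)
    return(list(rt_h = tt[length(tt)] / 3600, cr = c_end / x1, censored = TRUE))
  target <- cfg$theta * c_end
  i <- which(cib >= target)[1]
  if (i == 1L) {
    rt <- tt[1]
    cr <- cib[1] / x1
  } else {
    # linear interpolation of the crossing between grid points
    t0 <- tt[i - 1]; t1 <- tt[i]; c0 <- cib[i - 1]; c1 <- cib[i]
    rt <- if (c1 > c0) t0 + (target - c0) / (c1 - c0) * (t1 - t0) else t1
    cr <- target / x1
  }
  list(rt_h = rt / 3600, cr = min(max(cr, 0), 1), censored = FALSE)
}

#' Export a trajectory as a tidy data frame
#'
#' @param traj A `kin_trajectory`.
#' @param path Optional CSV path; written when non-`NULL`.
#' @return Data frame with columns `time_s`, `species`, `concentration`.
#' @export
trajectory_to_df <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "kin_trajectory"))
  df <- data.frame(
    time_s = rep(traj$time, times = length(traj$species)),
    species = rep(traj$species, each = length(traj$time)),
    concentration = as.vector(traj$conc),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
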