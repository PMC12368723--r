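# Snow ablation optimizer (SAO) for bound-constrained minimization, and
# the surrogate hyperparameter tuning built on it.

#' Define a box search space
#'
#' @param name Character vector of dimension names.
#' @param lower,upper Numeric bounds, `lower < upper`.
#' @param kind `"continuous"` or `"integer"` per dimension.  Integer
#'   dimensions are kept continuous internally and rounded only when the
#'   objective is evaluated.
#' @return Data frame of class `search_space`.
#' @export
search_space <- function(name, lower, upper,
                         kind = rep("continuous", length(name))) {
  stopifnot(length(name) == length(lower), length(lower) == length(upper),
            all(lower < upper), all(kind %in% c("continuous", "integer")))
  structure(data.frame(name = name, lower = lower, upper = upper,
                       kind = kind, stringsAsFactors = FALSE),
            class = c("search_space", "data.frame"))
}

#' SAO settings
#'
#' @param n_pop Population size N (default 15).
#' @param n_iter Iteration budget T (default 20); the total number of
#'   objective evaluations is at most `n_pop * (n_iter + 1)`.
#' @param ddf_range Range of the degree-day factor controlling the melt
#'   (exploitation step-size) schedule.
#' @param seed Optional integer seed; the run is deterministic given it.
#' @return A list of class `sao_config`.
#' @export
sao_config <- function(n_pop = 15, n_iter = 20, ddf_range = c(0.35, 0.6),
                       seed = NULL) {
  stopifnot(n_pop >= 2, n_iter >= 0, length(ddf_range) == 2,
            ddf_range[1] <= ddf_range[2])
  structure(list(n_pop = as.integer(n_pop), n_iter = as.integer(n_iter),
                 ddf_range = ddf_range, seed = seed),
            class = "sao_config")
}

# round integer dimensions for evaluation; internal state stays continuous
round_integers <- function(z, space) {
  ints <- space$kind == "integer"
  z[ints] <- round(z[ints])
  z
}

#' Run the snow ablation optimizer
#'
#' Population-based bound-constrained minimization.  The melt schedule
#' couples a decaying temperature \eqn{\Theta(t) = e^{-t/T}} with a rising
#' degree-day factor \eqn{DDF(t) = 0.35 + 0.25 (e^{t/T} - 1)/(e - 1)} into
#' a melt factor \eqn{M(t) = DDF(t)\,\Theta(t)}.  Each iteration the
#' population is resampled into an exploration subset (fraction decaying
#' linearly from 1 to 0.5) that moves around an elite solution drawn from
#' the top half, and an exploitation subset attracted to the melt-scaled
#' global best; both moves add Gaussian-perturbed pulls toward the best
#' solution and the population centroid.  Out-of-bounds coordinates are
#' clipped.  Candidates with non-finite objective are discarded (the
#' individual keeps its previous position).
#'
#' @param objective Function mapping a named position vector to a scalar
#'   to minimize.
#' @param space A `search_space`.
#' @param cfg A `sao_config`.
#' @return List with `best_par` (named, integer dims rounded),
#'   `best_value`, `trace` (per-iteration best value and subpopulation
#'   sizes), `n_evals`.
#' @export
run_sao <- function(objective, space, cfg = sao_config()) {
  stopifnot(inherits(space, "search_space"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  d <- nrow(space)
  N <- cfg$n_pop
  Tmax <- cfg$n_iter
  lo <- space$lower; hi <- space$upper
  n_evals <- 0L

  eval_pos <- function(z) {
    n_evals <<- n_evals + 1L
    v <- tryCatch(objective(setNames(round_integers(z, space), space$name)),
                  error = function(e) NaN)
    if (!is.numeric(v) || length(v) != 1) NaN else as.numeric(v)
  }

  Z <- sapply(seq_len(d), function(j) runif(N, lo[j], hi[j]))
  Z <- matrix(Z, N, d)
  f <- apply(Z, 1, eval_pos)
  if (all(!is.finite(f))) stop("objective non-finite on the entire initial population")
  if (any(!is.finite(f)))
    warning(sum(!is.finite(f)), " initial candidates had non-finite objective")
  f[!is.finite(f)] <- Inf

  ib <- which.min(f)
  best_z <- Z[ib, ]; best_f <- f[ib]
  trace <- data.frame(iter = 0L, best_value = best_f,
                      n_explore = N, n_exploit = 0L)

  if (Tmax > 0) {
    ddf_lo <- cfg$ddf_range[1]
    ddf_span <- cfg$ddf_range[2] - cfg$ddf_range[1]
    for (t in seq_len(Tmax)) {
      theta <- exp(-t / Tmax)
      ddf <- ddf_lo + ddf_span * (exp(t / Tmax) - 1) / (exp(1) - 1)
      M <- ddf * theta
      frac_explore <- 1 - 0.5 * t / Tmax
      n_exp <- round(frac_explore * N)
      explorers <- sample.int(N) <= n_exp   # membership resampled each iteration
      centroid <- colMeans(Z)
      top_half <- order(f)[seq_len(max(1, floor(N / 2)))]
      for (i in seq_len(N)) {
        B <- rnorm(d)
        r <- runif(1)
        pull <- B * (r * (best_z - Z[i, ]) + (1 - r) * (centroid - Z[i, ]))
        cand <- if (explorers[i]) {
          elite <- Z[sample(top_half, 1), ]
          elite + pull
        } else {
          M * best_z + pull
        }
        cand <- pmin(pmax(cand, lo), hi)
        fc <- eval_pos(cand)
        if (is.finite(fc)) {
          Z[i, ] <- cand
          f[i] <- fc
          if (fc < best_f) { best_f <- fc; best_z <- cand }
        }
      }
      trace <- rbind(trace, data.frame(iter = t, best_value = best_f,
                                       n_explore = n_exp,
                                       n_exploit = N - n_exp))
    }
  }
  list(best_par = setNames(round_integers(best_z, space), space$name),
       best_value = best_f, trace = trace, n_evals = n_evals)
}

#' Pure random-search baseline on the same box
#'
#' Comparison baseline for the metaheuristic: uniform draws over the box,
#' same evaluation budget semantics.
#'
#' @inheritParams run_sao
#' @param n_evals Total evaluation budget.
#' @param seed Optional integer seed.
#' @return List with `best_par`, `best_value`, `n_evals`.
#' @export
run_random_search <- function(objective, space, n_evals, seed = NULL) {
  stopifnot(inherits(space, "search_space"), n_evals >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(space)
  best_f <- Inf; best_z <- NULL
  for (i in seq_len(n_evals)) {
    z <- runif(d, space$lower, space$upper)
    v <- tryCatch(objective(setNames(round_integers(z, space), space$name)),
                  error = function(e) NaN)
    if (is.finite(v) && v < best_f) { best_f <- v; best_z <- z }
  }
  if (is.null(best_z)) stop("objective non-finite on every candidate")
  list(best_par = setNames(round_integers(best_z, space), space$name),
       best_value = best_f, n_evals = n_evals)
}

#' Default hyperparameter search space for the surrogates
#'
#' Tree depth 4..10, learning rate 0.01..0.3, L2 leaf regularization
#' 0..10, boosting iterations 100..1000.
#'
#' @return A `search_space`.
#' @export
default_hyperparameter_space <- function() {
  search_space(
    name = c("depth", "learning_rate", "l2_leaf_reg", "iterations"),
    lower = c(4, 0.01, 0, 100),
    upper = c(10, 0.3, 10, 1000),
    kind = c("integer", "continuous", "continuous", "integer"))
}

#' Tune surrogate hyperparameters with SAO
#'
#' The objective is the validation-split mean squared error of a
#' surrogate trained at the candidate hyperparameters; training failures
#' discard the candidate.
#'
#' @param train,validation Flat data frames (x1..x14 plus the outcome).
#' @param outcome Outcome column: `"y1"` (RT), `"y2"` (CR), `"y3"` (Cost).
#' @param space Hyperparameter `search_space`.
#' @param cfg A `sao_config`.
#' @param train_seed Seed fixed across candidate trainings.
#' @return List with `hyperparameters`, `best_value` (validation MSE),
#'   `trace`, `n_evals`.
#' @export
tune_hyperparameters <- function(train, validation, outcome = "y1",
                                 space = default_hyperparameter_space(),
                                 cfg = sao_config(), train_seed = 0L) {
  stopifnot(nrow(train) > 0, nrow(validation) > 0)
  yv <- validation[[outcome]]
  objective <- function(par) {
    hp <- hyperparameters(depth = par[["depth"]],
                          learning_rate = par[["learning_rate"]],
                          l2_leaf_reg = par[["l2_leaf_reg"]],
                          iterations = par[["iterations"]])
    model <- train_surrogate(train, outcome = outcome, hp = hp,
                             seed = train_seed)
    mean((yv - predict(model, validation))^2)
  }
  res <- run_sao(objective, space, cfg)
  hp <- hyperparameters(depth = res$best_par[["depth"]],
                        learning_rate = res$best_par[["learning_rate"]],
                        l2_leaf_reg = res$best_par[["l2_leaf_reg"]],
                        iterations = res$best_par[["iterations"]])
  list(hyperparameters = hp, best_value = res$best_value,
       trace = res$trace, n_evals = res$n_evals)
}
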