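# Monte Carlo perturbation analysis: input perturbation, prediction
# uncertainty reports, RBF sensitivity surfaces, and strategy robustness.

#' Perturbation settings
#'
#' Perturbations are Gaussian and proportional: each input receives
#' `delta_j ~ N(0, (w_j * sigma * |x_j|)^2)`, i.e. `sigma * |x|` is the
#' standard deviation.
#'
#' @param sigmas Perturbation levels (default 0.1, 0.2, 0.3, 0.5).
#' @param replicates Monte Carlo replicates per sample (default 500).
#' @param w Per-feature weight vector (default all 1; recycled to 14).
#' @param clip Clip perturbed inputs to the sampling bounds (surrogates
#'   are untrained outside them); disable for distributional checks.
#' @param seed Integer seed.
#' @return A list of class `perturbation_config`.
#' @export
perturbation_config <- function(sigmas = c(0.1, 0.2, 0.3, 0.5),
                                replicates = 500, w = 1, clip = TRUE,
                                seed = 1L) {
  stopifnot(all(sigmas >= 0), replicates >= 1, all(w >= 0))
  structure(list(sigmas = sigmas, replicates = as.integer(replicates),
                 w = rep_len(w, 14), clip = clip, seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Perturb a design vector
#'
#' @param x Design vector (length 14).
#' @param sigma Perturbation level (>= 0).
#' @param w Per-feature weights (recycled).
#' @param clip Clip the result to the sampling bounds.
#' @param seed Optional seed.
#' @param bounds Bounds used when clipping.
#' @return Perturbed numeric vector named x1..x14.
#' @export
perturb_input <- function(x, sigma, w = 1, clip = TRUE, seed = NULL,
                          bounds = input_bounds()) {
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  xv <- as.numeric(x)
  w <- rep_len(w, length(xv))
  out <- xv + rnorm(length(xv), 0, w * sigma * abs(xv))
  if (clip) out <- pmin(pmax(out, bounds$min), bounds$max)
  setNames(out, paste0("x", seq_along(xv)))
}

# replicate matrix of perturbed inputs for one sample (vectorized draws)
perturb_matrix <- function(x, sigma, w, n, clip, bounds) {
  xv <- as.numeric(x)
  d <- length(xv)
  P <- matrix(rnorm(n * d, mean = rep(xv, each = n),
                    sd = rep(w * sigma * abs(xv), each = n)), n, d)
  if (clip) P <- pmin(pmax(P, matrix(bounds$min, n, d, byrow = TRUE)),
                      matrix(bounds$max, n, d, byrow = TRUE))
  colnames(P) <- paste0("x", seq_len(d))
  as.data.frame(P)
}

#' Monte Carlo prediction uncertainty under input perturbation
#'
#' For every sample and perturbation level, all 14 inputs are perturbed
#' simultaneously and the three surrogates are re-evaluated
#' `cfg$replicates` times.  Uncertainty is summarized by the percentile
#' (2.5, 97.5) confidence interval and the relative uncertainty
#' `100 * CI width / |baseline|`; baselines below 1e-9 in magnitude
#' yield a missing relative uncertainty (the absolute width is kept).
#'
#' @param models Named list of `surrogate_model`s `rt`, `cr`, `cost`.
#' @param samples Data frame of design vectors (columns x1..x14).
#' @param cfg A `perturbation_config`.
#' @return Data frame of class `uncertainty_report`: one row per sample
#'   x sigma x metric with baseline, replicate mean, CI bounds, CI
#'   width, and relative uncertainty (%).
#' @export
mc_uncertainty <- function(models, samples, cfg = perturbation_config()) {
  stopifnot(all(c("rt", "cr", "cost") %in% names(models)))
  samples <- as.data.frame(samples)
  set.seed(cfg$seed)
  bounds <- input_bounds()
  metric_names <- c("rt", "cr", "cost")
  out <- list()
  for (s in seq_len(nrow(samples))) {
    x <- as.numeric(samples[s, paste0("x", 1:14)])
    base <- vapply(metric_names, function(m)
      model_predict(models[[m]], samples[s, , drop = FALSE]), 0)
    for (sg in cfg$sigmas) {
      P <- perturb_matrix(x, sg, cfg$w, cfg$replicates, cfg$clip, bounds)
      for (m in metric_names) {
        pred <- model_predict(models[[m]], P)
        ci <- unname(quantile(pred, c(0.025, 0.975), type = 7))
        width <- ci[2] - ci[1]
        rel <- if (abs(base[[m]]) < 1e-9) NA_real_
               else 100 * width / abs(base[[m]])
        out[[length(out) + 1L]] <- data.frame(
          sample = s, sigma = sg, metric = m,
          baseline = base[[m]], mean = mean(pred),
          ci_lower = ci[1], ci_upper = ci[2],
          ci_width = width, rel_uncertainty = rel)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("uncertainty_report", "data.frame")
  res
}

# thin-plate-spline RBF interpolation phi(r) = r^2 log r, exact at nodes
tps_interpolate <- function(xy, z, xy_new) {
  phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  n <- nrow(xy)
  K <- phi(as.matrix(dist(xy)))
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, numeric(3))
  coefs <- solve(A, rhs)
  w <- coefs[seq_len(n)]
  a <- coefs[n + 1:3]
  D <- sqrt(outer(xy_new[, 1], xy[, 1], "-")^2 +
            outer(xy_new[, 2], xy[, 2], "-")^2)
  as.vector(phi(D) %*% w + a[1] + a[2] * xy_new[, 1] + a[3] * xy_new[, 2])
}

#' RT sensitivity surface over the (x5, x3) plane
#'
#' On a coarse node grid within the sampling bounds, the relative RT
#' uncertainty at perturbation level `sigma` is computed around each
#' node (the remaining inputs sit at the reference point); a thin-plate
#' spline then interpolates the field onto a dense grid.  The
#' interpolant reproduces the node values exactly.
#'
#' @param models Named list of surrogates (`rt` is used).
#' @param grid List with numeric vectors `x5` and `x3` of node
#'   coordinates (at least a 2 x 2 grid).
#' @param sigma Perturbation level.
#' @param cfg A `perturbation_config` (its `sigmas` are ignored).
#' @param dense_n Dense-grid resolution per axis.
#' @param features Length-2 character vector of the two swept inputs.
#' @return List with `nodes` (data frame of node coordinates and values)
#'   and `dense` (data frame of interpolated coordinates and values).
#' @export
sensitivity_surface <- function(models, grid, sigma = 0.3,
                                cfg = perturbation_config(), dense_n = 50,
                                features = c("x5", "x3")) {
  f1 <- grid[[features[1]]]; f2 <- grid[[features[2]]]
  if (length(f1) < 2 || length(f2) < 2)
    stop("degenerate grid: need at least 2 nodes per axis")
  nodes <- expand.grid(a = f1, b = f2, KEEP.OUT.ATTRS = FALSE)
  names(nodes) <- features
  ref <- as.numeric(reference_input())
  bounds <- input_bounds()
  set.seed(cfg$seed)
  vals <- vapply(seq_len(nrow(nodes)), function(i) {
    x <- setNames(ref, paste0("x", 1:14))
    x[features] <- as.numeric(nodes[i, ])
    base <- model_predict(models$rt, as.data.frame(as.list(x)))
    P <- perturb_matrix(x, sigma, cfg$w, cfg$replicates, cfg$clip, bounds)
    pred <- model_predict(models$rt, P)
    ci <- unname(quantile(pred, c(0.025, 0.975), type = 7))
    if (abs(base) < 1e-9) NA_real_ else 100 * (ci[2] - ci[1]) / abs(base)
  }, 0)
  nodes$value <- vals
  # scale coordinates to [0, 1] for a well-conditioned TPS system
  sc <- function(v, f) (v - min(grid[[f]])) / (max(grid[[f]]) - min(grid[[f]]))
  xy <- cbind(sc(nodes[[features[1]]], features[1]),
              sc(nodes[[features[2]]], features[2]))
  d1 <- seq(min(f1), max(f1), length.out = dense_n)
  d2 <- seq(min(f2), max(f2), length.out = dense_n)
  dense <- expand.grid(a = d1, b = d2, KEEP.OUT.ATTRS = FALSE)
  names(dense) <- features
  xy_new <- cbind(sc(dense[[features[1]]], features[1]),
                  sc(dense[[features[2]]], features[2]))
  dense$value <- tps_interpolate(xy, vals, xy_new)
  list(nodes = nodes, dense = dense)
}

#' Robustness assessment of operating strategies
#'
#' Each strategy is perturbed `replicates` times at level `sigma`; for
#' every metric the relative mean shift (%) and coefficient of variation
#' (%) are computed, and the combined score is the mean over the three
#' metrics of `(relative mean shift + CV) / 2`.  Lower scores indicate
#' more robust strategies; the returned table is augmented with the
#' rank (1 = most robust).
#'
#' @param strategies Data frame from [select_strategies()] (columns
#'   `name` and the decision variables), or any data frame with a `name`
#'   column plus x-columns; non-decision inputs are taken from `fixed`.
#' @param models Named list of surrogates `rt`, `cr`, `cost`.
#' @param sigma Perturbation level (default 0.2).
#' @param replicates Replicates per strategy (default 30).
#' @param w Per-feature weights.
#' @param seed Integer seed.
#' @param fixed Full design vector for non-decision variables.
#' @return Data frame of class `robustness_table`: per strategy and
#'   metric shifts/CVs, the combined score, and the rank.
#' @export
assess_robustness <- function(strategies, models, sigma = 0.2,
                              replicates = 30, w = 1, seed = 1L,
                              fixed = reference_input()) {
  stopifnot(all(c("rt", "cr", "cost") %in% names(models)))
  bounds <- input_bounds()
  xcols <- intersect(paste0("x", 1:14), names(strategies))
  metric_names <- c("rt", "cr", "cost")
  rows <- lapply(seq_len(nrow(strategies)), function(i) {
    # common random numbers: every strategy sees the same draws, so
    # identical strategies score identically and comparisons are paired
    set.seed(seed)
    x <- setNames(as.numeric(fixed), paste0("x", 1:14))
    x[xcols] <- as.numeric(strategies[i, xcols])
    xdf <- as.data.frame(as.list(x))
    P <- perturb_matrix(x, sigma, rep_len(w, 14), replicates, TRUE, bounds)
    res <- data.frame(name = strategies$name[i])
    scores <- numeric(0)
    for (m in metric_names) {
      base <- model_predict(models[[m]], xdf)
      pred <- model_predict(models[[m]], P)
      shift <- if (abs(base) < 1e-9) NA_real_
               else 100 * abs(mean(pred) - base) / abs(base)
      cv <- if (abs(mean(pred)) < 1e-9) NA_real_
            else 100 * sd(pred) / abs(mean(pred))
      res[[paste0(m, "_shift_pct")]] <- shift
      res[[paste0(m, "_cv_pct")]] <- cv
      scores <- c(scores, (shift + cv) / 2)
    }
    res$combined_score <- mean(scores)
    res
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(out$combined_score, ties.method = "first")
  class(out) <- c("robustness_table", "data.frame")
  out
}
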