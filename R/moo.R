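# Constrained NSGA-II over surrogate-predicted (RT, CR, Cost):
# nondominated sorting, crowding distance, SBX/polynomial variation,
# Deb's feasibility rule, Pareto front, and the four named strategies.

#' Fast nondominated sort
#'
#' @param points Numeric matrix (n x m) of objective vectors, all
#'   minimized.
#' @return List of integer vectors: front 1 is the nondominated set,
#'   each later front is nondominated once earlier fronts are removed.
#' @export
fast_nondominated_sort <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1)
  # D[i, j] = TRUE when i dominates j (vectorized pairwise comparison)
  le_all <- matrix(TRUE, n, n)
  lt_any <- matrix(FALSE, n, n)
  for (m in seq_len(ncol(points))) {
    v <- points[, m]
    le_all <- le_all & outer(v, v, "<=")
    lt_any <- lt_any | outer(v, v, "<")
  }
  D <- le_all & lt_any
  ncount <- colSums(D)
  fronts <- list()
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    current <- which(remaining & ncount == 0L)
    fronts[[length(fronts) + 1L]] <- current
    remaining[current] <- FALSE
    ncount <- ncount - colSums(D[current, , drop = FALSE])
  }
  fronts
}

#' Crowding distance of a front
#'
#' Per-objective boundary points receive infinite distance; interior
#' points sum the normalized gaps between their neighbors over the
#' objectives.  Fronts of size <= 2 are all infinite.  Interior points
#' whose full objective vector duplicates another member get distance 0:
#' they add no diversity to the front.
#'
#' @param front Numeric matrix (n x m) of objective vectors belonging to
#'   one front.
#' @return Numeric vector of distances.
#' @export
crowding_distance <- function(front) {
  front <- as.matrix(front)
  n <- nrow(front)
  if (n <= 2) return(rep(Inf, n))
  dist <- numeric(n)
  for (m in seq_len(ncol(front))) {
    v <- front[, m]
    ord <- order(v)
    rng <- v[ord[n]] - v[ord[1]]
    dist[ord[c(1, n)]] <- Inf
    if (rng > 0)
      dist[ord[2:(n - 1)]] <- dist[ord[2:(n - 1)]] +
        (v[ord[3:n]] - v[ord[1:(n - 2)]]) / rng
  }
  key <- apply(front, 1, paste, collapse = "\r")
  dup <- key %in% key[duplicated(key)]
  dist[dup & is.finite(dist)] <- 0
  dist
}

#' Define the surrogate-based optimization problem
#'
#' Objectives: minimize RT (h), maximize CR, minimize Cost, all predicted
#' by the trained surrogates.  Constraints (industrial admissibility):
#' RT in \[0.5, 72\] h, CR in \[0.85, 0.98\], Cost <= 800 units.
#'
#' @param surrogates Named list with `surrogate_model`s `rt`, `cr`,
#'   `cost`.
#' @param decision_vars Design variables searched over (default x3, x5,
#'   x6: hydronium concentration, catalyst precursor concentration, and
#'   the dehydration rate constant); the remaining variables are fixed at
#'   `fixed`.
#' @param fixed Full design vector supplying the non-decision variables
#'   (default: the reference point, 10x the lower bounds).
#' @param bounds Bounds data frame restricted to the sampling box.
#' @param constraints List with `rt` (length-2 range, h), `cr` (length-2
#'   range, fraction), `cost_max` (scalar).
#' @return A list of class `moo_problem`.
#' @export
moo_problem <- function(surrogates,
                        decision_vars = c("x3", "x5", "x6"),
                        fixed = reference_input(),
                        bounds = input_bounds(),
                        constraints = list(rt = c(0.5, 72),
                                           cr = c(0.85, 0.98),
                                           cost_max = 800)) {
  stopifnot(all(c("rt", "cr", "cost") %in% names(surrogates)),
            all(decision_vars %in% bounds$variable))
  structure(list(surrogates = surrogates, decision_vars = decision_vars,
                 fixed = as.numeric(fixed), bounds = bounds,
                 constraints = constraints),
            class = "moo_problem")
}

# a "model" is either a surrogate_model or a plain function of the
# design data frame (used for reduced-problem audits)
model_predict <- function(model, newdata) {
  if (is.function(model)) model(newdata) else predict(model, newdata)
}

# decode decision matrix -> full design matrix -> objectives + violation
evaluate_population <- function(problem, Z) {
  X <- matrix(rep(problem$fixed, each = nrow(Z)), nrow(Z), 14)
  colnames(X) <- problem$bounds$variable
  X[, problem$decision_vars] <- Z
  Xdf <- as.data.frame(X)
  rt <- model_predict(problem$surrogates$rt, Xdf)
  cr <- model_predict(problem$surrogates$cr, Xdf)
  cost <- model_predict(problem$surrogates$cost, Xdf)
  cs <- problem$constraints
  viol <- pmax(0, cs$rt[1] - rt) / diff(cs$rt) +
          pmax(0, rt - cs$rt[2]) / diff(cs$rt) +
          pmax(0, cs$cr[1] - cr) / diff(cs$cr) +
          pmax(0, cr - cs$cr[2]) / diff(cs$cr) +
          pmax(0, cost - cs$cost_max) / cs$cost_max
  list(X = Xdf, rt = rt, cr = cr, cost = cost,
       obj = cbind(rt, -cr, cost), violation = viol)
}

# rank a population by Deb's feasibility rule: feasible solutions ordered
# by (front, -crowding); infeasible appended ordered by total violation
constrained_order <- function(obj, violation) {
  n <- nrow(obj)
  feas <- violation <= 0
  ord_feas <- integer(0)
  rank_front <- rep(NA_integer_, n)
  crowd <- rep(NA_real_, n)
  if (any(feas)) {
    idx <- which(feas)
    fronts <- fast_nondominated_sort(obj[idx, , drop = FALSE])
    for (fi in seq_along(fronts)) {
      members <- idx[fronts[[fi]]]
      rank_front[members] <- fi
      cd <- crowding_distance(obj[members, , drop = FALSE])
      crowd[members] <- cd
      ord_feas <- c(ord_feas, members[order(-cd)])
    }
  }
  ord_infeas <- which(!feas)[order(violation[!feas])]
  list(order = c(ord_feas, ord_infeas), rank_front = rank_front,
       crowding = crowd, feasible = feas)
}

# simulated binary crossover, per-coordinate, clipped later
sbx_crossover <- function(p1, p2, lo, hi, eta = 15, rate = 0.9) {
  d <- length(p1)
  c1 <- p1; c2 <- p2
  if (runif(1) <= rate) {
    for (j in seq_len(d)) {
      if (runif(1) > 0.5 || abs(p1[j] - p2[j]) < 1e-14) next
      u <- runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
              else (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[j] <- 0.5 * ((1 + beta) * p1[j] + (1 - beta) * p2[j])
      c2[j] <- 0.5 * ((1 - beta) * p1[j] + (1 + beta) * p2[j])
    }
  }
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

polynomial_mutation <- function(z, lo, hi, eta = 20, rate = NULL) {
  d <- length(z)
  if (is.null(rate)) rate <- 1 / d
  for (j in seq_len(d)) {
    if (runif(1) > rate) next
    u <- runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
             else 1 - (2 * (1 - u))^(1 / (eta + 1))
    z[j] <- z[j] + delta * (hi[j] - lo[j])
  }
  pmin(pmax(z, lo), hi)
}

#' Run constrained NSGA-II on the surrogate problem
#'
#' Binary tournaments under Deb's feasibility rule, simulated binary
#' crossover (eta 15, rate 0.9), polynomial mutation (eta 20, rate 1/d),
#' and elitist environmental selection.  Returns the feasible
#' nondominated archive of the final population.
#'
#' @param problem A `moo_problem`.
#' @param pop_size Population size (default 200).
#' @param generations Number of generations (default 500).
#' @param seed Integer seed; the run is deterministic given it.
#' @return A `pareto_front`: data frame with the decision variables, the
#'   predicted `RT`, `CR`, `Cost`, and the full design vector columns;
#'   attribute `decision_vars` records the searched variables.
#' @export
run_nsga2 <- function(problem, pop_size = 200, generations = 500,
                      seed = 1L) {
  stopifnot(inherits(problem, "moo_problem"))
  set.seed(seed)
  dv <- problem$decision_vars
  b <- problem$bounds
  lo <- b$min[match(dv, b$variable)]
  hi <- b$max[match(dv, b$variable)]
  d <- length(dv)
  N <- pop_size

  # log-uniform initialization (the box spans orders of magnitude)
  Z <- exp(matrix(runif(N * d, rep(log(lo), each = N),
                        rep(log(hi), each = N)), N, d))
  ev <- evaluate_population(problem, Z)

  for (g in seq_len(generations)) {
    co <- constrained_order(ev$obj, ev$violation)
    pos <- integer(N); pos[co$order] <- seq_len(N)  # smaller = better
    # binary tournaments to pick N parents
    cand <- matrix(sample.int(N, 2 * N, replace = TRUE), N, 2)
    parents <- ifelse(pos[cand[, 1]] <= pos[cand[, 2]], cand[, 1], cand[, 2])
    Q <- matrix(0, N, d)
    for (i in seq(1, N - 1, by = 2)) {
      ch <- sbx_crossover(Z[parents[i], ], Z[parents[i + 1], ], lo, hi)
      Q[i, ] <- polynomial_mutation(ch[[1]], lo, hi)
      Q[i + 1, ] <- polynomial_mutation(ch[[2]], lo, hi)
    }
    if (N %% 2 == 1)
      Q[N, ] <- polynomial_mutation(Z[parents[N], ], lo, hi)
    evQ <- evaluate_population(problem, Q)
    Zall <- rbind(Z, Q)
    objall <- rbind(ev$obj, evQ$obj)
    violall <- c(ev$violation, evQ$violation)
    keep <- constrained_order(objall, violall)$order[seq_len(N)]
    Z <- Zall[keep, , drop = FALSE]
    ev <- evaluate_population(problem, Z)
  }

  co <- constrained_order(ev$obj, ev$violation)
  sel <- which(co$feasible & co$rank_front == 1L)
  if (!length(sel))
    stop("no feasible solution found; consider relaxing the constraints")
  # deduplicate identical decision vectors
  key <- apply(signif(Z[sel, , drop = FALSE], 12), 1, paste, collapse = "|")
  sel <- sel[!duplicated(key)]
  front <- data.frame(ev$X[sel, , drop = FALSE],
                      RT = ev$rt[sel], CR = ev$cr[sel], Cost = ev$cost[sel])
  rownames(front) <- NULL
  structure(front, class = c("pareto_front", "data.frame"),
            decision_vars = dv)
}

#' Select the four named industrial strategies from a Pareto front
#'
#' `max_output` minimizes RT, `max_yield` maximizes CR, `min_cost`
#' minimizes Cost, and `balanced` minimizes the Euclidean distance to the
#' ideal point after min-max normalization of (RT, 1-CR, Cost) over the
#' front.  The similarity matrix is the cosine similarity of the
#' bound-normalized decision vectors.
#'
#' @param front A `pareto_front`.
#' @param bounds Bounds used for decision-vector normalization.
#' @return List with `strategies` (data frame: name, decision variables,
#'   RT, CR, Cost) and `similarity` (4 x 4 cosine-similarity matrix).
#' @export
select_strategies <- function(front, bounds = input_bounds()) {
  stopifnot(nrow(front) >= 1)
  obj <- cbind(front$RT, 1 - front$CR, front$Cost)
  rng <- apply(obj, 2, function(v) {
    r <- max(v) - min(v)
    if (r == 0) r <- 1
    (v - min(v)) / r
  })
  rng <- matrix(rng, nrow = nrow(front))
  pick <- c(balanced = which.min(sqrt(rowSums(rng^2))),
            max_output = which.min(front$RT),
            max_yield = which.max(front$CR),
            min_cost = which.min(front$Cost))
  dv <- attr(front, "decision_vars")
  strategies <- data.frame(name = names(pick),
                           front[pick, c(dv, "RT", "CR", "Cost"),
                                 drop = FALSE],
                           stringsAsFactors = FALSE)
  rownames(strategies) <- NULL
  # cosine similarity of bound-normalized decision vectors
  lo <- bounds$min[match(dv, bounds$variable)]
  hi <- bounds$max[match(dv, bounds$variable)]
  Zn <- t((t(as.matrix(front[pick, dv, drop = FALSE])) - lo) / (hi - lo))
  sim <- matrix(1, 4, 4, dimnames = list(names(pick), names(pick)))
  for (i in 1:4) for (j in 1:4) {
    ni <- sqrt(sum(Zn[i, ]^2)); nj <- sqrt(sum(Zn[j, ]^2))
    sim[i, j] <- if (ni == 0 || nj == 0) 1 else
      sum(Zn[i, ] * Zn[j, ]) / (ni * nj)
  }
  list(strategies = strategies, similarity = sim)
}

#' Hypervolume (3-objective, minimize) by inclusion-exclusion on a grid
#'
#' Small audit helper used to track front quality across generations:
#' Monte Carlo estimate of the volume dominated by `points` relative to
#' `ref` (both in minimized objective space).
#'
#' @param points Matrix of objective vectors (minimized).
#' @param ref Reference point (worse than all points).
#' @param n_mc Monte Carlo sample size.
#' @param seed Seed for the sampling.
#' @return Scalar hypervolume estimate.
#' @export
hypervolume_mc <- function(points, ref, n_mc = 20000, seed = 1L) {
  points <- as.matrix(points)
  m <- ncol(points)
  set.seed(seed)
  ideal <- apply(points, 2, min)
  U <- sapply(seq_len(m), function(j) runif(n_mc, ideal[j], ref[j]))
  dominated <- rep(FALSE, n_mc)
  for (i in seq_len(nrow(points))) {
    inside <- rep(TRUE, n_mc)
    for (j in seq_len(m)) inside <- inside & U[, j] >= points[i, j]
    dominated <- dominated | inside
    if (all(dominated)) break
  }
  mean(dominated) * prod(ref - ideal)
}
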