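# Nondominated sorting, crowding distance, constrained NSGA-II,
# and strategy selection.

# brute-force domination audit: i dominates j in minimized space
dominates_bf <- function(a, b) all(a <= b) && any(a < b)

audit_front1 <- function(points) {
  n <- nrow(points)
  vapply(seq_len(n), function(i)
    !any(vapply(seq_len(n), function(j)
      j != i && dominates_bf(points[j, ], points[i, ]), TRUE)), TRUE)
}

test_that("nondominated sort matches the brute-force audit", {
  pts <- rbind(c(1, 1), c(2, 2), c(0, 3), c(3, 0))
  fronts <- fast_nondominated_sort(pts)
  expect_equal(sort(fronts[[1]]), c(1, 3, 4))
  expect_equal(fronts[[2]], 2)
  expect_equal(fast_nondominated_sort(matrix(c(1, 2), 1)), list(1L))
  same <- matrix(1, 5, 3)
  expect_equal(fast_nondominated_sort(same), list(1:5))
  # randomized audit against the brute-force pairwise oracle
  set.seed(15)
  for (r in 1:10) {
    pts <- matrix(runif(60), 20, 3)
    fronts <- fast_nondominated_sort(pts)
    expect_setequal(fronts[[1]], which(audit_front1(pts)))
    # later fronts are nondominated after removing earlier fronts
    rest <- setdiff(seq_len(20), fronts[[1]])
    if (length(rest) > 1) {
      expect_setequal(fronts[[2]],
                      rest[audit_front1(pts[rest, , drop = FALSE])])
    }
    expect_setequal(unlist(fronts), 1:20)
  }
})

test_that("crowding distance matches hand computations", {
  expect_equal(crowding_distance(matrix(runif(4), 2, 2)), c(Inf, Inf))
  # collinear, equally spaced: middle point gets gap/range = 1 per objective
  front <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(crowding_distance(front), c(Inf, 2, Inf))
  # duplicated interior vectors get zero distance
  front2 <- rbind(c(0, 3), c(1, 2), c(1, 2), c(3, 0))
  d <- crowding_distance(front2)
  expect_equal(d[2:3], c(0, 0))
  expect_equal(d[c(1, 4)], c(Inf, Inf))
})

# deterministic mock surrogates over the decision slice (x3, x5, x6)
mock_models <- function() {
  list(
    rt = function(df) 2 + 50 * (0.0121 - df$x5) / 0.0121^1 * (df$x5 < 0.0121) +
      5 * df$x3,
    cr = function(df) 0.7 + 0.25 * (log10(df$x5) - log10(0.00121)) / 2 +
      0.05 * (log10(df$x6) - log10(7.45e-4)) / 2,
    cost = function(df) 300 + 8000 * df$x5^1.2 + 30 * df$x3 + 100 * df$x6)
}

test_that("NSGA-II returns a feasible mutually nondominated front", {
  prob <- moo_problem(mock_models())
  front <- run_nsga2(prob, pop_size = 60, generations = 40, seed = 9)
  expect_gt(nrow(front), 1)
  # constraint satisfaction
  expect_true(all(front$RT >= 0.5 & front$RT <= 72))
  expect_true(all(front$CR >= 0.85 & front$CR <= 0.98))
  expect_true(all(front$Cost <= 800))
  # mutual nondomination in (RT, -CR, Cost)
  obj <- cbind(front$RT, -front$CR, front$Cost)
  expect_true(all(audit_front1(obj)))
  # decision variables inside their bounds, fixed variables at reference
  b <- input_bounds()
  for (v in c("x3", "x5", "x6")) {
    lo <- b$min[b$variable == v]; hi <- b$max[b$variable == v]
    expect_true(all(front[[v]] >= lo & front[[v]] <= hi))
  }
  ref <- as.numeric(reference_input())
  expect_true(all(front$x1 == ref[1]))
  expect_true(all(front$x10 == ref[10]))
  # seed-determinism
  front2 <- run_nsga2(prob, pop_size = 60, generations = 40, seed = 9)
  expect_identical(as.data.frame(front), as.data.frame(front2))
})

test_that("a constant cost objective collapses to the RT-CR trade-off", {
  models <- mock_models()
  models$cost <- function(df) rep(500, nrow(df))
  prob <- moo_problem(models)
  front <- run_nsga2(prob, pop_size = 60, generations = 40, seed = 10)
  obj2 <- cbind(front$RT, -front$CR)
  expect_true(all(audit_front1(obj2)))
})

test_that("infeasible problems report an actionable error", {
  models <- mock_models()
  models$cr <- function(df) rep(0.5, nrow(df))   # CR can never reach 0.85
  prob <- moo_problem(models)
  expect_error(run_nsga2(prob, pop_size = 20, generations = 5, seed = 1),
               "feasible")
})

test_that("longer runs do not lose hypervolume (3 seeds)", {
  prob <- moo_problem(mock_models())
  ref_pt <- c(72, -0.85, 800)
  hv <- function(front, seed) {
    hypervolume_mc(cbind(front$RT, -front$CR, front$Cost), ref_pt,
                   n_mc = 5000, seed = seed)
  }
  gains <- vapply(1:3, function(s) {
    early <- run_nsga2(prob, pop_size = 40, generations = 5, seed = s)
    late <- run_nsga2(prob, pop_size = 40, generations = 40, seed = s)
    hv(late, 99) - hv(early, 99)
  }, 0)
  expect_gte(mean(gains >= -1e-9), 2 / 3)
})

test_that("strategy selection matches the hand-computed toy front", {
  front <- structure(
    data.frame(x3 = c(0.5, 0.6, 0.7), x5 = c(0.002, 0.004, 0.008),
               x6 = c(0.01, 0.02, 0.03),
               RT = c(1, 2, 10), CR = c(0.90, 0.95, 0.99),
               Cost = c(100, 200, 500)),
    class = c("pareto_front", "data.frame"),
    decision_vars = c("x3", "x5", "x6"))
  sel <- select_strategies(front)
  st <- sel$strategies
  # normalized ideal-point distances: 1.0, 0.522, 1.414 -> middle point
  expect_equal(st$RT[st$name == "balanced"], 2)
  expect_equal(st$RT[st$name == "max_output"], 1)
  expect_equal(st$CR[st$name == "max_yield"], 0.99)
  expect_equal(st$Cost[st$name == "min_cost"], 100)
  # independent recomputation of the balanced pick
  obj <- cbind(front$RT, 1 - front$CR, front$Cost)
  nrm <- apply(obj, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  dists <- sqrt(rowSums(nrm^2))
  expect_equal(dists, c(1, 0.522, sqrt(2)), tolerance = 1e-3)
  expect_equal(which.min(dists), 2L)
  # similarity matrix is symmetric with unit diagonal
  expect_equal(unname(diag(sel$similarity)), rep(1, 4))
  expect_equal(sel$similarity, t(sel$similarity))
  # single-point front: all strategies identical, similarity all 1
  f1 <- front[2, , drop = FALSE]
  attr(f1, "decision_vars") <- c("x3", "x5", "x6")
  class(f1) <- c("pareto_front", "data.frame")
  sel1 <- select_strategies(f1)
  expect_equal(nrow(unique(sel1$strategies[, -1])), 1)
  expect_true(all(abs(sel1$similarity - 1) < 1e-12))
})
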