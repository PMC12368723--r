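# Techno-economic model: seven-component production cost of one batch.

#' Production cost of a batch
#'
#' Seven-component cost model (abstract currency units), a relative
#' comparator rather than an absolute cost prediction:
#' \deqn{C_{catalyst} = 8000\,x_5^{1.2}}
#' \deqn{C_{reagent}  = 40 x_1 + 20 x_2 + 30 x_3 + 10 x_4}
#' \deqn{C_{fixed}    = 200}
#' \deqn{C_{energy}   = 15\sqrt{y_1}}
#' \deqn{C_{maint}    = 10(1 + 0.05\,y_1^{1.5})}
#' \deqn{C_{purif}    = 500(1 - y_2)^{1.5}}
#' \deqn{C_{labor}    = 150 + 5 y_1}
#' with the reaction time \eqn{y_1} in hours and the conversion rate
#' \eqn{y_2} a fraction in \[0, 1\].
#'
#' @param x Design vector (a `simulation_input`, or any numeric vector
#'   whose first five elements are x1..x5 in mol/m^3).  Concentrations
#'   beyond x5 are ignored.
#' @param y1 Reaction time in hours, >= 0.
#' @param y2 Conversion rate fraction.  Values outside \[0, 1\] raise an
#'   error unless `clamp_cr = TRUE`, in which case they are clamped with
#'   a warning (surrogate predictions under perturbation can overshoot).
#' @param clamp_cr Clamp out-of-range `y2` instead of erroring.
#' @return A list of class `cost_breakdown` with the seven components and
#'   `total` (their exact sum).
#' @export
compute_cost <- function(x, y1, y2, clamp_cr = FALSE) {
  xv <- as.numeric(x)
  if (length(xv) < 5 || any(!is.finite(xv[1:5])) || any(xv[1:5] < 0))
    stop("x must provide nonnegative concentrations x1..x5")
  if (!is.finite(y1) || y1 < 0) stop("reaction time y1 must be >= 0")
  if (!is.finite(y2)) stop("conversion rate y2 must be finite")
  if (y2 < 0 || y2 > 1) {
    if (!clamp_cr)
      stop("conversion rate y2 outside [0, 1]; use clamp_cr = TRUE for perturbed predictions")
    warning(sprintf("clamping conversion rate %.4g into [0, 1]", y2))
    y2 <- min(max(y2, 0), 1)
  }
  comp <- c(
    C_catalyst = 8000 * xv[5]^1.2,
    C_reagent  = 40 * xv[1] + 20 * xv[2] + 30 * xv[3] + 10 * xv[4],
    C_fixed    = 200,
    C_energy   = 15 * sqrt(y1),
    C_maint    = 10 * (1 + 0.05 * y1^1.5),
    C_purif    = 500 * (1 - y2)^1.5,
    C_labor    = 150 + 5 * y1
  )
  structure(c(as.list(comp), list(total = sum(comp))),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  comp <- unlist(x[setdiff(names(x), "total")])
  cat("<cost_breakdown> total =", format(x$total, digits = 6), "units\n")
  for (nm in names(comp))
    cat(sprintf("  %-11s %10.4f\n", nm, comp[[nm]]))
  invisible(x)
}

#' Serialize a cost breakdown to JSON
#' @param x A `cost_breakdown`.
#' @param path Optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
cost_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cost_breakdown"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
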