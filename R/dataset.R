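# Dataset generation: sampling the design space, labeling with the
# simulator + cost model, splits, and correlation summaries.

#' Sampling configuration for the design space
#'
#' Each design-variable range spans two orders of magnitude, so the
#' default sampling law is independent log-uniform per dimension;
#' Latin-hypercube-in-log and plain uniform are available.
#'
#' @param n_samples Number of design points (>= 1).
#' @param bounds Bounds data frame as from [input_bounds()].
#' @param law One of `"log-uniform"`, `"uniform"`, `"lhs-log"`.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(n_samples = 8000, bounds = input_bounds(),
                            law = c("log-uniform", "uniform", "lhs-log"),
                            seed = 1L) {
  law <- match.arg(law)
  stopifnot(n_samples >= 1, all(bounds$min > 0), all(bounds$min < bounds$max))
  structure(list(n_samples = as.integer(n_samples), bounds = bounds,
                 law = law, seed = as.integer(seed)),
            class = "sampling_config")
}

#' Sample design points from the input space
#'
#' @param cfg A `sampling_config`.
#' @return Data frame (`n_samples` x 14) with columns x1..x14, every
#'   column within its bounds.
#' @export
sample_inputs <- function(cfg = sampling_config()) {
  stopifnot(inherits(cfg, "sampling_config"))
  b <- cfg$bounds
  d <- nrow(b)
  n <- cfg$n_samples
  set.seed(cfg$seed)
  u <- switch(cfg$law,
    "log-uniform" = matrix(runif(n * d), n, d),
    "uniform"     = matrix(runif(n * d), n, d),
    "lhs-log"     = lhs::randomLHS(n, d))
  X <- if (cfg$law == "uniform") {
    sweep(sweep(u, 2, b$max - b$min, "*"), 2, b$min, "+")
  } else {
    lo <- log(b$min)
    exp(sweep(sweep(u, 2, log(b$max) - lo, "*"), 2, lo, "+"))
  }
  X <- as.data.frame(X)
  names(X) <- b$variable
  X
}

#' Label sampled design points with the simulator and cost model
#'
#' Runs one batch simulation per row, extracts RT and CR, and prices the
#' run.  Row results do not depend on evaluation order.  Integration
#' failures are flagged (outputs set to `NA`), never silently dropped;
#' more than `max_fail_frac` failures aborts with diagnostics.
#'
#' @param inputs Data frame of design points (columns x1..x14).
#' @param mech A `mechanism_spec` (default: canonical mechanism).
#' @param kcfg A `kinetics_config`.
#' @param max_fail_frac Abort threshold for the failed-row fraction.
#' @param provenance Optional list (e.g. the sampling seed) stored with
#'   the dataset.
#' @return A `labeled_dataset`: list with `inputs`, `outputs` (y1 = RT h,
#'   y2 = CR, y3 = Cost), `censored`, `failed`, `provenance`.
#' @export
build_dataset <- function(inputs, mech = NULL, kcfg = kinetics_config(),
                          max_fail_frac = 0.01, provenance = list()) {
  if (is.null(mech)) mech <- canonical_mechanism()
  n <- nrow(inputs)
  stopifnot(n >= 1, all(paste0("x", 1:14) %in% names(inputs)))
  X <- as.matrix(inputs[, paste0("x", 1:14)])
  y1 <- y2 <- y3 <- rep(NA_real_, n)
  censored <- failed <- logical(n)
  messages <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      inp <- simulation_input(X[i, ], perturbed = TRUE)
      traj <- simulate_batch(inp, mech, kcfg)
      m <- extract_metrics(traj, inp, kcfg)
      cost <- compute_cost(inp, m$rt_h, m$cr)
      list(m = m, cost = cost$total)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      messages <- c(messages, sprintf("row %d: %s", i, conditionMessage(res)))
    } else {
      y1[i] <- res$m$rt_h
      y2[i] <- res$m$cr
      y3[i] <- res$cost
      censored[i] <- res$m$censored
    }
  }
  if (mean(failed) > max_fail_frac)
    stop(sprintf("%d/%d simulations failed:\n%s", sum(failed), n,
                 paste(head(messages, 10), collapse = "\n")))
  structure(
    list(inputs = as.data.frame(X),
         outputs = data.frame(y1 = y1, y2 = y2, y3 = y3),
         censored = censored,
         failed = failed,
         provenance = c(provenance,
                        list(mechanism_hash = mechanism_hash(mech),
                             kinetics = unclass(kcfg),
                             n_failed = sum(failed)))),
    class = "labeled_dataset")
}

#' Sample and label a dataset in one call
#'
#' @param cfg A `sampling_config`.
#' @inheritParams build_dataset
#' @return A `labeled_dataset`.
#' @export
generate_dataset <- function(cfg = sampling_config(), mech = NULL,
                             kcfg = kinetics_config()) {
  build_dataset(sample_inputs(cfg), mech, kcfg,
                provenance = list(seed = cfg$seed, law = cfg$law,
                                  n_samples = cfg$n_samples))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$inputs), " rows (",
      sum(x$censored), " censored, ", sum(x$failed), " failed)\n", sep = "")
  print(summary(x$outputs))
  invisible(x)
}

#' Flatten a labeled dataset to one data frame
#'
#' @param x A `labeled_dataset`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @param drop_failed Drop rows whose simulation failed.
#' @return Data frame with x1..x14, y1..y3, `censored`.
#' @export
as.data.frame.labeled_dataset <- function(x, row.names = NULL,
                                          optional = FALSE, ...,
                                          drop_failed = TRUE) {
  df <- cbind(x$inputs, x$outputs, censored = x$censored)
  if (drop_failed) df <- df[!x$failed, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Split a dataset into train / validation / test
#'
#' Disjoint, exhaustive, and deterministic under the seed.  Failed rows
#' are excluded before splitting.
#'
#' @param ds A `labeled_dataset` or flat data frame.
#' @param fractions Length-3 nonnegative fractions summing to 1.
#' @param seed Integer seed for the permutation.
#' @return List with data frames `train`, `validation`, `test`.
#' @export
split_dataset <- function(ds, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  df <- if (inherits(ds, "labeled_dataset")) as.data.frame(ds) else ds
  n <- nrow(df)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  idx <- list(train = perm[seq_len(n_train)],
              validation = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n - n_train - n_val)])
  if (any(vapply(idx, length, 1L) == 0))
    stop("split produced an empty partition")
  lapply(idx, function(i) {
    out <- df[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Pearson correlation matrix of inputs and outputs
#'
#' @param ds A `labeled_dataset` or flat data frame with x1..x14 and
#'   y1..y3.
#' @return 17x17 symmetric correlation matrix with unit diagonal.
#'   Zero-variance columns are flagged with a warning and yield `NA`
#'   entries.
#' @export
summarize_correlations <- function(ds) {
  df <- if (inherits(ds, "labeled_dataset")) as.data.frame(ds) else ds
  cols <- c(paste0("x", 1:14), paste0("y", 1:3))
  df <- df[, cols]
  if (nrow(df) < 3) stop("need at least 3 rows for correlations")
  zv <- vapply(df, function(v) var(v) == 0 || !is.finite(var(v)), TRUE)
  if (any(zv))
    warning("zero-variance columns (correlations undefined): ",
            paste(cols[zv], collapse = ", "))
  suppressWarnings(cor(df))
}

# md5 fingerprint of a data frame's values (provenance / caching);
# computed on the binary serialization, so it is fast and exact
dataset_hash <- function(ds) {
  df <- if (inherits(ds, "labeled_dataset")) as.data.frame(ds) else ds
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(df, con, version = 3)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Persist a labeled dataset as CSV with a JSON provenance sidecar
#'
#' @param ds A `labeled_dataset`.
#' @param path CSV output path; the sidecar is written to
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  write.csv(as.data.frame(ds, drop_failed = FALSE), path, row.names = FALSE)
  meta <- c(ds$provenance, list(hash = dataset_hash(ds)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
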