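# SHAP-style attribution of the trained surrogates: per-sample feature
# attributions (TreeSHAP), global importance ranking, and two-variable
# partial-dependence interaction surfaces.

#' TreeSHAP attributions for a surrogate
#'
#' Tree-path-exact Shapley attributions of each prediction to the input
#' features, in label units.  Local accuracy holds row-wise: baseline +
#' sum of attributions = model prediction.
#'
#' @param model A `surrogate_model`.
#' @param inputs Data frame or matrix with the model's feature columns.
#' @return An `attribution_matrix`: list with `phi` (n x p matrix of
#'   attributions), `baseline` (expected value), `prediction` (row sums
#'   plus baseline), `features`.
#' @export
attribute_shap <- function(model, inputs) {
  stopifnot(inherits(model, "surrogate_model"))
  df <- as.data.frame(inputs)
  miss <- setdiff(model$features, names(df))
  if (length(miss)) stop("feature-name mismatch; missing: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(df[, model$features, drop = FALSE])
  contrib <- predict(model$booster, X, predcontrib = TRUE)
  p <- length(model$features)
  phi <- contrib[, seq_len(p), drop = FALSE]
  colnames(phi) <- model$features
  baseline <- unname(contrib[1, p + 1])
  structure(list(phi = phi, baseline = baseline,
                 prediction = rowSums(phi) + baseline,
                 features = model$features),
            class = "attribution_matrix")
}

#' Rank features by mean absolute attribution
#'
#' @param attr An `attribution_matrix`.
#' @return Data frame (`feature`, `mean_abs_attribution`) in descending
#'   order; ties broken by feature index.
#' @export
rank_importance <- function(attr) {
  stopifnot(inherits(attr, "attribution_matrix"))
  imp <- colMeans(abs(attr$phi))
  ord <- order(-imp, seq_along(imp))   # stable: ties keep feature order
  data.frame(feature = attr$features[ord],
             mean_abs_attribution = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Two-variable interaction surface (2-D partial dependence)
#'
#' Model prediction averaged over the background rows with the feature
#' pair fixed at each node of a rectangular grid.
#'
#' @param model A `surrogate_model`, or a plain function of the design
#'   data frame (useful for analytic checks).
#' @param features Length-2 character vector naming the feature pair.
#' @param grid List of two numeric vectors of grid values (named after
#'   the features), or `NULL` to span the background range with
#'   `n_grid` points per axis.
#' @param background Data frame of background rows used for averaging
#'   (non-empty).
#' @param n_grid Grid resolution per axis when `grid` is `NULL`.
#' @return List with `f1`, `f2` (grid values) and `surface`
#'   (length(f1) x length(f2) matrix of averaged predictions).
#' @export
interaction_surface <- function(model, features, grid = NULL, background,
                                n_grid = 20) {
  stopifnot(length(features) == 2)
  if (!is.function(model)) stopifnot(all(features %in% model$features))
  bg <- as.data.frame(background)
  if (nrow(bg) == 0) stop("empty background set")
  if (is.null(grid)) {
    grid <- lapply(features, function(f)
      seq(min(bg[[f]]), max(bg[[f]]), length.out = n_grid))
    names(grid) <- features
  }
  f1 <- grid[[features[1]]]; f2 <- grid[[features[2]]]
  nodes <- expand.grid(a = f1, b = f2, KEEP.OUT.ATTRS = FALSE)
  # one big prediction call: background replicated per node
  nb <- nrow(bg)
  big <- bg[rep(seq_len(nb), times = nrow(nodes)), , drop = FALSE]
  big[[features[1]]] <- rep(nodes$a, each = nb)
  big[[features[2]]] <- rep(nodes$b, each = nb)
  pred <- model_predict(model, big)
  means <- tapply(pred, rep(seq_len(nrow(nodes)), each = nb), mean)
  list(f1 = f1, f2 = f2,
       surface = matrix(as.numeric(means), length(f1), length(f2)))
}

#' Export an importance ranking as JSON
#' @param ranking Data frame from [rank_importance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
importance_to_json <- function(ranking, path) {
  jsonlite::write_json(ranking, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
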