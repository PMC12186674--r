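# Post-hoc model interrogation: permutation feature importance (PFI) and
# partial dependence (PDP).

#' Permutation feature importance
#'
#' For each feature (or feature group), the increase in RMSE when that
#' column (or block of columns, shuffled jointly) is permuted, averaged
#' over seeded repeats. Importances are reported in metric units (RMSE
#' increase, %), not normalized, so they are directly comparable with the
#' experimental noise floor. Shuffling a whole descriptor block as one
#' "solvent" feature guards against correlated descriptors masking each
#' other.
#'
#' @param model fitted `surrogate_model` (anything with a `predict`
#'   returning `$mean`).
#' @param X encoded feature matrix (column names required).
#' @param y observed response.
#' @param n_repeats shuffles per feature (>= 2, default 20).
#' @param seed integer seed.
#' @param groups optional named list: group name -> character vector of
#'   column names shuffled jointly (appended to the per-column features).
#' @return data.frame (feature, importance, sd, rank) of class
#'   `importance_table`, sorted by rank.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 20, seed = 1L,
                                   groups = NULL) {
  X <- as.matrix(X)
  stopifnot(n_repeats >= 2, !is.null(colnames(X)))
  feats <- c(as.list(stats::setNames(colnames(X), colnames(X))), groups)
  bad <- setdiff(unlist(feats), colnames(X))
  if (length(bad)) stop_config("unknown feature(s): %s",
                               paste(bad, collapse = ", "))
  baseline <- rmse(y, predict(model, X)$mean)
  n <- nrow(X)
  perms <- with_seed(derive_seed(seed, "pfi"),
                     lapply(seq_len(n_repeats), function(r) sample.int(n)))
  res <- lapply(names(feats), function(f) {
    cols <- feats[[f]]
    d <- vapply(perms, function(p) {
      Xp <- X
      Xp[, cols] <- X[p, cols]
      rmse(y, predict(model, Xp)$mean) - baseline
    }, numeric(1))
    data.frame(feature = f, importance = mean(d), sd = stats::sd(d))
  })
  out <- do.call(rbind, res)
  out$rank <- rank(-out$importance, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Partial dependence of the model response on one or two features
#'
#' For each grid value g, the response is the model prediction averaged
#' over the data rows with the feature(s) overwritten by g. Deterministic;
#' grids span the observed range.
#'
#' @param model fitted `surrogate_model`.
#' @param X encoded feature matrix (column names required).
#' @param features one or two column names.
#' @param grid_size grid points per feature (default 20).
#' @return data.frame with the feature grid column(s) and `response`.
#' @export
partial_dependence <- function(model, X, features, grid_size = 20) {
  X <- as.matrix(X)
  if (length(features) < 1 || length(features) > 2)
    stop_config("partial dependence supports 1 or 2 features")
  bad <- setdiff(features, colnames(X))
  if (length(bad)) stop_config("unknown feature(s): %s",
                               paste(bad, collapse = ", "))
  grids <- lapply(features, function(f)
    seq(min(X[, f]), max(X[, f]), length.out = grid_size))
  grid <- expand.grid(grids)
  names(grid) <- features
  grid$response <- vapply(seq_len(nrow(grid)), function(i) {
    Xg <- X
    for (f in features) Xg[, f] <- grid[[f]][i]
    mean(predict(model, Xg)$mean)
  }, numeric(1))
  grid
}
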