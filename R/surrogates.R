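# Surrogate-model zoo: several regressor families with predictive
# uncertainty behind one interface, cross-validated scoring, and
# lowest-RMSE model selection per black-box objective.

.surrogate_registry <- new.env(parent = emptyenv())

#' Register a surrogate family
#'
#' The zoo is extensible: a family is any function
#' `fit(X, y, seed, control)` returning an object whose `predict` method
#' yields a data.frame with `mean` and `sd` columns.
#'
#' @param name family name.
#' @param fit fitting function.
#' @param overwrite replace an existing entry?
#' @export
register_surrogate_family <- function(name, fit, overwrite = FALSE) {
  if (!overwrite && !is.null(.surrogate_registry[[name]]))
    stop_config("family '%s' already registered", name)
  .surrogate_registry[[name]] <- fit
  invisible(name)
}

#' Names of the registered surrogate families
#' @return character vector.
#' @export
surrogate_families <- function() sort(ls(.surrogate_registry))

register_builtin_families <- function() {
  register_surrogate_family("gaussian_process", fit_gp, overwrite = TRUE)
  register_surrogate_family("boosted_trees", fit_boosted_trees,
                            overwrite = TRUE)
  register_surrogate_family("ridge_ensemble", fit_ridge_ensemble,
                            overwrite = TRUE)
}

#' Fit a surrogate model
#'
#' Uncertainty contract: the Gaussian process reports its posterior
#' standard deviation; ensemble families (boosted trees, ridge) report the
#' spread across >= 20 bootstrap members. Refitting with the same seed is
#' bit-reproducible.
#'
#' @param family registered family name (see [surrogate_families()]).
#' @param X numeric matrix of encoded conditions (>= 5 rows).
#' @param y numeric response (yield, %).
#' @param seed integer seed.
#' @param control named list of family-specific settings.
#' @return object of class `surrogate_model` with a `predict` method.
#' @export
fit_surrogate <- function(family, X, y, seed = 1L, control = list()) {
  fit <- .surrogate_registry[[family]]
  if (is.null(fit)) stop_config("unknown surrogate family '%s'", family)
  X <- as.matrix(X)
  if (nrow(X) < 5L) stop_config("need at least 5 training rows")
  if (length(y) != nrow(X)) stop_config("X and y are not aligned")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_config("non-finite values in training data")
  fit(X, y, seed = seed, control = control)
}

#' Cross-validate a surrogate family
#'
#' Seeded k-fold cross-validation (default 5 folds, i.e. an 80/20 split per
#' fold). RMSE and R-squared are computed on held-out points only; the
#' per-fold predictions are kept on the report for audit.
#'
#' @inheritParams fit_surrogate
#' @param folds number of folds.
#' @return object of class `model_report`: list with `family`, `cv_rmse`,
#'   `cv_r2`, `hyperparameters`, `seed`, and `predictions`
#'   (data.frame row/fold/observed/predicted).
#' @export
cross_validate <- function(family, X, y, folds = 5, seed = 1L,
                           control = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * folds) stop_config("too few rows (%d) for %d folds", n, folds)
  fold <- with_seed(derive_seed(seed, "cv_folds"),
                    sample(rep_len(seq_len(folds), n)))
  pred <- rep(NA_real_, n)
  hp <- NULL
  cv_control <- utils::modifyList(control, list(cv_scoring = TRUE))
  for (k in seq_len(folds)) {
    tr <- fold != k
    m <- fit_surrogate(family, X[tr, , drop = FALSE], y[tr],
                       seed = derive_seed(seed, paste0("cv_fit_", k)),
                       control = cv_control)
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])$mean
    hp <- m$hyperparameters %||% hp
  }
  structure(list(family = family,
                 cv_rmse = rmse(y, pred),
                 cv_r2 = r_squared(y, pred),
                 hyperparameters = hp,
                 seed = seed,
                 predictions = data.frame(row = seq_len(n), fold = fold,
                                          observed = y, predicted = pred)),
            class = "model_report")
}

#' Serialize a model report for audit
#'
#' Writes the report (family, CV metrics, hyperparameters, seed) as JSON
#' and the per-fold held-out predictions as CSV.
#'
#' @param report a `model_report`.
#' @param json_path output JSON path.
#' @param csv_path optional CSV path for the per-fold predictions
#'   (default: `json_path` with a `.predictions.csv` suffix).
#' @return `json_path`, invisibly.
#' @export
write_model_report <- function(report, json_path,
                               csv_path = paste0(json_path,
                                                 ".predictions.csv")) {
  stopifnot(inherits(report, "model_report"))
  jsonlite::write_json(report[c("family", "cv_rmse", "cv_r2",
                                "hyperparameters", "seed")],
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(report$predictions, csv_path, row.names = FALSE,
                   quote = FALSE)
  invisible(json_path)
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s: CV RMSE %.3f, CV R2 %.3f\n",
              x$family, x$cv_rmse, x$cv_r2))
  invisible(x)
}

#' Select the best surrogate family by cross-validated RMSE
#'
#' All families are scored with the same seeded fold assignment; the family
#' with the lowest CV RMSE wins, ties broken by higher CV R-squared and
#' then by the declared family order. The winner is refit on the full data.
#'
#' @inheritParams fit_surrogate
#' @param families character vector of >= 2 registered family names.
#' @param folds number of CV folds.
#' @return list with `model` (fitted winner), `report` (its
#'   `model_report`), and `reports` (all candidate reports, in declared
#'   order).
#' @export
select_best <- function(X, y, families, seed = 1L, folds = 5,
                        control = list()) {
  if (length(families) < 2L) stop_config("need at least 2 candidate families")
  reports <- list(); errs <- character(0)
  for (f in families) {
    r <- tryCatch(
      cross_validate(f, X, y, folds = folds, seed = seed,
                     control = control[[f]] %||% list()),
      error = function(e) e)
    if (inherits(r, "error")) errs <- c(errs, sprintf("%s: %s", f, r$message))
    else reports[[length(reports) + 1L]] <- r
  }
  if (!length(reports))
    stop_config("all surrogate families failed:\n%s",
                paste(errs, collapse = "\n"))
  rmses <- vapply(reports, `[[`, numeric(1), "cv_rmse")
  r2s <- vapply(reports, `[[`, numeric(1), "cv_r2")
  ord <- order(rmses, -r2s, seq_along(reports))
  best <- reports[[ord[1L]]]
  model <- fit_surrogate(best$family, X, y,
                         seed = derive_seed(seed, paste0("fit_", best$family)),
                         control = control[[best$family]] %||% list())
  list(model = model, report = best, reports = reports)
}
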