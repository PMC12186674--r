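# Gaussian-process regression with an isotropic squared-exponential kernel
# on standardized inputs. Hyperparameters (signal variance, lengthscale,
# noise variance) by type-II maximum likelihood from a fixed set of starts,
# so a fit is a deterministic function of the data.

gp_nll <- function(theta, D2, y) {
  ls2 <- exp(2 * theta[1]); sf2 <- exp(theta[2]); sn2 <- exp(theta[3])
  n <- length(y)
  K <- sf2 * exp(-0.5 * D2 / ls2)
  diag(K) <- diag(K) + sn2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

fit_gp <- function(X, y, seed = 1L, control = list()) {
  X <- as.matrix(X); n <- nrow(X)
  cx <- colMeans(X)
  sx <- apply(X, 2, stats::sd); sx[sx < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, cx, "-"), 2, sx, "/")
  my <- mean(y); sy <- stats::sd(y)
  constant <- !is.finite(sy) || sy < 1e-12
  obj <- list(family = "gaussian_process", x_center = cx, x_scale = sx,
              y_center = my, y_scale = if (constant) 1 else sy,
              Z = Z, constant = constant, seed = seed)
  if (constant) {
    class(obj) <- c("gp_surrogate", "surrogate_model")
    return(obj)
  }
  ys <- (y - my) / sy
  D2 <- as.matrix(stats::dist(Z))^2
  starts <- list(c(log(1), log(1), log(1e-2)),
                 c(log(3), log(1), log(1e-4)),
                 c(log(2), log(1), log(1e-7)),
                 c(log(0.5), log(1), log(1e-1)))
  lower <- c(log(0.05), log(0.05), log(1e-8))
  upper <- c(log(30), log(10), log(1))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, gp_nll, D2 = D2, y = ys, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  th <- best$par
  ls2 <- exp(2 * th[1]); sf2 <- exp(th[2]); sn2 <- exp(th[3])
  K <- sf2 * exp(-0.5 * D2 / ls2)
  diag(K) <- diag(K) + sn2
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  obj$theta <- c(lengthscale = sqrt(ls2), signal_var = sf2, noise_var = sn2)
  obj$L <- L; obj$alpha <- alpha
  class(obj) <- c("gp_surrogate", "surrogate_model")
  obj
}

#' @export
predict.gp_surrogate <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  if (object$constant) {
    return(data.frame(mean = rep(object$y_center, nrow(Xs)),
                      sd = rep(0, nrow(Xs))))
  }
  Zs <- sweep(sweep(Xs, 2, object$x_center, "-"), 2, object$x_scale, "/")
  ls2 <- object$theta[["lengthscale"]]^2
  sf2 <- object$theta[["signal_var"]]
  # cross-covariances between test and training points
  d2 <- outer(rowSums(Zs^2), rowSums(object$Z^2), "+") -
    2 * Zs %*% t(object$Z)
  Ks <- sf2 * exp(-0.5 * pmax(d2, 0) / ls2)
  mu <- as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Ks))
  var_lat <- pmax(sf2 - colSums(v^2), 0)
  data.frame(mean = object$y_center + object$y_scale * mu,
             sd = object$y_scale * sqrt(var_lat))
}
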