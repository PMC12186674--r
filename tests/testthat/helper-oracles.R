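# Independent oracles and shared fixtures. The oracles deliberately use
# naive algorithms (double loops, Monte Carlo, quadrature) so they share
# no code with the implementation they check.

# O(n^2) pairwise-dominance Pareto oracle (maximize yield, minimize cost).
oracle_pareto_idx <- function(points) {
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dom <- points$yield[j] >= points$yield[i] &&
        points$cost[j] <= points$cost[i] &&
        (points$yield[j] > points$yield[i] ||
           points$cost[j] < points$cost[i])
      if (dom) { keep[i] <- FALSE; break }
    }
  }
  which(keep)
}

# Monte-Carlo hypervolume oracle: fraction of the reference box dominated.
oracle_hv_mc <- function(front, ref, n = 1e6, seed = 99) {
  set.seed(seed)
  ys <- runif(n, ref$yield, max(front$yield))
  cs <- runif(n, min(front$cost), ref$cost)
  box <- (max(front$yield) - ref$yield) * (ref$cost - min(front$cost))
  dom <- rep(FALSE, n)
  for (i in seq_len(nrow(front)))
    dom <- dom | (ys <= front$yield[i] & cs >= front$cost[i])
  mean(dom) * box
}

# Independent R-side hypervolume (union of rectangles by 1-D integration
# over a fine cost grid) used inside the EHVI quadrature oracle.
oracle_hv_exact <- function(yield, cost, ref) {
  keep <- yield > ref$yield & cost < ref$cost
  yield <- yield[keep]; cost <- cost[keep]
  if (!length(yield)) return(0)
  cuts <- sort(unique(c(cost, ref$cost)))
  area <- 0
  for (i in seq_len(length(cuts) - 1)) {
    covering <- yield[cost <= cuts[i]]
    if (length(covering))
      area <- area + (cuts[i + 1] - cuts[i]) * (max(covering) - ref$yield)
  }
  area
}

# 1-D quadrature EHVI oracle for a single Gaussian-yield candidate.
oracle_ehvi_quad <- function(mu, sd, cost, front, ref, n_grid = 4001) {
  ys <- seq(mu - 6 * sd, mu + 6 * sd, length.out = n_grid)
  base <- oracle_hv_exact(front$yield, front$cost, ref)
  gain <- vapply(ys, function(y)
    oracle_hv_exact(c(front$yield, y), c(front$cost, cost), ref) - base,
    numeric(1))
  w <- dnorm(ys, mu, sd)
  sum(gain * w) / sum(w)
}

# Small single-solvent design space for continuous-only tests.
toy_space <- function(n_solvents = 1, overrides = list()) {
  desc <- matrix(seq_len(n_solvents * 5), ncol = 5,
                 dimnames = list(NULL, paste0("sig", c(0, 2, 3, 4, 5))))
  design_space(solvents = paste0("S", seq_len(n_solvents)),
               descriptors = desc, overrides = overrides)
}

# A space compatible with the packaged 16-run example campaign: its eight
# solvents with synthetic descriptors, and residence time opened to
# 120 min (the excerpt explored longer times than the optimization
# bounds).
fixture_space <- function() {
  solvents <- c("DMF", "DMSO", "Acetone", "NMP", "DCM", "Cyclohexanone",
                "THFA", "EA")
  set.seed(421)
  desc <- matrix(rnorm(8 * 5), ncol = 5,
                 dimnames = list(solvents, paste0("sig", c(0, 2, 3, 4, 5))))
  vars <- default_continuous_variables()
  vars$upper[vars$name == "time_min"] <- 120
  design_space(continuous = vars, solvents = solvents, descriptors = desc)
}

# Deterministic test-only surrogate families.
make_fun_model <- function(f) {
  structure(list(f = f), class = c("fun_surrogate", "surrogate_model"))
}
predict.fun_surrogate <- function(object, newdata, ...) {
  m <- object$f(as.matrix(newdata))
  data.frame(mean = m, sd = 0)
}
registerS3method("predict", "fun_surrogate", predict.fun_surrogate,
                 envir = asNamespace("stats"))

register_test_families <- function() {
  if (!"mean_only" %in% surrogate_families())
    register_surrogate_family("mean_only", function(X, y, seed, control) {
      make_fun_model(local({ m <- mean(y); function(Z) rep(m, nrow(Z)) }))
    })
  if (!"oracle_linear" %in% surrogate_families())
    register_surrogate_family("oracle_linear", function(X, y, seed, control) {
      b <- qr.solve(cbind(1, X), y)
      make_fun_model(function(Z) as.numeric(cbind(1, Z) %*% b))
    })
}
register_test_families()

# Shared stated-world objects for campaign-scale tests: one synthetic
# library (seed chosen once), its filtered 8-solvent training space, and
# calibrated ground-truth parameters.
shared_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lib <- make_library(20, seed = 42)
    flt <- filter_solvents(lib)
    sv8 <- select_training_solvents(flt$shortlist, 8, seed = 42)
    lib8 <- flt$shortlist[flt$shortlist$name %in% sv8, ]
    space <- space_from_library(
      lib8, overrides = flt$overrides[names(flt$overrides) %in% sv8])
    params <- calibrate_params(ground_truth_params(), lib)
    cache <<- list(library = lib, shortlist = flt$shortlist, lib8 = lib8,
                   space = space, params = params)
    cache
  }
})
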