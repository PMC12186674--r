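# Multiobjective core: Pareto dominance, exact 2-D hypervolume, joint
# batch EHVI by Monte Carlo with common random numbers, batch selection
# (greedy + swap hill-climbing, exhaustive on small pools), and bounded
# local refinement of a batch.
#
# Orientation everywhere: yield is maximized, cost is minimized.

#' Pareto dominance between two objective points
#'
#' `a` dominates `b` iff `a$yield >= b$yield` and `a$cost <= b$cost` with
#' at least one strict inequality. Identical points dominate neither.
#'
#' @param a,b lists or one-row data.frames with `yield` and `cost`.
#' @return logical flag.
#' @export
dominates <- function(a, b) {
  stopifnot(is.finite(a$yield), is.finite(a$cost),
            is.finite(b$yield), is.finite(b$cost))
  (a$yield >= b$yield && a$cost <= b$cost) &&
    (a$yield > b$yield || a$cost < b$cost)
}

#' Pareto front of a set of objective points
#'
#' @param points data.frame with `yield` and `cost` columns (>= 1 row).
#' @return the nondominated rows, ordered by cost ascending, with an
#'   `"index"` attribute giving their row numbers in `points`.
#' @export
pareto_front <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L)
  keep <- cpp_pareto_mask(points$yield, points$cost)
  idx <- which(keep)
  idx <- idx[order(points$cost[idx], points$yield[idx])]
  out <- points[idx, , drop = FALSE]
  attr(out, "index") <- idx
  out
}

#' Reference point for hypervolume
#'
#' Convention: yield reference 0 % and cost reference
#' `cost_factor * max(observed cost)`, recomputed from the evaluated data,
#' so the hypervolume is comparable across iterations within a run.
#'
#' @param points data.frame with `yield` and `cost`.
#' @param cost_factor multiplier on the maximum observed cost.
#' @return list with `yield` and `cost`.
#' @export
reference_point <- function(points, cost_factor = 1.1) {
  list(yield = 0, cost = cost_factor * max(points$cost))
}

#' Exact 2-D hypervolume
#'
#' Area dominated by the front and bounded by the reference point,
#' computed by a sorted sweep (exact in two objectives).
#'
#' @param front data.frame with `yield` and `cost` (may be empty).
#' @param ref reference point, list with `yield` (below all yields of
#'   interest) and `cost` (above all costs).
#' @return nonnegative area.
#' @export
hypervolume <- function(front, ref) {
  if (is.null(front) || nrow(front) == 0L) return(0)
  if (any(front$yield < ref$yield) || any(front$cost > ref$cost))
    stop_config("reference point must be worse than every front point")
  cpp_hv2d(front$yield, front$cost, ref$yield, ref$cost)
}

# Standard-normal draw matrix for common random numbers.
ehvi_draws <- function(n_draws, q, seed) {
  with_seed(derive_seed(seed, "ehvi_draws"),
            matrix(stats::rnorm(n_draws * q), nrow = n_draws, ncol = q))
}

#' Joint batch EHVI by Monte Carlo
#'
#' Expected hypervolume improvement of evaluating a batch jointly: yields
#' are sampled from each candidate's predictive normal (independently
#' across candidates), costs are analytic and fixed. The same seed yields
#' the same draw matrix, giving common random numbers across compared
#' batches.
#'
#' @param mu,sd predictive mean and sd of yield per candidate (length q).
#' @param cost deterministic cost per candidate (length q).
#' @param front current Pareto front (data.frame yield/cost).
#' @param ref reference point (see [hypervolume()]).
#' @param n_draws Monte Carlo sample size.
#' @param seed integer seed.
#' @param Z optional pre-drawn `n_draws x q` standard-normal matrix
#'   (overrides `seed`).
#' @return nonnegative EHVI estimate.
#' @export
ehvi_batch <- function(mu, sd, cost, front, ref, n_draws = 128, seed = 1L,
                       Z = NULL) {
  q <- length(mu)
  if (q < 1L) stop_config("batch must contain at least one candidate")
  stopifnot(length(sd) == q, length(cost) == q, all(sd >= 0))
  if (nrow(front) && (any(front$yield < ref$yield) ||
                      any(front$cost > ref$cost)))
    stop_config("reference point must be worse than every front point")
  if (is.null(Z)) Z <- ehvi_draws(n_draws, q, seed)
  cpp_joint_ehvi(front$yield %||% numeric(0), front$cost %||% numeric(0),
                 mu, sd, cost, ref$yield, ref$cost,
                 Z[, seq_len(q), drop = FALSE])
}

#' Per-candidate (q = 1) EHVI for a whole pool
#'
#' Shared draws across candidates (common random numbers).
#'
#' @inheritParams ehvi_batch
#' @return numeric vector, one EHVI per candidate.
#' @export
individual_ehvi <- function(mu, sd, cost, front, ref, n_draws = 128,
                            seed = 1L, z = NULL) {
  if (is.null(z)) z <- as.numeric(ehvi_draws(n_draws, 1L, seed))
  cpp_individual_ehvi(front$yield %||% numeric(0),
                      front$cost %||% numeric(0),
                      mu, sd, cost, ref$yield, ref$cost, z)
}

#' Select a batch maximizing joint EHVI
#'
#' Exhaustive enumeration when `choose(pool, q) <= exhaustive_limit`;
#' otherwise a shortlist of the strongest individual-EHVI candidates is
#' searched by greedy construction followed by pairwise swap hill-climbing.
#' The returned batch scores at least as high (under the same draws) as
#' the batch of the top-q individual-EHVI candidates and as every batch
#' visited during the search.
#'
#' @param mu,sd,cost predictive mean/sd and analytic cost for the whole
#'   candidate pool.
#' @param q batch size.
#' @param front,ref as in [ehvi_batch()].
#' @param seed integer seed (fixes the common draws).
#' @param n_draws Monte Carlo draws.
#' @param shortlist shortlist size for the greedy/swap search.
#' @param exhaustive_limit enumerate all subsets when the subset count is
#'   at or below this.
#' @return list with `batch` (indices into the pool), `joint_ehvi`,
#'   `individual_ehvi` (full pool), and `method`.
#' @export
select_batch <- function(mu, sd, cost, q, front, ref, seed = 1L,
                         n_draws = 128, shortlist = 25,
                         exhaustive_limit = 1e5) {
  m <- length(mu)
  if (m < q) stop_config("candidate pool (%d) smaller than batch size %d", m, q)
  Z <- ehvi_draws(n_draws, q, seed)
  joint <- function(idx) {
    ehvi_batch(mu[idx], sd[idx], cost[idx], front, ref,
               Z = Z[, seq_along(idx), drop = FALSE])
  }
  ind <- individual_ehvi(mu, sd, cost, front, ref, z = Z[, 1L])
  if (choose(m, q) <= exhaustive_limit) {
    combos <- utils::combn(m, q)
    vals <- apply(combos, 2, joint)
    best <- which.max(vals)
    return(list(batch = combos[, best], joint_ehvi = vals[best],
                individual_ehvi = ind, method = "exhaustive"))
  }
  cand <- order(ind, decreasing = TRUE)[seq_len(min(shortlist, m))]
  best_idx <- NULL; best_val <- -Inf
  note <- function(idx) {
    v <- joint(idx)
    if (v > best_val) { best_val <<- v; best_idx <<- idx }
    v
  }
  # greedy construction over the shortlist
  batch <- integer(0)
  for (slot in seq_len(q)) {
    avail <- setdiff(cand, batch)
    vals <- vapply(avail, function(i) joint(c(batch, i)), numeric(1))
    batch <- c(batch, avail[which.max(vals)])
  }
  cur_val <- note(batch)
  # pairwise swap hill-climbing
  for (pass in 1:3) {
    improved <- FALSE
    for (s in seq_len(q)) {
      for (i in setdiff(cand, batch)) {
        trial <- batch; trial[s] <- i
        v <- note(trial)
        if (v > cur_val + 1e-12) {
          batch <- trial; cur_val <- v; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  # never worse than the naive top-q individual batch
  note(order(ind, decreasing = TRUE)[seq_len(q)])
  list(batch = best_idx, joint_ehvi = best_val, individual_ehvi = ind,
       method = "greedy_swap")
}

#' Refine a batch by bounded local optimization
#'
#' Continuous coordinates only; each point's solvent stays fixed and its
#' (possibly solubility-overridden) bounds are respected. The joint EHVI is
#' optimized with L-BFGS-B under common random numbers, so the returned
#' batch never scores below the input batch; on any failure the input is
#' returned unchanged.
#'
#' @param batch data.frame of q conditions.
#' @param model fitted `surrogate_model` for yield.
#' @param encoder a [build_encoder()] (or design_space).
#' @param space the [design_space()].
#' @param front,ref as in [ehvi_batch()].
#' @param cost_fun function(conditions) -> analytic cost vector.
#' @param seed integer seed.
#' @param n_draws Monte Carlo draws.
#' @param maxit L-BFGS-B iteration cap.
#' @return list with `batch` (refined conditions), `ehvi_before`,
#'   `ehvi_after`.
#' @export
refine_batch <- function(batch, model, encoder, space, front, ref, cost_fun,
                         seed = 1L, n_draws = 128, maxit = 25) {
  if (inherits(encoder, "design_space")) encoder <- build_encoder(encoder)
  q <- nrow(batch)
  vars <- space$continuous
  nv <- nrow(vars)
  lower_b <- vars$lower
  upper_m <- vapply(batch$solvent, function(sv)
    solvent_upper_bounds(space, sv)[vars$name], numeric(nv))
  # scale to [0,1]^(q*nv)
  to_unit <- function(b) {
    vapply(seq_len(nv), function(j)
      (b[[vars$name[j]]] - lower_b[j]) / (upper_m[j, ] - lower_b[j]),
      numeric(q))
  }
  from_unit <- function(x) {
    U <- matrix(clamp(x, 0, 1), nrow = q)
    b <- batch
    for (j in seq_len(nv))
      b[[vars$name[j]]] <- lower_b[j] + U[, j] * (upper_m[j, ] - lower_b[j])
    b
  }
  Z <- ehvi_draws(n_draws, q, seed)
  score <- function(x) {
    b <- from_unit(x)
    p <- predict(model, encode_conditions(b, encoder))
    ehvi_batch(p$mean, pmax(p$sd, 0), cost_fun(b), front, ref, Z = Z)
  }
  x0 <- as.numeric(to_unit(batch))
  before <- score(x0)
  res <- tryCatch(
    stats::optim(x0, function(x) -score(x), method = "L-BFGS-B",
                 lower = 0, upper = 1,
                 control = list(maxit = maxit, factr = 1e10)),
    error = function(e) NULL)
  if (is.null(res) || -res$value < before)
    return(list(batch = batch, ehvi_before = before, ehvi_after = before))
  list(batch = from_unit(res$par), ehvi_before = before,
       ehvi_after = -res$value)
}
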