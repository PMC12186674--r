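# Closed-loop campaign: initialize (stratified LHS), propose (model
# selection -> candidate pool -> joint-EHVI batch -> refinement), update
# (append results, recompute front and hypervolume), stopping criteria,
# and the pool-based benchmarking harness.

#' Campaign configuration
#'
#' @param q batch size per iteration (default 5).
#' @param families surrogate families competing each iteration.
#' @param featurization `"raw_descriptors"` or `"pca_components"`.
#' @param pca_k principal components kept under PCA featurization.
#' @param pool_per_solvent LHS candidates drawn per allowed solvent each
#'   iteration (default 200).
#' @param n_draws Monte Carlo draws for EHVI.
#' @param shortlist shortlist size for the batch search.
#' @param refine_maxit L-BFGS-B iteration cap for refinement.
#' @param ref_cost_factor reference-point cost multiplier (default 1.1).
#' @param noise_sd configured experimental noise, % (default 1.8).
#' @param hv_rel_tol,patience,rmse_factor stopping thresholds (see
#'   [check_stopping()]).
#' @param prices a [price_table()].
#' @param limiting_mmol,solvent_volume_L cost-objective settings.
#' @param surrogate_control per-family control lists.
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(q = 5L,
                            families = c("gaussian_process", "boosted_trees"),
                            featurization = "raw_descriptors", pca_k = 3L,
                            pool_per_solvent = 200L, n_draws = 128L,
                            shortlist = 25L, refine_maxit = 25L,
                            ref_cost_factor = 1.1, noise_sd = 1.8,
                            hv_rel_tol = 0.01, patience = 2L,
                            rmse_factor = 2.0, prices = price_table(),
                            limiting_mmol = 0.2, solvent_volume_L = 0.005,
                            surrogate_control = list()) {
  structure(as.list(environment()), class = "campaign_config")
}

#' Start a campaign: stratified LHS design awaiting evaluation
#'
#' @param space a [design_space()].
#' @param n_init initial design size; a warning is logged below twice the
#'   number of variables (continuous + solvent choice).
#' @param seed master seed; all downstream randomness derives from it.
#' @param config a [campaign_config()].
#' @param solvent_prices named cost-per-litre vector (or `solvent_library`)
#'   used by the analytic cost objective.
#' @return object of class `campaign_state` with the design in `$pending`.
#' @export
initialize_campaign <- function(space, n_init, seed = 1L,
                                config = campaign_config(),
                                solvent_prices = NULL) {
  if (!inherits(space, "design_space")) stop_config("invalid design space")
  nvar <- nrow(space$continuous) + 1L
  if (n_init < 2 * nvar)
    warning(sprintf("n_init = %d is below 2 x %d variables", n_init, nvar))
  if (inherits(solvent_prices, "solvent_library"))
    solvent_prices <- stats::setNames(solvent_prices$price_per_L,
                                      solvent_prices$name)
  design <- lhs_sample(space, n_init, derive_seed(seed, "init_lhs"))
  structure(list(space = space, config = config, seed = as.integer(seed),
                 solvent_prices = solvent_prices,
                 pending = design,
                 evaluated = NULL,   # conditions + yield + cost
                 iteration = 0L,
                 hv_history = numeric(0),
                 front_history = list(),
                 model_reports = list(),
                 diagnostics = list()),
            class = "campaign_state")
}

#' @export
print.campaign_state <- function(x, ...) {
  cat(sprintf(paste0("<campaign_state> iteration %d: %d evaluated, ",
                     "%d pending, hypervolume %s\n"),
              x$iteration,
              if (is.null(x$evaluated)) 0L else nrow(x$evaluated),
              if (is.null(x$pending)) 0L else nrow(x$pending),
              if (length(x$hv_history))
                sprintf("%.4g", utils::tail(x$hv_history, 1)) else "-"))
  invisible(x)
}

campaign_cost_fun <- function(state) {
  cfg <- state$config
  function(conds) reaction_cost(conds, cfg$prices, state$solvent_prices,
                                cfg$limiting_mmol, cfg$solvent_volume_L)
}

#' Current Pareto front of a campaign
#' @param state a `campaign_state` with evaluated points.
#' @return data.frame of nondominated evaluated rows (cost ascending).
#' @export
campaign_front <- function(state) {
  if (is.null(state$evaluated)) stop_config("no evaluated points yet")
  pareto_front(state$evaluated)
}

#' Feed measured results back into a campaign
#'
#' Appends conditions with their measured objective values, recomputes the
#' Pareto front and hypervolume (data-driven reference point), and
#' increments the iteration counter. Exact duplicates of already-evaluated
#' conditions are kept with a warning (replicates are allowed).
#'
#' @param state a `campaign_state`.
#' @param conditions data.frame of evaluated conditions.
#' @param objectives data.frame with `yield` and `cost` (if `cost` is
#'   absent it is computed analytically).
#' @return updated `campaign_state`.
#' @export
update_campaign <- function(state, conditions, objectives) {
  stopifnot(inherits(state, "campaign_state"),
            nrow(conditions) == nrow(objectives), "yield" %in% names(objectives))
  ok <- validate_conditions(conditions, state$space)
  if (!all(ok))
    warning(paste(c("conditions outside declared bounds kept for the record:",
                    utils::head(attr(ok, "violations"), 5)), collapse = "\n"))
  cost <- if ("cost" %in% names(objectives)) objectives$cost
          else campaign_cost_fun(state)(conditions)
  new <- cbind(conditions[, c(state$space$continuous$name, "solvent")],
               yield = objectives$yield, cost = cost)
  if (!is.null(state$evaluated)) {
    key <- function(d) do.call(paste, c(d[, c(state$space$continuous$name,
                                              "solvent")], sep = "|"))
    if (any(key(new) %in% key(state$evaluated)))
      warning("duplicate condition(s) appended (replicates kept)")
    state$evaluated <- rbind(state$evaluated, new)
  } else state$evaluated <- new
  rownames(state$evaluated) <- NULL
  # drop matching rows from the pending design
  if (!is.null(state$pending) && nrow(state$pending)) {
    key <- function(d) do.call(paste, c(d[, c(state$space$continuous$name,
                                              "solvent")], sep = "|"))
    state$pending <- state$pending[!(key(state$pending) %in% key(new)), ,
                                   drop = FALSE]
  }
  ref <- reference_point(state$evaluated, state$config$ref_cost_factor)
  front <- pareto_front(state$evaluated)
  state$iteration <- state$iteration + 1L
  state$hv_history <- c(state$hv_history, hypervolume(front, ref))
  state$front_history[[state$iteration]] <- attr(front, "index")
  state
}

#' Propose the next batch of conditions
#'
#' Pipeline: cross-validated model selection over the configured families,
#' a fresh LHS candidate pool (`pool_per_solvent` per allowed solvent),
#' joint-EHVI batch selection, then bounded local refinement. All
#' randomness derives from `(state$seed, iteration)` unless `seed` is
#' given.
#'
#' @param state a `campaign_state` with >= 5 evaluated points.
#' @param q batch size (default from config).
#' @param seed optional integer seed override.
#' @return data.frame of q proposed conditions; acquisition diagnostics in
#'   `attr(, "diagnostics")` and the winning model report in
#'   `attr(, "model_report")`.
#' @export
propose <- function(state, q = NULL, seed = NULL) {
  cfg <- state$config
  q <- q %||% cfg$q
  if (is.null(state$evaluated) || nrow(state$evaluated) < 5L)
    stop_config("need at least 5 evaluated points before proposing")
  seed <- seed %||% derive_seed(state$seed, paste0("iter_", state$iteration))
  encoder <- build_encoder(state$space, cfg$featurization, cfg$pca_k)
  X <- encode_conditions(state$evaluated, encoder)
  y <- state$evaluated$yield
  sel <- select_best(X, y, cfg$families, seed = derive_seed(seed, "select"),
                     control = cfg$surrogate_control)
  pool <- lhs_sample(state$space,
                     cfg$pool_per_solvent * length(state$space$solvents),
                     derive_seed(seed, "cand_pool"))
  if (nrow(pool) < q) stop_config("candidate pool smaller than batch size")
  pred <- predict(sel$model, encode_conditions(pool, encoder))
  cost_fun <- campaign_cost_fun(state)
  cost <- cost_fun(pool)
  ref <- reference_point(state$evaluated, cfg$ref_cost_factor)
  front <- pareto_front(state$evaluated)
  bs <- select_batch(pred$mean, pmax(pred$sd, 0), cost, q, front, ref,
                     seed = derive_seed(seed, "batch"),
                     n_draws = cfg$n_draws, shortlist = cfg$shortlist)
  batch <- pool[bs$batch, , drop = FALSE]
  rownames(batch) <- NULL
  rf <- refine_batch(batch, sel$model, encoder, state$space, front, ref,
                     cost_fun, seed = derive_seed(seed, "refine"),
                     n_draws = cfg$n_draws, maxit = cfg$refine_maxit)
  diag <- list(iteration = state$iteration, seed = seed,
               selected_family = sel$report$family,
               cv_rmse = sel$report$cv_rmse, cv_r2 = sel$report$cv_r2,
               joint_ehvi_selected = bs$joint_ehvi,
               joint_ehvi_refined = rf$ehvi_after,
               batch_method = bs$method)
  out <- rf$batch
  attr(out, "diagnostics") <- diag
  attr(out, "model_report") <- sel$report
  attr(out, "all_reports") <- sel$reports
  attr(out, "acquisition") <- cbind(pool,
                                    pred_mean = pred$mean,
                                    pred_sd = pred$sd, cost = cost,
                                    ehvi = bs$individual_ehvi,
                                    selected = seq_len(nrow(pool)) %in%
                                      bs$batch)
  out
}

#' Run one propose/measure/update iteration against an oracle
#'
#' Convenience wrapper used by simulations: proposes a batch, evaluates it
#' with `measure(conditions)` (returning a yield vector), and updates the
#' state. The winning model report is appended to the state history.
#'
#' @param state a `campaign_state`.
#' @param measure function(conditions) -> numeric yields.
#' @param q batch size.
#' @return updated `campaign_state`.
#' @export
step_campaign <- function(state, measure, q = NULL) {
  batch <- propose(state, q = q)
  yields <- measure(batch)
  state <- update_campaign(state, batch, data.frame(yield = yields))
  state$model_reports[[length(state$model_reports) + 1L]] <-
    attr(batch, "model_report")
  state$diagnostics[[length(state$diagnostics) + 1L]] <-
    attr(batch, "diagnostics")
  state
}

#' Stopping decision for a campaign
#'
#' Three criteria: `hv_converged` — relative hypervolume improvement below
#' `hv_rel_tol` for `patience` consecutive iterations; `model_accurate` —
#' latest CV RMSE at or below `rmse_factor` times the configured noise sd;
#' `front_stable` — front membership unchanged over `patience` iterations
#' (advisory). The loop stops when `hv_converged` AND `model_accurate`.
#'
#' @param state a `campaign_state` with >= 2 iterations of history.
#' @param hv_rel_tol,patience,rmse_factor thresholds (defaults from
#'   config).
#' @return list with `stop` flag and `reasons` (character subset of
#'   `hv_converged`, `model_accurate`, `front_stable`).
#' @export
check_stopping <- function(state, hv_rel_tol = NULL, patience = NULL,
                           rmse_factor = NULL) {
  cfg <- state$config
  hv_rel_tol <- hv_rel_tol %||% cfg$hv_rel_tol
  patience <- patience %||% cfg$patience
  rmse_factor <- rmse_factor %||% cfg$rmse_factor
  hv <- state$hv_history
  if (length(hv) < 2L) stop_config("need at least 2 iterations of history")
  reasons <- character(0)
  rel <- abs(diff(hv)) / pmax(utils::head(hv, -1), .Machine$double.eps)
  if (length(rel) >= patience &&
      all(utils::tail(rel, patience) < hv_rel_tol))
    reasons <- c(reasons, "hv_converged")
  if (length(state$model_reports)) {
    last <- state$model_reports[[length(state$model_reports)]]
    if (last$cv_rmse <= rmse_factor * cfg$noise_sd)
      reasons <- c(reasons, "model_accurate")
  }
  fh <- state$front_history
  if (length(fh) >= patience + 1L) {
    recent <- fh[(length(fh) - patience):length(fh)]
    if (all(vapply(recent, identical, logical(1), recent[[1]])))
      reasons <- c(reasons, "front_stable")
  }
  list(stop = all(c("hv_converged", "model_accurate") %in% reasons),
       reasons = reasons)
}

#' Pool-based acquisition benchmark
#'
#' Replays an acquisition strategy against a fixed pool of already
#' evaluated conditions: starting from an initial subset, one pool member
#' is sampled per iteration (without replacement) — by highest q = 1 EHVI
#' under a surrogate refit after every sample, or uniformly at random —
#' and the hypervolume of the accumulated set is recorded. The reference
#' point is fixed from the full pool so curves are comparable.
#'
#' @param pool data.frame of conditions with `yield` and `cost` (e.g. from
#'   [make_pool()]).
#' @param space the [design_space()] the pool lives in.
#' @param init_idx integer indices of the initial training subset.
#' @param acquisition `"ehvi"` or `"random"`.
#' @param seeds integer vector; one learning curve per seed.
#' @param family surrogate family refit at every step (default
#'   `"gaussian_process"`).
#' @param n_steps number of samples to draw (default: exhaust the pool).
#' @param stop_hv optional hypervolume target; the run stops early once the
#'   accumulated set reaches it (used for samples-to-target statistics).
#' @param config a [campaign_config()] (EHVI draws, reference factor).
#' @return tidy data.frame (acquisition, seed, step, n_sampled, hv);
#'   `step = 0` rows hold the initial-subset hypervolume.
#' @export
pool_benchmark <- function(pool, space, init_idx,
                           acquisition = c("ehvi", "random"),
                           seeds = 1:5, family = "gaussian_process",
                           n_steps = NULL, stop_hv = NULL,
                           config = campaign_config()) {
  acquisition <- match.arg(acquisition)
  stopifnot(all(init_idx %in% seq_len(nrow(pool))))
  encoder <- build_encoder(space, config$featurization, config$pca_k)
  Xall <- encode_conditions(pool, encoder)
  ref <- reference_point(pool, config$ref_cost_factor)
  n_steps <- n_steps %||% (nrow(pool) - length(init_idx))
  out <- list()
  for (s in seeds) {
    sampled <- init_idx
    hv <- hypervolume(pareto_front(pool[sampled, ]), ref)
    rows <- data.frame(acquisition = acquisition, seed = s, step = 0L,
                       n_sampled = length(sampled), hv = hv)
    for (step in seq_len(n_steps)) {
      if (!is.null(stop_hv) && utils::tail(rows$hv, 1) >= stop_hv) break
      remaining <- setdiff(seq_len(nrow(pool)), sampled)
      if (!length(remaining)) break
      pick <- if (acquisition == "random") {
        with_seed(derive_seed(s, paste0("rand_", step)),
                  remaining[sample.int(length(remaining), 1L)])
      } else {
        m <- fit_surrogate(family, Xall[sampled, , drop = FALSE],
                           pool$yield[sampled],
                           seed = derive_seed(s, paste0("fit_", step)))
        p <- predict(m, Xall[remaining, , drop = FALSE])
        front <- pareto_front(pool[sampled, ])
        e <- individual_ehvi(p$mean, pmax(p$sd, 0), pool$cost[remaining],
                             front, ref, n_draws = config$n_draws,
                             seed = derive_seed(s, paste0("ehvi_", step)))
        remaining[which.max(e)]
      }
      sampled <- c(sampled, pick)
      rows <- rbind(rows, data.frame(
        acquisition = acquisition, seed = s, step = step,
        n_sampled = length(sampled),
        hv = hypervolume(pareto_front(pool[sampled, ]), ref)))
    }
    out[[length(out) + 1L]] <- rows
  }
  do.call(rbind, out)
}

#' Select a spread-out training subset of solvents
#'
#' Greedy maximin selection in the leading principal components of the
#' standardized descriptors: the training set of solvents should span the
#' descriptor space, mirroring a space-filling design over the discrete
#' dimension.
#'
#' @param library a `solvent_library`.
#' @param k number of solvents to select (default 8).
#' @param n_components principal components used (default 3).
#' @param seed seed choosing the starting solvent.
#' @return character vector of k solvent names.
#' @export
select_training_solvents <- function(library, k = 8, n_components = 3,
                                     seed = 1L) {
  stopifnot(k >= 1, k <= nrow(library))
  std <- standardize_descriptors(descriptor_matrix(library))
  S <- pca_reduce(std$standardized, min(n_components,
                                        ncol(std$standardized)))$scores
  chosen <- with_seed(derive_seed(seed, "solvent_start"),
                      sample.int(nrow(S), 1L))
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(nrow(S)), chosen)
    d <- vapply(rest, function(i)
      min(sqrt(rowSums((S[chosen, , drop = FALSE] -
                          matrix(S[i, ], length(chosen), ncol(S),
                                 byrow = TRUE))^2))), numeric(1))
    chosen <- c(chosen, rest[which.max(d)])
  }
  library$name[chosen]
}

#' Save a campaign state to JSON (+ campaign CSV alongside)
#'
#' @param state a `campaign_state`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_campaign <- function(state, path) {
  # 17 significant digits round-trip IEEE doubles bit-exactly through text
  ser <- list(seed = state$seed, iteration = state$iteration,
              hv_history = sprintf("%.17g", state$hv_history),
              front_history = state$front_history,
              evaluated = state$evaluated, pending = state$pending,
              solvent_prices = as.list(state$solvent_prices),
              space = list(continuous = state$space$continuous,
                           solvents = state$space$solvents,
                           descriptors = state$space$descriptors,
                           overrides = state$space$overrides),
              config = unclass(state$config)[
                setdiff(names(state$config), c("prices", "surrogate_control"))],
              prices = as.list(unclass(state$config$prices)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a campaign state saved with [save_campaign()]
#' @param path JSON path.
#' @return a `campaign_state`.
#' @export
load_campaign <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  desc <- as.matrix(j$space$descriptors)
  rownames(desc) <- j$space$solvents
  ov <- lapply(j$space$overrides, unlist)
  space <- design_space(continuous = j$space$continuous,
                        solvents = j$space$solvents,
                        descriptors = desc, overrides = ov)
  cfg_args <- j$config[names(j$config) %in% names(formals(campaign_config))]
  cfg <- do.call(campaign_config, cfg_args)
  cfg$prices <- do.call(price_table, j$prices[c("alkene", "he", "catalyst",
                                               "acid", "internal_standard")])
  state <- initialize_campaign(space, n_init = max(2L, 14L),
                               seed = j$seed, config = cfg,
                               solvent_prices = unlist(j$solvent_prices))
  state$pending <- if (is.null(j$pending) || !length(j$pending)) NULL
                   else as.data.frame(j$pending)
  state$evaluated <- if (is.null(j$evaluated)) NULL else
    as.data.frame(j$evaluated)
  state$iteration <- j$iteration
  state$hv_history <- as.numeric(j$hv_history %||% character(0))
  fh <- j$front_history
  if (is.matrix(fh)) fh <- lapply(seq_len(nrow(fh)), function(i) fh[i, ])
  if (!is.list(fh)) fh <- list(fh)
  state$front_history <- lapply(fh, as.integer)
  state
}
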