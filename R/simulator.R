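# Synthetic ground truth standing in for the flow reactor: a yield
# response surface with the qualitative structure observed in the real
# campaign, plus solvent-library and evaluated-pool generators. It is a
# response-surface stand-in, not a mechanistic kinetic model.

#' Ground-truth parameters for the yield simulator
#'
#' The surface is driven by absorbed photon dose (the product of catalyst
#' loading and residence time, saturating), increases with alkene and
#' Hantzsch ester equivalents (diminishing returns), carries mild positive
#' acid and temperature effects, and is penalized linearly in the
#' standardized sig3 solvent descriptor (asymmetry of the s-profile).
#' Replicate noise defaults to 1.8 % (homoscedastic Gaussian, the measured
#' reproducibility of the analytical setup).
#'
#' @param y_max plateau yield, % (default 85).
#' @param dose_scale saturation constant for photon dose, mol %%*min
#'   (default 30).
#' @param sig3_slope yield penalty per unit of standardized sig3
#'   (default 0.35).
#' @param alkene_exp,he_exp diminishing-returns exponents (defaults 0.8,
#'   0.6).
#' @param acid_slope,temp_slope mild positive effects (defaults 0.10,
#'   0.05).
#' @param noise_sd replicate noise sd, % (default 1.8).
#' @param sig3_center,sig3_scale standardization constants for sig3;
#'   calibrated to a library via [calibrate_params()].
#' @return list of class `ground_truth_params`.
#' @export
ground_truth_params <- function(y_max = 85, dose_scale = 30,
                                sig3_slope = 0.35, alkene_exp = 0.8,
                                he_exp = 0.6, acid_slope = 0.10,
                                temp_slope = 0.05, noise_sd = 1.8,
                                sig3_center = 0, sig3_scale = 1) {
  stopifnot(y_max > 0, y_max <= 100, noise_sd >= 0, dose_scale > 0,
            sig3_scale > 0)
  structure(list(y_max = y_max, dose_scale = dose_scale,
                 sig3_slope = sig3_slope, alkene_exp = alkene_exp,
                 he_exp = he_exp, acid_slope = acid_slope,
                 temp_slope = temp_slope, noise_sd = noise_sd,
                 sig3_center = sig3_center, sig3_scale = sig3_scale),
            class = "ground_truth_params")
}

#' Calibrate simulator parameters to a solvent library
#'
#' Sets the sig3 standardization constants to the library's mean and sd so
#' the solvent penalty spans the library realistically.
#'
#' @param params a [ground_truth_params()].
#' @param library a `solvent_library`.
#' @return updated params.
#' @export
calibrate_params <- function(params, library) {
  params$sig3_center <- mean(library$sig3)
  params$sig3_scale <- stats::sd(library$sig3)
  params
}

sig3_of <- function(conditions, library) {
  s <- stats::setNames(library$sig3, library$name)
  miss <- setdiff(unique(conditions$solvent), names(s))
  if (length(miss)) stop_config("solvent(s) not in library: %s",
                                paste(miss, collapse = ", "))
  as.numeric(s[conditions$solvent])
}

#' Noiseless true yield of the simulator
#'
#' `yield = y_max * sat(dose) * phi_alkene * phi_HE * phi_acid,T *
#' psi_solvent` with `dose = catalyst_molpct * time_min`,
#' `sat(d) = d / (d + dose_scale)`,
#' `phi_alkene = (alkene_eq / 2)^alkene_exp` (similarly HE), a mild linear
#' acid/temperature factor, and
#' `psi = clamp(1 - sig3_slope * standardized sig3, 0, 1)`; clipped to
#' [0, 100].
#'
#' @param conditions data.frame of conditions (vectorized).
#' @param library a `solvent_library` providing sig3 per solvent.
#' @param params a [ground_truth_params()].
#' @return numeric yield vector, %.
#' @export
true_yield <- function(conditions, library, params = ground_truth_params()) {
  dose <- conditions$catalyst_molpct * conditions$time_min
  sat <- dose / (dose + params$dose_scale)
  phi_a <- (conditions$alkene_eq / 2)^params$alkene_exp
  phi_h <- (conditions$he_eq / 2)^params$he_exp
  phi_at <- clamp(0.85 + params$acid_slope * (conditions$acid_eq - 0.1) / 0.9 +
                    params$temp_slope * (conditions$temp_C - 10) / 40, 0, 1)
  z3 <- (sig3_of(conditions, library) - params$sig3_center) / params$sig3_scale
  psi <- clamp(1 - params$sig3_slope * z3, 0, 1)
  clamp(params$y_max * sat * phi_a * phi_h * phi_at * psi, 0, 100)
}

#' Observe a noisy yield from the simulator
#'
#' True yield plus seeded Gaussian noise (sd = `noise_sd`), clipped to
#' [0, 100].
#'
#' @inheritParams true_yield
#' @param seed integer seed.
#' @return numeric yield vector, %.
#' @export
observe_yield <- function(conditions, library,
                          params = ground_truth_params(), seed = 1L) {
  mu <- true_yield(conditions, library, params)
  with_seed(seed,
            clamp(mu + stats::rnorm(length(mu), 0, params$noise_sd), 0, 100))
}

#' Generate a synthetic solvent library
#'
#' Descriptors are drawn from a seeded correlated multivariate normal;
#' prices and solubilities are lognormal. Constructed guarantees: at least
#' one solvent is flagged basic, at least one has HE solubility below the
#' working concentration (rejected by the filter), and at least one sits
#' between 1x and 2x the working concentration (exercising the
#' solubility-clamped upper bound).
#'
#' @param n_solvents number of solvents (>= 4 so the guarantees fit).
#' @param seed integer seed.
#' @param reaction_conc working concentration, mM (default 40).
#' @return a `solvent_library`.
#' @export
make_library <- function(n_solvents = 20, seed = 1L, reaction_conc = 40) {
  stopifnot(n_solvents >= 4)
  with_seed(seed, {
    mu <- c(sig0 = 100, sig2 = 60, sig3 = 2, sig4 = 6, sig5 = 4)
    sds <- c(25, 20, 1.2, 3, 2.5)
    R <- matrix(c(1.0, 0.5, 0.2, 0.3, 0.1,
                  0.5, 1.0, 0.4, 0.2, 0.3,
                  0.2, 0.4, 1.0, 0.1, 0.2,
                  0.3, 0.2, 0.1, 1.0, 0.4,
                  0.1, 0.3, 0.2, 0.4, 1.0), 5, 5)
    Sigma <- diag(sds) %*% R %*% diag(sds)
    D <- MASS::mvrnorm(n_solvents, mu, Sigma)
    colnames(D) <- names(mu)
    df <- data.frame(name = sprintf("solvent_%02d", seq_len(n_solvents)),
                     D,
                     price_per_L = stats::rlnorm(n_solvents, log(40), 0.6),
                     he_solubility_mM = stats::rlnorm(n_solvents, log(150), 0.8),
                     cat_solubility_mM = stats::rlnorm(n_solvents, log(2.5), 0.7),
                     is_basic = FALSE,
                     stringsAsFactors = FALSE)
    # constructed guarantees (deterministic post-edits)
    df$is_basic[n_solvents] <- TRUE
    o <- order(df$he_solubility_mM)
    if (!any(df$he_solubility_mM < reaction_conc))
      df$he_solubility_mM[o[1]] <- 0.75 * reaction_conc
    in_band <- df$he_solubility_mM >= reaction_conc &
      df$he_solubility_mM < 2 * reaction_conc
    if (!any(in_band)) df$he_solubility_mM[o[2]] <- 1.5 * reaction_conc
    as_solvent_library(df)
  })
}

#' Generate a synthetic evaluated pool
#'
#' `n` LHS conditions over `space`, evaluated with [observe_yield()] and
#' the analytic cost objective — a stand-in for a full campaign dataset
#' used by the pool benchmark.
#'
#' @param space a [design_space()].
#' @param n pool size (>= 10).
#' @param library a `solvent_library` (sig3 and prices).
#' @param params a [ground_truth_params()] (calibrated to `library`).
#' @param seed integer seed.
#' @param prices a [price_table()].
#' @param limiting_mmol,solvent_volume_L cost settings.
#' @return data.frame of conditions with `yield` and `cost` columns;
#'   attributes `params` and `seed` record provenance.
#' @export
make_pool <- function(space, n, library, params = NULL, seed = 1L,
                      prices = price_table(), limiting_mmol = 0.2,
                      solvent_volume_L = 0.005) {
  stopifnot(n >= 10)
  if (is.null(params))
    params <- calibrate_params(ground_truth_params(), library)
  conds <- lhs_sample(space, n, derive_seed(seed, "pool_lhs"))
  y <- observe_yield(conds, library, params, derive_seed(seed, "pool_obs"))
  cost <- reaction_cost(conds, prices, library, limiting_mmol,
                        solvent_volume_L)
  pool <- cbind(conds, yield = y, cost = cost)
  attr(pool, "params") <- params
  attr(pool, "seed") <- seed
  pool
}
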