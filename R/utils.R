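# Internal helpers shared across modules.

# Canonical continuous-variable order used in every encoding:
# alkene eq, Hantzsch ester eq, catalyst mol %, acid eq, temperature, time.
.VAR_ORDER <- c("alkene_eq", "he_eq", "catalyst_molpct", "acid_eq",
                "temp_C", "time_min")

# Campaign CSV column layout (fixed order, case-insensitive on read).
.CAMPAIGN_COLS <- c("alkene_eq", "catalyst_molpct", "he_eq", "acid_eq",
                    "temp_C", "time_min", "solvent", "cost", "yield_pct")

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Every source of randomness in a campaign (LHS, CV folds, Monte Carlo
#' draws, batch search) draws its own seed from the master seed through this
#' deterministic fan-out, so a whole loop replays bit-identically from one
#' integer. Result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param tag character label naming the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- as.double(master %% 2147483647)
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}
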