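# File formats: campaign CSV (fixed column layout), JSON run
# configuration, and the packaged example campaign.

#' Read a campaign CSV
#'
#' Fixed column layout (case-insensitive header, order-fixed):
#' `alkene_eq, catalyst_molpct, he_eq, acid_eq, temp_C, time_min, solvent,
#' cost, yield_pct`. Comma-separated, UTF-8, dot decimals. Parse errors
#' report row and column coordinates.
#'
#' @param path CSV file path.
#' @return data.frame with canonical column names and a `yield` alias
#'   column for the objective pipeline.
#' @export
read_campaign_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  got <- tolower(names(df))
  want <- tolower(.CAMPAIGN_COLS)
  miss <- setdiff(want, got)
  if (length(miss))
    stop_config("campaign CSV lacks column(s): %s", paste(miss, collapse = ", "))
  if (!identical(got[seq_along(want)], want))
    stop_config("campaign CSV columns must appear in the order: %s",
                paste(.CAMPAIGN_COLS, collapse = ", "))
  names(df) <- .CAMPAIGN_COLS
  num_cols <- setdiff(.CAMPAIGN_COLS, "solvent")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
    if (length(bad))
      stop_config("non-numeric value '%s' at row %d, column '%s'",
                  df[[cn]][bad[1]], bad[1], cn)
    df[[cn]] <- v
  }
  df$yield <- df$yield_pct
  df
}

#' Write a campaign CSV
#'
#' @param data data.frame of conditions with `yield` (or `yield_pct`) and
#'   `cost`, or a `campaign_state` (its evaluated table is written).
#' @param path output path.
#' @export
write_campaign_csv <- function(data, path) {
  if (inherits(data, "campaign_state")) data <- data$evaluated
  df <- as.data.frame(data)
  if (!"yield_pct" %in% names(df)) df$yield_pct <- df$yield
  utils::write.csv(df[, .CAMPAIGN_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' The packaged 16-run example campaign
#'
#' Sixteen flow photoredox amine-synthesis experiments (the highest- and
#' lowest-yield run for each of eight solvents from a training design),
#' with analytic cost in cost units and HPLC yield in %.
#'
#' @return data.frame of 16 rows (see [read_campaign_csv()] for columns).
#' @export
example_campaign <- function() {
  read_campaign_csv(system.file("extdata", "flow_campaign_16runs.csv",
                                package = "nemobo", mustWork = TRUE))
}

.CONFIG_KEYS <- c("seed", "q", "families", "featurization", "pca_k",
                  "pool_per_solvent", "n_draws", "shortlist",
                  "refine_maxit", "ref_cost_factor", "noise_sd",
                  "hv_rel_tol", "patience", "rmse_factor",
                  "solvent_library", "campaign_csv", "n_init",
                  "reaction_conc_mM", "limiting_mmol", "solvent_volume_L",
                  "prices", "optics")

#' Read and validate a JSON run configuration
#'
#' Known keys only (unknown keys are rejected): seeding, acquisition
#' settings, stopping thresholds, featurization, file references, cost
#' settings, and optical constants (`optics`: `epsilon`, default 1413.5
#' (mol/L)^-1 cm^-1 at 470 nm; `path_length_cm`; `A_max`).
#'
#' @param path JSON file path.
#' @return named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(j), .CONFIG_KEYS)
  if (length(unknown))
    stop_config("unknown configuration key(s): %s",
                paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, q = 5L, n_init = 48L,
                   families = c("gaussian_process", "boosted_trees"),
                   featurization = "raw_descriptors", pca_k = 3L,
                   pool_per_solvent = 200L, n_draws = 128L, shortlist = 25L,
                   refine_maxit = 25L, ref_cost_factor = 1.1,
                   noise_sd = 1.8, hv_rel_tol = 0.01, patience = 2L,
                   rmse_factor = 2.0, reaction_conc_mM = 40,
                   limiting_mmol = 0.2, solvent_volume_L = 0.005,
                   optics = list(epsilon = 1413.5, path_length_cm = 0.1,
                                 A_max = 2.0))
  utils::modifyList(defaults, j)
}

config_to_campaign <- function(rc) {
  prices <- if (is.null(rc$prices)) price_table() else
    do.call(price_table, as.list(rc$prices))
  campaign_config(q = rc$q, families = rc$families,
                  featurization = rc$featurization, pca_k = rc$pca_k,
                  pool_per_solvent = rc$pool_per_solvent,
                  n_draws = rc$n_draws, shortlist = rc$shortlist,
                  refine_maxit = rc$refine_maxit,
                  ref_cost_factor = rc$ref_cost_factor,
                  noise_sd = rc$noise_sd, hv_rel_tol = rc$hv_rel_tol,
                  patience = rc$patience, rmse_factor = rc$rmse_factor,
                  prices = prices, limiting_mmol = rc$limiting_mmol,
                  solvent_volume_L = rc$solvent_volume_L)
}
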