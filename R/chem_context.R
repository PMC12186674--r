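# A-priori chemistry layer: solvent library handling, descriptor
# standardization + PCA, the analytic cost objective, and single-wavelength
# Beer-Lambert photophysics.

.DESCRIPTOR_COLS <- c("sig0", "sig2", "sig3", "sig4", "sig5")
.LIBRARY_COLS <- c("name", .DESCRIPTOR_COLS, "price_per_L",
                   "he_solubility_mM", "cat_solubility_mM", "is_basic")

#' Read a solvent library from a delimited table
#'
#' Expected columns: `name`, five descriptor columns (by default the sigma
#' moments `sig0, sig2, sig3, sig4, sig5`; `sig3` is the asymmetry of the
#' s-profile), `price_per_L`, `he_solubility_mM`, `cat_solubility_mM`,
#' `is_basic`. Tab- or comma-separated, chosen by file extension.
#'
#' @param path file path (.tsv/.txt -> tab, otherwise comma).
#' @param descriptor_cols names of the five descriptor columns.
#' @return data.frame of class `solvent_library`.
#' @export
read_solvent_library <- function(path, descriptor_cols = .DESCRIPTOR_COLS) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_solvent_library(df, descriptor_cols)
}

#' Coerce a data.frame to a solvent library
#'
#' @param df data.frame with the library columns.
#' @param descriptor_cols names of the descriptor columns.
#' @return data.frame of class `solvent_library`.
#' @export
as_solvent_library <- function(df, descriptor_cols = .DESCRIPTOR_COLS) {
  need <- c("name", descriptor_cols, "price_per_L", "he_solubility_mM",
            "cat_solubility_mM", "is_basic")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("solvent library lacks column(s): %s",
                                paste(miss, collapse = ", "))
  if (anyDuplicated(df$name)) stop_config("solvent names must be unique")
  if (any(df$price_per_L < 0)) stop_config("prices must be >= 0")
  if (any(df$he_solubility_mM < 0) || any(df$cat_solubility_mM < 0))
    stop_config("solubilities must be >= 0")
  D <- as.matrix(df[, descriptor_cols])
  if (!all(is.finite(D))) stop_config("descriptors must be finite")
  df$is_basic <- as.logical(df$is_basic)
  attr(df, "descriptor_cols") <- descriptor_cols
  class(df) <- c("solvent_library", "data.frame")
  df
}

#' Write a solvent library to CSV
#' @param library a `solvent_library`.
#' @param path output path.
#' @export
write_solvent_library <- function(library, path) {
  utils::write.csv(as.data.frame(library), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

descriptor_matrix <- function(library) {
  cols <- attr(library, "descriptor_cols") %||% .DESCRIPTOR_COLS
  m <- as.matrix(as.data.frame(library)[, cols])
  rownames(m) <- library$name
  m
}

#' Shortlist solvents on a-priori criteria
#'
#' Removes inherently basic solvents (the reaction is acid-catalyzed) and
#' solvents whose Hantzsch ester solubility cannot support 1.0 eq at the
#' working concentration (solids block and scatter light). Retained
#' solvents whose HE solubility is below `max_eq * reaction_conc` receive a
#' solubility-clamped upper bound for `he_eq` so the solution stays clear.
#'
#' @param library a `solvent_library`.
#' @param reaction_conc limiting-reactant concentration, mM (default 40).
#' @param require_clear if TRUE (default) apply the solubility criteria.
#' @param max_eq global upper bound for HE equivalents (default 2.0).
#' @param max_cat_molpct,min_cat_molpct global catalyst-loading bounds,
#'   mol % (defaults 5.0 and 0.5). The reported catalyst solubility caps
#'   the usable loading per solvent (`100 * solubility / reaction_conc`);
#'   solvents that cannot dissolve even the minimum loading are rejected.
#' @return list with `shortlist` (a `solvent_library`, original order),
#'   `rejected` (data.frame name/reason), and `overrides` (named list
#'   solvent -> named upper-bound vector, e.g. `c(he_eq = 1.51)` or
#'   `c(catalyst_molpct = 3.2)`).
#' @export
filter_solvents <- function(library, reaction_conc = 40,
                            require_clear = TRUE, max_eq = 2.0,
                            max_cat_molpct = 5.0, min_cat_molpct = 0.5) {
  stopifnot(inherits(library, "solvent_library"), nrow(library) >= 1)
  reason <- rep(NA_character_, nrow(library))
  reason[library$is_basic] <- "basic"
  if (require_clear) {
    insol <- is.na(reason) & library$he_solubility_mM < reaction_conc
    reason[insol] <- "insoluble at 1.0 eq"
    cat_cap <- 100 * library$cat_solubility_mM / reaction_conc
    cat_bad <- is.na(reason) & cat_cap <= min_cat_molpct
    reason[cat_bad] <- "catalyst insoluble"
  }
  keep <- is.na(reason)
  shortlist <- library[keep, , drop = FALSE]
  overrides <- list()
  if (require_clear) {
    for (i in seq_len(nrow(shortlist))) {
      ov <- c()
      sol <- shortlist$he_solubility_mM[i]
      if (sol < max_eq * reaction_conc)
        ov <- c(ov, he_eq = clamp_upper_equivalents(sol, reaction_conc,
                                                    max_eq))
      cap <- round(100 * shortlist$cat_solubility_mM[i] / reaction_conc, 2)
      if (cap < max_cat_molpct) ov <- c(ov, catalyst_molpct = cap)
      if (length(ov)) overrides[[shortlist$name[i]]] <- ov
    }
  }
  if (nrow(shortlist) == 0L) warning("no solvents survive the filters")
  list(shortlist = shortlist,
       rejected = data.frame(name = library$name[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE),
       overrides = overrides)
}

#' Build a design space from a filtered solvent library
#'
#' @param library a `solvent_library` (already shortlisted).
#' @param continuous continuous variables (default Table-of-bounds values).
#' @param overrides per-solvent upper-bound overrides, e.g. from
#'   [filter_solvents()].
#' @return a [design_space()].
#' @export
space_from_library <- function(library,
                               continuous = default_continuous_variables(),
                               overrides = list()) {
  design_space(continuous = continuous, solvents = library$name,
               descriptors = descriptor_matrix(library),
               overrides = overrides)
}

#' Standardize a descriptor matrix
#'
#' Each column is centered and scaled to unit standard deviation; the
#' stored means and sds allow an exact back-transform.
#'
#' @param X numeric matrix (solvents x descriptors), >= 2 rows.
#' @return list with `standardized`, `center`, `scale`.
#' @export
standardize_descriptors <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_config("standardization needs at least 2 rows")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- sdv < .Machine$double.eps * 1e3
  if (any(zero))
    stop_config("degenerate descriptor column(s) with zero variance: %s",
                paste(colnames(X)[zero], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  list(standardized = Z, center = mu, scale = sdv)
}

#' Invert [standardize_descriptors()]
#' @param Z standardized matrix.
#' @param std the list returned by [standardize_descriptors()].
#' @return matrix on the original scale.
#' @export
unstandardize_descriptors <- function(Z, std) {
  sweep(sweep(as.matrix(Z), 2, std$scale, "*"), 2, std$center, "+")
}

#' Principal component reduction of standardized descriptors
#'
#' Deterministic PCA via singular value decomposition. Sign convention:
#' each loading vector is flipped so its largest-magnitude element is
#' positive, fixing the rotation across platforms.
#'
#' @param Z standardized matrix (see [standardize_descriptors()]).
#' @param k number of components, `1 <= k <= ncol(Z)`.
#' @return list with `scores` (rows x k), `loadings` (cols x k),
#'   `explained` (length-k fractions of total variance), and
#'   `explained_all` (all components; sums to 1).
#' @export
pca_reduce <- function(Z, k) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  if (k < 1 || k > p) stop_config("k must be in [1, %d]", p)
  s <- svd(scale(Z, center = TRUE, scale = FALSE))
  ev <- s$d^2 / sum(s$d^2)
  V <- s$v
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(Z, 2, colMeans(Z), "-") %*% V[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(Z)
  rownames(V) <- colnames(Z)
  list(scores = scores, loadings = V[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)], explained_all = ev)
}

#' Reagent price table
#'
#' Unit prices in cost units per mmol for the stoichiometric components;
#' solvent prices come from the library (`price_per_L`). The shipped
#' defaults are a synthetic toy table (the campaign's real prices are
#' supplied by the user), with an expensive Ir photocatalyst so catalyst
#' loading dominates cost.
#'
#' @param alkene,he,catalyst,acid,internal_standard unit prices per mmol.
#' @return named numeric vector of class `price_table`.
#' @export
price_table <- function(alkene = 0.5, he = 0.8, catalyst = 100,
                        acid = 0.05, internal_standard = 0) {
  p <- c(alkene = alkene, he = he, catalyst = catalyst, acid = acid,
         internal_standard = internal_standard)
  if (any(!is.finite(p)) || any(p < 0)) stop_config("prices must be >= 0")
  class(p) <- c("price_table", "numeric")
  p
}

#' Analytic reaction cost
#'
#' `cost = limiting_amount * (alkene_eq * p_alkene + he_eq * p_he +
#' acid_eq * p_acid + catalyst_molpct/100 * p_catalyst) +
#' solvent_volume * price_per_L`. Linear in every amount; deterministic, so
#' cost is treated as a noiseless objective in the acquisition.
#'
#' @param conditions data.frame of conditions (vectorized).
#' @param prices a [price_table()].
#' @param solvent_prices named numeric vector, cost units per litre per
#'   solvent label (or a `solvent_library`).
#' @param limiting_mmol amount of limiting reactant, mmol (default 0.2).
#' @param solvent_volume_L solvent volume per experiment, L (default 0.005).
#' @return numeric cost vector.
#' @export
reaction_cost <- function(conditions, prices, solvent_prices,
                          limiting_mmol = 0.2, solvent_volume_L = 0.005) {
  stopifnot(inherits(prices, "price_table"),
            limiting_mmol > 0, solvent_volume_L >= 0)
  if (inherits(solvent_prices, "solvent_library"))
    solvent_prices <- stats::setNames(solvent_prices$price_per_L,
                                      solvent_prices$name)
  miss <- setdiff(unique(conditions$solvent), names(solvent_prices))
  if (length(miss)) stop_config("no solvent price for: %s",
                                paste(miss, collapse = ", "))
  reagents <- limiting_mmol *
    (conditions$alkene_eq * prices[["alkene"]] +
     conditions$he_eq * prices[["he"]] +
     conditions$acid_eq * prices[["acid"]] +
     conditions$catalyst_molpct / 100 * prices[["catalyst"]])
  as.numeric(reagents + solvent_volume_L *
               solvent_prices[conditions$solvent])
}

#' Beer-Lambert absorbance
#'
#' `A = epsilon * c * l` with the decadic convention
#' `A = log10(I0 / I) = -log10(T)`.
#'
#' @param epsilon molar extinction coefficient, (mol/L)^-1 cm^-1.
#' @param concentration absorber concentration, mol/L.
#' @param path_length optical path length, cm.
#' @return absorbance in AU.
#' @export
absorbance <- function(epsilon, concentration, path_length) {
  if (any(c(epsilon, concentration, path_length) < 0))
    stop_config("absorbance inputs must be non-negative")
  epsilon * concentration * path_length
}

#' Maximum absorber concentration keeping the medium transparent
#'
#' Inverts Beer-Lambert at a target absorbance ceiling:
#' `c = A_max / (epsilon * l)`. Used to bound photocatalyst loading so
#' light penetration stays uniform across the reactor channel.
#'
#' @param epsilon molar extinction coefficient, (mol/L)^-1 cm^-1 (> 0).
#' @param path_length optical path length, cm (> 0).
#' @param A_max absorbance ceiling, AU (>= 0).
#' @return concentration in mol/L.
#' @export
max_transparent_concentration <- function(epsilon, path_length, A_max) {
  if (epsilon <= 0 || path_length <= 0)
    stop_config("epsilon and path_length must be > 0")
  if (A_max < 0) stop_config("A_max must be >= 0")
  A_max / (epsilon * path_length)
}
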