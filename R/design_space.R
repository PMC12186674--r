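#' Continuous reaction variable
#'
#' @param name variable name (one of the canonical campaign columns).
#' @param lower,upper finite bounds in the variable's own units; `lower < upper`.
#' @param units unit label (eq, mol %, degC, min).
#' @return one-row data.frame describing the variable.
#' @export
continuous_variable <- function(name, lower, upper, units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lower) || !is.finite(upper))
    stop_config("bounds for '%s' must be finite", name)
  if (!(lower < upper))
    stop_config("lower bound must be strictly below upper bound for '%s'", name)
  data.frame(name = name, lower = as.numeric(lower),
             upper = as.numeric(upper), units = units,
             stringsAsFactors = FALSE)
}

#' Default continuous bounds for the photoredox amine synthesis
#'
#' Six continuous variables: alkene (1,1-diphenylethylene) and Hantzsch
#' ester equivalents 1.0-2.0, Ir(ppy)3 photocatalyst 0.5-5.0 mol %,
#' propionic acid 0.1-1.0 eq, temperature 10-50 degC, residence time
#' 4-60 min.
#'
#' @return data.frame of six continuous variables in canonical order.
#' @export
default_continuous_variables <- function() {
  rbind(
    continuous_variable("alkene_eq",       1.0,  2.0, "eq"),
    continuous_variable("he_eq",           1.0,  2.0, "eq"),
    continuous_variable("catalyst_molpct", 0.5,  5.0, "mol %"),
    continuous_variable("acid_eq",         0.1,  1.0, "eq"),
    continuous_variable("temp_C",          10,   50,  "degC"),
    continuous_variable("time_min",        4,    60,  "min")
  )
}

#' Mixed continuous / discrete design space
#'
#' The discrete dimension is a solvent choice; each solvent carries a
#' fixed-length numeric descriptor vector (typically five COSMO sigma
#' moments). Per-solvent upper-bound overrides express solubility caps,
#' e.g. a Hantzsch ester equivalents ceiling in poorly solubilizing
#' solvents; lower bounds are always global.
#'
#' @param continuous data.frame of continuous variables
#'   (see [continuous_variable()]).
#' @param solvents character vector of unique solvent labels.
#' @param descriptors numeric matrix, one row per solvent (rownames =
#'   solvent labels), identical column count for all solvents.
#' @param overrides named list: solvent label -> named numeric vector of
#'   per-variable upper-bound overrides, each within the global bounds.
#' @return object of class `design_space`.
#' @export
design_space <- function(continuous = default_continuous_variables(),
                         solvents, descriptors, overrides = list()) {
  if (length(solvents) < 1L) stop_config("design space needs at least one solvent")
  if (anyDuplicated(solvents)) stop_config("solvent labels must be unique")
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) != length(solvents))
    stop_config("descriptor matrix must have one row per solvent")
  if (!all(is.finite(descriptors))) stop_config("descriptors must be finite")
  if (is.null(colnames(descriptors)))
    colnames(descriptors) <- paste0("d", seq_len(ncol(descriptors)))
  rownames(descriptors) <- solvents
  for (sv in names(overrides)) {
    if (!sv %in% solvents) stop_config("override names unknown solvent '%s'", sv)
    ov <- overrides[[sv]]
    for (v in names(ov)) {
      i <- match(v, continuous$name)
      if (is.na(i)) stop_config("override names unknown variable '%s'", v)
      if (ov[[v]] > continuous$upper[i] || ov[[v]] <= continuous$lower[i])
        stop_config("override for '%s' in '%s' must lie within global bounds", v, sv)
    }
  }
  structure(list(continuous = continuous, solvents = as.character(solvents),
                 descriptors = descriptors, overrides = overrides),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat("Design space:", nrow(x$continuous), "continuous variables,",
      length(x$solvents), "solvents,", length(x$overrides),
      "solvent-specific bound overrides\n")
  print(x$continuous, row.names = FALSE)
  invisible(x)
}

# Upper bounds for one solvent, with overrides applied.
solvent_upper_bounds <- function(space, solvent) {
  ub <- stats::setNames(space$continuous$upper, space$continuous$name)
  ov <- space$overrides[[solvent]]
  if (!is.null(ov)) ub[names(ov)] <- unlist(ov)
  ub
}

#' Validate conditions against a design space
#'
#' @param conditions data.frame with the six continuous columns and a
#'   `solvent` column.
#' @param space a [design_space()].
#' @return logical vector (one per row) with a `"violations"` attribute, a
#'   character vector describing every failed check.
#' @export
validate_conditions <- function(conditions, space) {
  stopifnot(is.data.frame(conditions))
  miss <- setdiff(c(space$continuous$name, "solvent"), names(conditions))
  if (length(miss)) stop_config("conditions lack column(s): %s",
                                paste(miss, collapse = ", "))
  ok <- rep(TRUE, nrow(conditions))
  viol <- character(0)
  bad_sv <- !(conditions$solvent %in% space$solvents)
  if (any(bad_sv)) {
    ok[bad_sv] <- FALSE
    viol <- c(viol, sprintf("row %d: unknown solvent '%s'",
                            which(bad_sv), conditions$solvent[bad_sv]))
  }
  for (i in which(!bad_sv)) {
    ub <- solvent_upper_bounds(space, conditions$solvent[i])
    for (v in space$continuous$name) {
      x <- conditions[[v]][i]
      lo <- space$continuous$lower[match(v, space$continuous$name)]
      if (!is.finite(x) || x < lo || x > ub[[v]]) {
        ok[i] <- FALSE
        viol <- c(viol, sprintf("row %d: %s = %g outside [%g, %g]",
                                i, v, x, lo, ub[[v]]))
      }
    }
  }
  attr(ok, "violations") <- viol
  ok
}

#' Latin hypercube sample over a mixed design space
#'
#' Continuous variables are sampled with a joint n-bin Latin hypercube
#' (each variable's range split into `n` equal bins, exactly one draw per
#' bin, uniform jitter within the bin). The solvent label is assigned by
#' stratification: `n` is divided as evenly as possible across the allowed
#' solvents and the assignment order is shuffled. Variables with a
#' per-solvent upper-bound override are linearly rescaled into the
#' overridden range for rows carrying that solvent.
#'
#' @param space a [design_space()].
#' @param n number of conditions (>= 1).
#' @param seed integer seed; the design is a pure function of
#'   `(space, n, seed)`.
#' @return data.frame of `n` conditions (six continuous columns + `solvent`).
#' @export
lhs_sample <- function(space, n, seed) {
  if (!inherits(space, "design_space")) stop_config("'space' must be a design_space")
  stopifnot(n >= 1)
  n <- as.integer(n)
  vars <- space$continuous
  with_seed(seed, {
    u <- vapply(seq_len(nrow(vars)), function(j) {
      (sample.int(n) - stats::runif(n)) / n
    }, numeric(n))
    if (n == 1L) u <- matrix(u, nrow = 1L)
    k <- length(space$solvents)
    counts <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
    solvent <- sample(rep(space$solvents, counts))
    cond <- as.data.frame(lapply(seq_len(nrow(vars)), function(j) {
      vars$lower[j] + u[, j] * (vars$upper[j] - vars$lower[j])
    }))
    names(cond) <- vars$name
    cond$solvent <- solvent
    # rescale overridden variables into the clamped range for their solvent
    for (sv in names(space$overrides)) {
      rows <- cond$solvent == sv
      if (!any(rows)) next
      ov <- space$overrides[[sv]]
      for (v in names(ov)) {
        j <- match(v, vars$name)
        lo <- vars$lower[j]; hi <- vars$upper[j]
        cond[[v]][rows] <- lo + (cond[[v]][rows] - lo) * (ov[[v]] - lo) / (hi - lo)
      }
    }
    rownames(cond) <- NULL
    cond
  })
}

#' Clamp reagent upper equivalents to a solubility limit
#'
#' When a reagent's solubility in a solvent cannot support the global
#' maximum equivalents at the working concentration, the solubility-implied
#' ratio becomes the upper bound (reported to 2 decimals), keeping the
#' reaction solution clear for uniform light penetration.
#'
#' @param solubility reagent solubility in the solvent, mmol/L.
#' @param base_concentration limiting-reactant concentration, mM.
#' @param max_eq global upper bound in equivalents.
#' @return clamped upper bound in equivalents.
#' @export
clamp_upper_equivalents <- function(solubility, base_concentration, max_eq) {
  if (any(c(solubility, base_concentration, max_eq) <= 0) ||
      any(!is.finite(c(solubility, base_concentration, max_eq))))
    stop_config("all inputs to clamp_upper_equivalents must be positive and finite")
  round(min(max_eq, solubility / base_concentration), 2)
}

#' Build a numeric encoder for conditions
#'
#' Encodings are the continuous values in the canonical order (alkene eq,
#' HE eq, catalyst mol %, acid eq, temperature, time) followed by the
#' solvent's descriptor vector, either raw or projected onto the leading
#' `k` principal components of the standardized descriptor matrix.
#'
#' @param space a [design_space()].
#' @param featurization `"raw_descriptors"` or `"pca_components"`.
#' @param k number of principal components kept when
#'   `featurization = "pca_components"`.
#' @return object of class `condition_encoder`.
#' @export
build_encoder <- function(space, featurization = c("raw_descriptors",
                                                   "pca_components"), k = 3) {
  featurization <- match.arg(featurization)
  D <- space$descriptors
  if (featurization == "pca_components") {
    std <- standardize_descriptors(D)
    p <- pca_reduce(std$standardized, k)
    feat <- p$scores
    colnames(feat) <- paste0("PC", seq_len(k))
  } else {
    feat <- D
  }
  structure(list(space = space, featurization = featurization, k = k,
                 features = feat,
                 feature_names = c(space$continuous$name, colnames(feat))),
            class = "condition_encoder")
}

#' Encode conditions as a numeric matrix
#'
#' @param conditions data.frame of conditions.
#' @param encoder a [build_encoder()] object (or a design_space, in which
#'   case a raw-descriptor encoder is built on the fly).
#' @return numeric matrix, one row per condition.
#' @export
encode_conditions <- function(conditions, encoder) {
  if (inherits(encoder, "design_space")) encoder <- build_encoder(encoder)
  stopifnot(inherits(encoder, "condition_encoder"))
  sv <- conditions$solvent
  bad <- setdiff(unique(sv), rownames(encoder$features))
  if (length(bad)) stop_config("unknown solvent label(s): %s",
                               paste(bad, collapse = ", "))
  cont <- as.matrix(conditions[, encoder$space$continuous$name, drop = FALSE])
  X <- cbind(cont, encoder$features[sv, , drop = FALSE])
  colnames(X) <- encoder$feature_names
  rownames(X) <- NULL
  X
}
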