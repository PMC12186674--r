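toy_library <- function() {
  as_solvent_library(data.frame(
    name = c("alpha", "pyr_like", "low_sol", "ipa_like", "beta", "lowcat"),
    sig0 = c(90, 110, 95, 80, 120, 85), sig2 = c(40, 55, 70, 45, 60, 50),
    sig3 = c(0.5, 2.4, 1.2, 3.0, 1.8, 2.2), sig4 = c(5, 7, 3, 8, 6, 4),
    sig5 = c(2, 4, 3, 6, 5, 3),
    price_per_L = c(30, 25, 50, 20, 80, 45),
    he_solubility_mM = c(200, 150, 39, 60.47, 95, 120),
    cat_solubility_mM = c(2, 3, 1, 1.2, 4, 0.1),
    is_basic = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)))
}

test_that("solvent filtering applies the basicity and solubility criteria", {
  flt <- filter_solvents(toy_library(), reaction_conc = 40)
  expect_equal(flt$rejected$reason[flt$rejected$name == "pyr_like"], "basic")
  expect_equal(flt$rejected$reason[flt$rejected$name == "low_sol"],
               "insoluble at 1.0 eq")
  # cannot dissolve even the minimum catalyst loading
  expect_equal(flt$rejected$reason[flt$rejected$name == "lowcat"],
               "catalyst insoluble")
  expect_setequal(flt$shortlist$name, c("alpha", "ipa_like", "beta"))
  # retained solvent below 2x working concentration gets a clamped HE
  # bound; a catalyst-solubility limit caps the loading the same way
  expect_equal(flt$overrides$ipa_like[["he_eq"]], 1.51)
  expect_equal(flt$overrides$ipa_like[["catalyst_molpct"]], 3.0)
  expect_null(flt$overrides$alpha)  # 2 mM at 40 mM is exactly 5 mol %
  # order preserved; reasons partition the removed set
  expect_equal(flt$shortlist$name, c("alpha", "ipa_like", "beta"))
  expect_equal(nrow(flt$rejected) + nrow(flt$shortlist), nrow(toy_library()))
})

test_that("solvent filtering is idempotent", {
  flt <- filter_solvents(toy_library())
  flt2 <- filter_solvents(flt$shortlist)
  expect_equal(as.data.frame(flt2$shortlist), as.data.frame(flt$shortlist))
  expect_equal(nrow(flt2$rejected), 0L)
  expect_equal(flt2$overrides, flt$overrides)
})

test_that("descriptor standardization centers, scales, and round-trips", {
  X <- descriptor_matrix(toy_library())
  std <- standardize_descriptors(X)
  expect_lt(max(abs(colMeans(std$standardized))), 1e-9)
  expect_lt(max(abs(apply(std$standardized, 2, sd) - 1)), 1e-9)
  expect_lt(max(abs(unstandardize_descriptors(std$standardized, std) - X)),
            1e-9)
  Xc <- cbind(X, const = 1)
  expect_error(standardize_descriptors(Xc), "const")
})

test_that("PCA matches the closed-form 2-D correlated case", {
  # two columns with sample correlation exactly rho: leading eigenvalue of
  # the 2x2 correlation matrix is (1 + rho), so the first-component
  # fraction is (1 + rho) / 2
  rho <- 0.9
  set.seed(1)
  n <- 50
  z <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n))))[, 2:3] * sqrt(n - 1)
  X <- cbind(x1 = z[, 1], x2 = rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  p <- pca_reduce(X, 2)
  expect_equal(p$explained[1], (1 + rho) / 2, tolerance = 1e-9)
  expect_equal(sum(p$explained_all), 1, tolerance = 1e-9)
})

test_that("full-rank PCA reconstructs the data and decorrelates scores", {
  Z <- standardize_descriptors(descriptor_matrix(toy_library()))$standardized
  p <- pca_reduce(Z, ncol(Z))
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  expect_false(is.unsorted(rev(p$explained_all)))
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - Z)), 1e-9)
  cv <- cov(p$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)
  # deterministic sign convention
  expect_identical(p$loadings, pca_reduce(Z, ncol(Z))$loadings)
  expect_error(pca_reduce(Z, 9), "k must be")
})

test_that("the analytic cost objective is the declared linear form", {
  cond <- data.frame(alkene_eq = 1.5, catalyst_molpct = 3.05, he_eq = 1.2,
                     acid_eq = 0.5, temp_C = 30, time_min = 20,
                     solvent = "alpha")
  zero <- price_table(0, 0, 0, 0, 0)
  expect_equal(reaction_cost(cond, zero, c(alpha = 1.0),
                             solvent_volume_L = 0.005), 0.005)
  cat_only <- price_table(0, 0, 10, 0, 0)
  expect_equal(reaction_cost(cond, cat_only, c(alpha = 0),
                             limiting_mmol = 0.2), 0.2 * 0.0305 * 10)
  cond2 <- cond; cond2$catalyst_molpct <- 2 * cond$catalyst_molpct
  expect_equal(reaction_cost(cond2, cat_only, c(alpha = 0)),
               2 * reaction_cost(cond, cat_only, c(alpha = 0)))
  # additive over components
  p_all <- price_table(0.5, 0.8, 100, 0.05)
  parts <- c(reaction_cost(cond, price_table(0.5, 0, 0, 0), c(alpha = 0)),
             reaction_cost(cond, price_table(0, 0.8, 0, 0), c(alpha = 0)),
             reaction_cost(cond, price_table(0, 0, 100, 0), c(alpha = 0)),
             reaction_cost(cond, price_table(0, 0, 0, 0.05), c(alpha = 0)))
  expect_equal(reaction_cost(cond, p_all, c(alpha = 0)), sum(parts))
  expect_error(reaction_cost(cond, p_all, c(beta = 1)), "no solvent price")
})

test_that("Beer-Lambert absorbance and its inverse agree with the optics", {
  expect_equal(absorbance(1413.5, 0.001, 0.1), 0.14, tolerance = 0.005 / 0.14)
  expect_equal(absorbance(1413.5, 0, 0.1), 0)
  expect_equal(absorbance(1413.5, 0.014, 0.1), 2, tolerance = 0.02)
  expect_equal(max_transparent_concentration(1413.5, 0.1, 2.0), 0.014149,
               tolerance = 1e-4)
  expect_equal(max_transparent_concentration(1413.5, 0.1, 0), 0)
  # exact mutual inverses
  for (A in c(0.14, 1, 2, 5)) {
    c_max <- max_transparent_concentration(1413.5, 0.1, A)
    expect_equal(absorbance(1413.5, c_max, 0.1), A, tolerance = 1e-12)
  }
  expect_error(absorbance(-1, 1, 1), "non-negative")
  expect_error(max_transparent_concentration(0, 1, 1), "> 0")
})
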