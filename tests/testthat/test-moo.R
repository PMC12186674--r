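pt <- function(y, c) list(yield = y, cost = c)

test_that("dominance follows the strict Pareto definition", {
  # trade-off pair: neither dominates
  expect_false(dominates(pt(71, 2.19), pt(26, 1.40)))
  expect_false(dominates(pt(26, 1.40), pt(71, 2.19)))
  # equal cost, strictly higher yield dominates
  expect_true(dominates(pt(10, 1.25), pt(3, 1.25)))
  # irreflexive
  expect_false(dominates(pt(10, 1.25), pt(10, 1.25)))
})

test_that("pareto_front matches the O(n^2) oracle on random clouds", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    pts <- data.frame(yield = round(runif(n, 0, 100), 1),
                      cost = round(runif(n, 0.5, 3), 2))
    f <- pareto_front(pts)
    expect_setequal(attr(f, "index"), oracle_pareto_idx(pts))
    expect_false(is.unsorted(f$cost))
    # idempotent (same rows; the index attribute is relative to the input)
    f2 <- pareto_front(f)
    expect_equal(f2$yield, f$yield)
    expect_equal(f2$cost, f$cost)
  }
  one <- data.frame(yield = 50, cost = 1)
  f1 <- pareto_front(one)
  expect_equal(f1$yield, 50)
  expect_equal(attr(f1, "index"), 1L)
})

test_that("the 16-run example campaign has the known 4-point front", {
  camp <- example_campaign()
  f <- pareto_front(data.frame(yield = camp$yield, cost = camp$cost))
  expect_equal(attr(f, "index"), c(14L, 10L, 1L, 9L))  # cost ascending
  expect_setequal(attr(f, "index"), oracle_pareto_idx(camp))
})

test_that("2-D hypervolume is exact", {
  expect_equal(hypervolume(data.frame(yield = numeric(0),
                                      cost = numeric(0)),
                           list(yield = 0, cost = 3)), 0)
  expect_equal(hypervolume(data.frame(yield = 50, cost = 1),
                           list(yield = 0, cost = 3)), 100)
  # 3-point fronts vs Monte-Carlo area oracle
  for (seed in 1:3) {
    set.seed(seed)
    front <- pareto_front(data.frame(yield = runif(8, 10, 90),
                                     cost = runif(8, 0.5, 2.5)))
    ref <- list(yield = 0, cost = 3)
    hv <- hypervolume(front, ref)
    expect_equal(hv, oracle_hv_mc(front, ref, n = 1e6, seed = seed + 10),
                 tolerance = 0.005)
  }
  expect_error(hypervolume(data.frame(yield = 50, cost = 5),
                           list(yield = 0, cost = 3)), "worse")
})

test_that("hypervolume is monotone under nondominated additions", {
  front <- data.frame(yield = c(20, 60), cost = c(1, 2))
  ref <- list(yield = 0, cost = 3)
  h0 <- hypervolume(front, ref)
  # dominated addition: unchanged
  expect_equal(hypervolume(pareto_front(rbind(front,
                                              data.frame(yield = 10, cost = 2.5))),
                           ref), h0)
  # nondominated in-box addition: strict increase
  expect_gt(hypervolume(pareto_front(rbind(front,
                                           data.frame(yield = 40, cost = 1.5))),
                        ref), h0)
})

test_that("EHVI handles the degenerate zero-uncertainty cases", {
  front <- data.frame(yield = c(20, 60), cost = c(1, 2))
  ref <- list(yield = 0, cost = 3)
  # dominated means with no uncertainty: zero improvement
  expect_equal(ehvi_batch(mu = c(10, 15), sd = c(0, 0), cost = c(2.5, 2.8),
                          front = front, ref = ref, seed = 1), 0)
  # single certain nondominated point: deterministic HV increment
  h0 <- hypervolume(front, ref)
  h1 <- hypervolume(pareto_front(rbind(front, data.frame(yield = 40,
                                                         cost = 1.5))), ref)
  expect_equal(ehvi_batch(40, 0, 1.5, front, ref, seed = 1), h1 - h0)
  expect_error(ehvi_batch(numeric(0), numeric(0), numeric(0), front, ref),
               "at least one")
})

test_that("Monte-Carlo EHVI matches 1-D quadrature within 1%", {
  front <- data.frame(yield = c(20, 45, 60), cost = c(0.8, 1.4, 2.1))
  ref <- list(yield = 0, cost = 3)
  cases <- list(c(50, 8, 1.0), c(65, 5, 2.5), c(30, 15, 0.6))
  for (cs in cases) {
    mc <- ehvi_batch(cs[1], cs[2], cs[3], front, ref, n_draws = 4096,
                     seed = 7)
    quad <- oracle_ehvi_quad(cs[1], cs[2], cs[3], front, ref)
    expect_equal(mc, quad, tolerance = 0.01)
  }
})

test_that("EHVI Monte-Carlo error shrinks like 1/sqrt(draws)", {
  front <- data.frame(yield = c(20, 60), cost = c(1, 2))
  ref <- list(yield = 0, cost = 3)
  est <- function(nd) vapply(1:40, function(s)
    ehvi_batch(50, 10, 1.5, front, ref, n_draws = nd, seed = s), numeric(1))
  ratio <- sd(est(4096)) / sd(est(1024))
  expect_lt(ratio, 0.75)  # ideal 0.5; generous stochastic slack
  expect_true(all(est(1024) >= 0))
})

test_that("select_batch equals the exhaustive argmax on small pools", {
  set.seed(21)
  m <- 8; q <- 2
  mu <- runif(m, 10, 80); sdv <- runif(m, 0, 10)
  cost <- runif(m, 0.5, 2.5)
  front <- data.frame(yield = c(30, 55), cost = c(1.0, 1.8))
  ref <- list(yield = 0, cost = 3)
  sel <- select_batch(mu, sdv, cost, q, front, ref, seed = 5)
  expect_equal(sel$method, "exhaustive")
  Z <- nemobo:::ehvi_draws(128, q, 5)
  combos <- combn(m, q)
  vals <- apply(combos, 2, function(i)
    ehvi_batch(mu[i], sdv[i], cost[i], front, ref, Z = Z))
  expect_setequal(sel$batch, combos[, which.max(vals)])
  expect_equal(sel$joint_ehvi, max(vals))
})

test_that("joint selection avoids redundant near-duplicates", {
  # A and A' are near-identical strong candidates; B is weaker but diverse.
  mu <- c(50, 50, 30); sdv <- c(0, 0, 0); cost <- c(2, 2.01, 0.5)
  front <- data.frame(yield = numeric(0), cost = numeric(0))
  ref <- list(yield = 0, cost = 10)
  for (lim in c(1e5, 0)) {  # exhaustive and greedy/swap paths
    sel <- select_batch(mu, sdv, cost, 2, front, ref, seed = 3,
                        exhaustive_limit = lim)
    expect_setequal(sel$batch, c(1L, 3L))
  }
  # the top-2 individual-EHVI batch would have been the duplicates
  ind <- individual_ehvi(mu, sdv, cost, front, ref, seed = 3)
  expect_equal(order(ind, decreasing = TRUE)[1:2], c(1L, 2L))
  # a candidate dominating everything is always selected
  mu2 <- c(80, 50, 30); cost2 <- c(0.4, 2, 1)
  sel2 <- select_batch(mu2, sdv, cost2, 2, front, ref, seed = 3)
  expect_true(1L %in% sel2$batch)
  expect_error(select_batch(mu, sdv, cost, 5, front, ref), "smaller than")
})

test_that("refinement improves EHVI within bounds", {
  sp <- toy_space()
  enc <- build_encoder(sp)
  # toy single-objective surface peaked at alkene_eq = 1.7
  model <- make_fun_model(function(Z) 100 - 50 * (Z[, 1] - 1.7)^2)
  front <- data.frame(yield = numeric(0), cost = numeric(0))
  ref <- list(yield = 0, cost = 3)
  cost_fun <- function(b) rep(1, nrow(b))
  batch <- lhs_sample(sp, 1, 4)
  batch$alkene_eq <- 1.3
  rf <- refine_batch(batch, model, enc, sp, front, ref, cost_fun, seed = 2)
  expect_gte(rf$ehvi_after, rf$ehvi_before)
  expect_equal(rf$batch$alkene_eq, 1.7, tolerance = 1e-3)
  expect_true(all(validate_conditions(rf$batch, sp)))
  # already-optimal batch is a fixed point (within tolerance)
  batch2 <- rf$batch
  rf2 <- refine_batch(batch2, model, enc, sp, front, ref, cost_fun, seed = 2)
  expect_equal(rf2$batch$alkene_eq, batch2$alkene_eq, tolerance = 1e-6)
})

test_that("refinement respects per-solvent overrides", {
  sp <- toy_space(2, overrides = list(S1 = list(he_eq = 1.51)))
  enc <- build_encoder(sp)
  model <- make_fun_model(function(Z) 50 * Z[, 2])  # wants maximal he_eq
  front <- data.frame(yield = numeric(0), cost = numeric(0))
  ref <- list(yield = 0, cost = 3)
  batch <- data.frame(alkene_eq = 1.5, he_eq = 1.2, catalyst_molpct = 2,
                      acid_eq = 0.5, temp_C = 30, time_min = 30,
                      solvent = c("S1", "S2"))
  rf <- refine_batch(batch, model, enc, sp, front, ref,
                     function(b) rep(1, nrow(b)), seed = 6)
  expect_lte(rf$batch$he_eq[rf$batch$solvent == "S1"], 1.51)
  expect_true(all(validate_conditions(rf$batch, sp)))
})
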