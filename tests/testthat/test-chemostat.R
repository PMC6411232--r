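p_def <- toy_params()

test_that("solve_at beta' = Inf reproduces the closed-form steady-state chain", {
  st <- toy_solve_at(10, Inf)
  expect_equal(unname(st$s["glc"]), 15 - 0.5 * 10, tolerance = 1e-10)
  expect_equal(unname(st$s["lac"]), 0.55 * 10, tolerance = 1e-10)
  expect_equal(st$sigma, 0.0022 * 5.5, tolerance = 1e-12)
  expect_equal(st$D, 8.1 / 348 - 0.0121, tolerance = 1e-10)
  expect_equal(st$X, 10 * st$D, tolerance = 1e-12)
  expect_true(st$feasible)
  # xi = 100: lactate secretion has ceased, death vanishes
  st2 <- toy_solve_at(100, Inf)
  expect_equal(unname(st2$s["lac"]), 0, tolerance = 1e-10)
  expect_equal(st2$D, 4.7 / 348, tolerance = 1e-10)
})

test_that("mass balance D(c_i - s_i) = X <u_i> holds at every reported state", {
  for (cfg in list(c(10, Inf), c(10, 0), c(50, 2000), c(100, 500))) {
    st <- suppressMessages(toy_solve_at(cfg[1], cfg[2]))
    for (m in names(st$s)) {
      cc <- if (m == "glc") p_def$c_g else 0
      resid <- st$D * (cc - st$s[[m]]) - st$X * st$u[[m]]
      expect_lt(abs(resid), 1e-8 * max(1, abs(st$D * cc)))
    }
  }
})

test_that("with no inhibiting metabolites beta = beta' exactly", {
  st <- toy_solve_at(10, 321)
  expect_equal(st$K, 1)
  expect_equal(st$beta_prime / st$K, 321)
})

test_that("solve_fixed_beta satisfies |beta'/K - beta| <= 1e-8 beta", {
  tox <- toxicity_model(K_inhib = c(lac = 8))
  st <- solve_fixed_beta(10, 100, toy_network(), toy_medium(), tox,
                         engine = toy_quadrature_engine())
  expect_lt(st$K, 1)
  expect_lt(abs(st$beta_prime / st$K - 100), 1e-6 * 100)
  # re-evaluating at the found beta' reproduces the state
  st2 <- solve_at(10, st$beta_prime, toy_network(), toy_medium(), tox,
                  engine = toy_quadrature_engine())
  expect_equal(st2$D, st$D, tolerance = 1e-9)
  # trivial brackets
  st0 <- solve_fixed_beta(10, 0, toy_network(), toy_medium(), tox,
                          engine = toy_quadrature_engine())
  expect_equal(st0$beta_prime, 0)
})

test_that("washout is flagged infeasible, empty polytopes produce flagged states", {
  # beta = Inf at xi = 25 sits in the toxicity-collapsed window (D < 0)
  st <- toy_solve_at(25, Inf)
  expect_false(st$feasible)
  expect_lt(st$D, 0)
  # a non-viable network yields a flagged state, not an error
  mn <- maintenance_network()
  st2 <- solve_at(1, Inf, mn, medium(character(0), numeric(0), numeric(0)))
  expect_false(st2$feasible)
  expect_match(st2$note, "empty polytope")
})

test_that("classify_stability follows the sign of dD/dxi", {
  expect_equal(classify_stability(1:3, c(3, 2, 1)),
               c("stable", "stable", "stable"))
  expect_equal(classify_stability(1:3, c(1, 2, 1))[2], "unstable")
  fl <- classify_stability(1:4, c(2, 1, 3, 2), feasible = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(fl[2], "infeasible")
  expect_error(classify_stability(1:2, c(1, 2)), "at least 3")
})

test_that("the unstable window exists at large beta and vanishes at beta = 0", {
  xg <- seq(2, 120, by = 4)
  sw <- suppressMessages(toy_sweep(xg, c(0, 50 / p_def$lambda_m)))
  hi <- sw[sw$beta > 0 & sw$feasible, ]
  lo <- sw[sw$beta == 0 & sw$feasible, ]
  expect_gt(sum(hi$stability == "unstable"), 0)
  expect_equal(sum(lo$stability == "unstable"), 0)
  # D decreases monotonically along the feasible beta = 0 branch
  expect_true(all(diff(lo$D) < 0))
})

test_that("medium depth: bisection matches closed form and grows with beta", {
  expect_equal(toy_medium_depth(Inf), 570, tolerance = 1e-5)
  expect_equal(toy_medium_depth(Inf, toy_params(tau = 0)),
               toy_medium_depth_fba(toy_params(tau = 0)), tolerance = 1e-5)
  md <- vapply(c(10, 200, 50 / p_def$lambda_m), toy_medium_depth, numeric(1))
  expect_true(all(diff(md) > 0))
  expect_true(all(md < 570))
})

test_that("phase_diagram labels regions and extracts boundaries", {
  xg <- seq(2, 120, by = 6)
  solve_fun <- function(xi, beta) suppressMessages(toy_solve_at(xi, beta))
  pd <- phase_diagram(c(0, 50 / p_def$lambda_m), xg, solve_fun)
  tb <- pd$table
  expect_setequal(unique(tb$region),
                  intersect(c("infeasible", "stable", "unstable"),
                            unique(tb$region)))
  # at beta = 0 no unstable cells; at high beta some
  expect_equal(sum(tb$region == "unstable" & tb$beta == 0), 0)
  expect_gt(sum(tb$region == "unstable" & tb$beta > 0), 0)
  # beyond the largest feasible xi everything is infeasible
  b <- pd$boundaries[pd$boundaries$beta == 0, ]
  expect_true(all(tb$region[tb$beta == 0 & tb$xi > b$xi_m] == "infeasible"))
  # unstable window endpoints are consistent
  bh <- pd$boundaries[pd$boundaries$beta > 0, ]
  expect_true(is.na(b$unstable_lo))
  expect_false(is.na(bh$unstable_lo))
  expect_lte(bh$unstable_lo, bh$unstable_hi)
})

test_that("cost perturbations preserve the qualitative sweep features", {
  # a costed toy variant with a binding crowding budget
  net <- toy_network()
  net$cost <- setNames(c(0.5, 0.2, 6, 0.05), net$reaction_ids)
  net$budget <- 3
  pert <- perturb_costs(net, 0.25, seed = 42)
  xg <- seq(5, 100, by = 5)
  D_of <- function(nw) vapply(xg, function(xi) {
    st <- suppressMessages(solve_at(xi, Inf, nw, toy_medium(), toy_toxicity(),
                                    engine = "fba"))
    st$D
  }, numeric(1))
  d0 <- D_of(net); d1 <- D_of(pert)
  # qualitative features: an increasing (unstable) segment, a washout window,
  # and recovery at large xi are all preserved under the 25% perturbation
  feats <- function(d) c(any(diff(d) > 0), any(d < 0), d[length(d)] > 0)
  expect_equal(feats(d1), feats(d0))
})

test_that("X crossing occurs iff toxicity is active", {
  xg <- seq(30, 100, by = 10)
  b <- 50 / p_def$lambda_m
  with_tox <- vapply(xg, function(xi) {
    fin <- suppressMessages(toy_solve_at(xi, b))
    fba <- suppressMessages(toy_solve_at(xi, Inf))
    fin$X - fba$X
  }, numeric(1))
  expect_gt(max(with_tox), 0)
  p0 <- toy_params(tau = 0)
  no_tox <- vapply(xg, function(xi) {
    fin <- suppressMessages(toy_solve_at(xi, b, p0))
    fba <- suppressMessages(toy_solve_at(xi, Inf, p0))
    fin$X - fba$X
  }, numeric(1))
  expect_true(all(no_tox <= 1e-10))
})

test_that("chemostat_sweep output table is well-formed", {
  xg <- c(5, 10, 20)
  sw <- suppressMessages(toy_sweep(xg, c(0, Inf)))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 6L)
  expect_true(all(c("xi", "beta", "beta_prime", "D", "X", "K", "sigma",
                    "s_glc", "s_lac", "u_glc", "u_lac", "stability",
                    "feasible", "engine", "converged") %in% names(sw)))
  expect_true(all(diff(sw$xi[sw$beta == 0]) > 0))
  expect_error(suppressMessages(toy_sweep(c(5, 5), 0)), "increasing")
  sw_empty <- suppressMessages(toy_sweep(xg, numeric(0)))
  expect_equal(nrow(sw_empty), 0L)
})
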