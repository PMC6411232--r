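test_that("uptake_bound implements U = min(V, c/xi) with the xi = 0 convention", {
  expect_equal(uptake_bound(15, 0.5, 10), 0.5)     # min(0.5, 1.5)
  expect_equal(uptake_bound(15, 0.5, 100), 0.15)   # min(0.5, 0.15)
  expect_equal(uptake_bound(15, 0.5, 0), 0.5)      # no supply limitation
  expect_equal(uptake_bound(Inf, 0.3, 50), 0.3)    # infinite feed: kinetic cap
  expect_equal(unname(uptake_bound(c(a = 15, b = 0), c(0.5, 0), 10)),
               c(0.5, 0))
  expect_error(uptake_bound(-1, 0.5, 1), "non-negative")
  expect_error(uptake_bound(1, -0.5, 1), "non-negative")
})

test_that("growth_inhibition matches the multiplicative form and its limits", {
  tox <- toxicity_model(K_inhib = c(nh4 = 1.05, lac = 8))
  expect_equal(growth_inhibition(c(nh4 = 0, lac = 0), tox), 1)
  expect_equal(growth_inhibition(c(nh4 = 1.05, lac = 8), tox), 0.25)
  expect_equal(growth_inhibition(c(nh4 = 1.05, lac = 0), tox), 0.5)
  expect_equal(growth_inhibition(c(other = 99), tox), 1) # absent => s = 0
  expect_error(growth_inhibition(c(nh4 = -1), tox), "negative")
  # non-increasing in each coordinate, always in (0, 1]
  set.seed(11)
  for (i in 1:20) {
    s1 <- c(nh4 = runif(1, 0, 20), lac = runif(1, 0, 20))
    s2 <- s1 + c(runif(1, 0, 5), 0)
    k1 <- growth_inhibition(s1, tox); k2 <- growth_inhibition(s2, tox)
    expect_lte(k2, k1)
    expect_gt(k1, 0); expect_lte(k1, 1)
  }
})

test_that("death_rate is the linear form sum(tau_i s_i)", {
  tox <- toxicity_model(tau = c(lac = 0.0022))
  expect_equal(death_rate(c(lac = 0), tox), 0)
  expect_equal(death_rate(c(lac = 5.5), tox), 0.0121)
  expect_equal(death_rate(c(lac = 7), toxicity_model(tau = c(lac = 0))), 0)
  set.seed(12)
  s <- sort(runif(10, 0, 30))
  d <- vapply(s, function(x) death_rate(c(lac = x), tox), numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("net_growth combines z, K and sigma as lambda = z K - sigma", {
  tox0 <- toxicity_model()
  expect_equal(net_growth(0.02, c(lac = 3), tox0), 0.02)
  tox <- toxicity_model(tau = c(lac = 0.0022))
  expect_equal(net_growth(8.1 / 348, c(lac = 5.5), tox),
               8.1 / 348 - 0.0121, tolerance = 1e-12)
  expect_lte(net_growth(0, c(lac = 4), tox), 0)
})

test_that("split_reversible produces non-negative pairs and is invertible", {
  mets <- "m"
  S <- matrix(1, 1, 1, dimnames = list(mets, "r"))
  net <- metabolic_network(mets, "r", S, lb = -Inf, ub = Inf,
                           exchange_ids = "m",
                           excretable = c(m = TRUE),
                           biomass = list(kind = "affine",
                                          weights = c(r = 1), e = 0, y = 1))
  sp <- split_reversible(net)
  expect_true(sp$split)
  expect_equal(length(sp$reaction_ids), 2L)
  expect_true(all(sp$lb == 0))
  v <- setNames(c(2.5, 1.25), sp$reaction_ids)
  expect_equal(unname(reassemble_fluxes(sp, v)), 1.25)

  # reverse-only flux becomes a single flipped excretion variable
  toy <- split_reversible(toy_network())
  expect_true("v_l__rev" %in% toy$reaction_ids)
  expect_equal(unname(toy$lb["v_l__rev"]), 0)
  expect_false(any(grepl("v_l__fwd", toy$reaction_ids)))

  # irreversible networks pass through unchanged (up to the split flag)
  two <- two_path_network()
  sp2 <- split_reversible(two)
  expect_equal(sp2$reaction_ids, two$reaction_ids)
  expect_equal(unname(sp2$lb), unname(two$lb))

  # splitting then reassembling is the identity on a feasible point
  P <- build_polytope(toy, toy_medium(), 10)
  v <- fba_solve(P)
  nets <- reassemble_fluxes(toy, v[toy$reaction_ids])
  expect_equal(unname(nets["v_l"]), unname(-v[["v_l__rev"]]))
  expect_equal(unname(nets["v_g"]), unname(v[["v_g"]]))
})

test_that("metabolic_network validates its invariants", {
  S <- matrix(1, 1, 1, dimnames = list("m", "r"))
  bio <- list(kind = "affine", weights = c(r = 1), e = 0, y = 1)
  expect_error(metabolic_network("m", "r", S, lb = 1, ub = 0, biomass = bio),
               "lb > ub.*r")
  expect_error(metabolic_network("m", "r", S, lb = 0, ub = 1,
                                 exchange_ids = "ghost", biomass = bio),
               "unknown exchange")
  expect_error(metabolic_network("m", "r", S, lb = 0, ub = 1,
                                 cost = c(r = -1), biomass = bio),
               "non-negative")
  expect_error(metabolic_network("m", "r", S, lb = 0, ub = 1, budget = 0,
                                 biomass = bio), "budget")
})

test_that("build_polytope encodes the balances, crowding row and z tilt", {
  net <- split_reversible(toy_network())
  P <- build_polytope(net, toy_medium(), 10)
  # one equality row per balanced metabolite, no crowding row (C = Inf)
  expect_equal(nrow(P$E), 4L)
  expect_false("crowding_slack" %in% P$var_names)
  # with a finite budget the crowding row appears with its slack in [0, C]
  two <- split_reversible(two_path_network(budget = 5))
  P2 <- build_polytope(two, medium("sub", 10, 1), 1)
  expect_equal(nrow(P2$E), 3L)
  expect_true("crowding_slack" %in% P2$var_names)
  expect_equal(unname(P2$u["crowding_slack"]), 5)
  # z is affine with finite coefficients
  expect_true(all(is.finite(P$w)))
  v <- fba_solve(P)
  expect_equal(polytope_z(P, v), (v[["v_atp"]] - 1) / 348)
})

test_that("toy polytope at xi = 10 projects onto the hand-derived 2-D region", {
  net <- split_reversible(toy_network())
  P <- build_polytope(net, toy_medium(), 10)
  U <- 0.5; R <- 0.45
  # completion of (v_g, v_atp) is unique given the equalities; feasibility of
  # the completion must coincide with membership in the eliminated region
  completion_ok <- function(x, t) {
    vo <- (t - 2 * x) / 18
    w <- 2 * x - vo            # excreted intermediate = -v_l
    v <- c(v_g = x, v_l__rev = w, v_o = vo, v_atp = t,
           upt__glc = x, upt__lac = 0, exc__lac = w)
    all(v >= P$l - 1e-9) && all(v <= P$u + 1e-9) &&
      max(abs(as.numeric(P$E %*% v[P$var_names]) - P$d)) < 1e-9
  }
  in_region <- function(x, t)
    x >= 0 && x <= U && t >= 2 * x && t <= min(38 * x, 2 * x + 18 * R)
  set.seed(42)
  for (i in 1:200) {
    x <- runif(1, -0.1, 0.7); t <- runif(1, -1, 12)
    expect_equal(completion_ok(x, t), in_region(x, t))
  }
})

test_that("polytopes are nested in xi and the xi = Inf limit closes uptakes", {
  net <- split_reversible(toy_network())
  P1 <- build_polytope(net, toy_medium(), 20)
  P2 <- build_polytope(net, toy_medium(), 80)
  # vertices of the tighter polytope satisfy the looser one's constraints
  set.seed(7)
  for (i in 1:12) {
    obj <- rnorm(length(P2$l))
    sol <- lp_over_polytope_test(P2, obj)
    v <- sol$v
    expect_true(all(v >= P1$l - 1e-8))
    expect_true(all(v <= P1$u + 1e-8))
    expect_lt(max(abs(as.numeric(P1$E %*% v) - P1$d)), 1e-8)
  }
  # xi = Inf: all finite-feed uptakes close; the toy stays feasible (origin)
  Pinf <- build_polytope(net, toy_medium(), Inf)
  expect_equal(unname(Pinf$u["upt__glc"]), 0)
  expect_false(polytope_is_empty(Pinf))
  # a network whose maintenance cannot be met is empty, not an error
  mn <- split_reversible(maintenance_network())
  Pm <- build_polytope(mn, medium(character(0), numeric(0), numeric(0)), 1)
  expect_true(polytope_is_empty(Pm))
})
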