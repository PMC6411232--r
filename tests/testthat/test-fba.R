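test_that("fba_solve reproduces the toy closed form across xi", {
  net <- split_reversible(toy_network())
  med <- toy_medium()
  for (xi in c(0, 5, 10, 30, 66, 100, 400)) {
    P <- build_polytope(net, med, xi)
    v <- fba_solve(P)
    want <- toy_fba_vertex(xi)
    expect_equal(attr(v, "z"), unname(want["z"]), tolerance = 1e-9)
    expect_equal(unname(v["v_g"]), unname(want["v_g"]), tolerance = 1e-9)
    expect_equal(unname(-v["v_l__rev"]), unname(want["v_l"]), tolerance = 1e-9)
    # quadrature beta = Inf agrees too
    expect_equal(toy_moments(xi, Inf)$z_mean, unname(want["z"]),
                 tolerance = 1e-12)
  }
})

test_that("the enzymatic-cost tie-break selects the cheap path", {
  net <- split_reversible(two_path_network(cost_a = 1, cost_b = 2))
  P <- build_polytope(net, medium("sub", 100, 1), 1)
  v <- fba_solve(P)
  expect_gt(v[["path_a"]], 0.9)
  expect_lt(v[["path_b"]], 1e-8)
  # swapping the costs swaps the carrier
  net2 <- split_reversible(two_path_network(cost_a = 3, cost_b = 0.5))
  v2 <- fba_solve(build_polytope(net2, medium("sub", 100, 1), 1))
  expect_lt(v2[["path_a"]], 1e-8)
  expect_gt(v2[["path_b"]], 0.9)
})

test_that("fba_solve reports infeasibility and unboundedness explicitly", {
  mn <- split_reversible(maintenance_network())
  Pm <- build_polytope(mn, medium(character(0), numeric(0), numeric(0)), 1)
  expect_error(fba_solve(Pm), "infeasible")
  # unbounded z: a free production loop with no bound
  S <- matrix(1, 1, 1, dimnames = list("m", "r"))
  un <- metabolic_network("m", "r", S, lb = 0, ub = Inf,
                          exchange_ids = "m", excretable = c(m = TRUE),
                          biomass = list(kind = "affine",
                                         weights = c(r = 1), e = 0, y = 1))
  Pu <- build_polytope(split_reversible(un),
                       medium(character(0), numeric(0), numeric(0)), 1)
  expect_error(fba_solve(Pu), "unbounded")
})

test_that("reduce_network drops zero-flux reactions and preserves the rest", {
  # toy network plus a dead-end dummy reaction that can never carry flux
  p <- toy_params()
  mets <- c("glc", "lac", "intermediate", "atp", "dead")
  rxns <- c("v_g", "v_l", "v_o", "v_atp", "dummy")
  S <- matrix(0, 5, 5, dimnames = list(mets, rxns))
  S["glc", "v_g"] <- -1; S["intermediate", "v_g"] <- 2; S["atp", "v_g"] <- 2
  S["lac", "v_l"] <- -1; S["intermediate", "v_l"] <- 1
  S["intermediate", "v_o"] <- -1; S["atp", "v_o"] <- 18
  S["atp", "v_atp"] <- -1
  S["dead", "dummy"] <- 1; S["atp", "dummy"] <- -1  # dead end: must be 0
  net <- metabolic_network(
    mets, rxns, S, lb = c(0, -Inf, 0, 0, 0),
    ub = c(p$V_g, 0, p$R, Inf, 10),
    exchange_ids = c("glc", "lac"), excretable = c(glc = FALSE, lac = TRUE),
    biomass = list(kind = "affine", weights = c(v_atp = 1), e = p$e, y = p$y))
  grid <- c(1, 10, 50, 200)
  red <- reduce_network(net, toy_medium(), xi_grid = grid)
  rep <- attr(red, "reduction_report")
  expect_true("dummy" %in% rep$removed_reactions)
  expect_true("dead" %in% rep$removed_metabolites)
  expect_setequal(red$reaction_ids, c("v_g", "v_l", "v_o", "v_atp"))

  # idempotence on the same grid
  red2 <- reduce_network(red, toy_medium(), xi_grid = grid)
  expect_setequal(red2$reaction_ids, red$reaction_ids)
  expect_setequal(red2$metabolite_ids, red$metabolite_ids)

  # support preservation: reduced solutions equal full-network solutions
  full <- split_reversible(net)
  reds <- split_reversible(red)
  for (xi in grid) {
    vf <- fba_solve(build_polytope(full, toy_medium(), xi))
    vr <- fba_solve(build_polytope(reds, toy_medium(), xi))
    nf <- reassemble_fluxes(full, vf[full$reaction_ids])
    nr <- reassemble_fluxes(reds, vr[reds$reaction_ids])
    expect_equal(nr, nf[names(nr)], tolerance = 1e-8)
  }
})

test_that("reduce_network reports infeasible grid points instead of dropping them", {
  mn <- maintenance_network()
  red <- reduce_network(mn, medium(character(0), numeric(0), numeric(0)),
                        xi_grid = c(1, 10))
  rep <- attr(red, "reduction_report")
  expect_equal(rep$skipped_xi, c(1, 10))
})

test_that("perturb_costs is reproducible, bounded and identity at 0", {
  net <- two_path_network(cost_a = 1, cost_b = 2)
  expect_equal(perturb_costs(net, 0, seed = 5)$cost, net$cost)
  p1 <- perturb_costs(net, 0.25, seed = 5)
  p2 <- perturb_costs(net, 0.25, seed = 5)
  expect_identical(p1$cost, p2$cost)
  expect_true(all(p1$cost >= 0.75 * net$cost & p1$cost <= 1.25 * net$cost))
  expect_false(identical(p1$cost, perturb_costs(net, 0.25, seed = 6)$cost))
})
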