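p_def <- toy_params()

test_that("toy parameter invariants and the growth-rate calibration hold", {
  expect_equal(p_def$lambda_m, (2 * 0.5 + 18 * 0.45 - 1) / 348)
  # calibration intent: maximum growth rate near 1/day
  expect_gt(p_def$lambda_m, 0.02)
  expect_lt(p_def$lambda_m, 0.03)
  expect_error(toy_params(y = 0))
})

test_that("toy_fba_vertex matches the vertex-enumeration oracle", {
  for (xi in c(0, 5, 10, 40, 100, 300)) {
    U <- min(p_def$V_g, if (xi > 0) p_def$c_g / xi else Inf)
    V <- toy_polygon_vertices(U, p_def$R)
    vstar <- V[which.max(V[, 2]), ]
    got <- toy_fba_vertex(xi)
    expect_equal(unname(got["v_g"]), unname(vstar[1]), tolerance = 1e-10)
    expect_equal(unname(got["v_atp"]), unname(vstar[2]), tolerance = 1e-10)
  }
  v10 <- toy_fba_vertex(10)
  expect_equal(unname(v10[c("v_g", "v_o", "v_l", "v_atp")]),
               c(0.5, 0.45, -0.55, 9.1))
  expect_equal(unname(v10["z"]), 8.1 / 348, tolerance = 1e-12)
  v100 <- toy_fba_vertex(100)
  expect_equal(unname(v100[c("v_g", "v_o", "v_l", "v_atp")]),
               c(0.15, 0.30, 0, 5.7))
  expect_equal(unname(v100["z"]), 4.7 / 348, tolerance = 1e-12)
  # lactate secretion vanishes exactly at and beyond xi = 2 c_g / R
  thr <- 2 * p_def$c_g / p_def$R
  expect_equal(unname(toy_fba_vertex(thr)["v_l"]), 0, tolerance = 1e-12)
  expect_equal(unname(toy_fba_vertex(thr + 50)["v_l"]), 0)
  expect_lt(toy_fba_vertex(thr - 5)["v_l"], 0)
})

test_that("toy_network limits: R = 0 is purely fermentative, V_g = 0 is inert", {
  net0 <- split_reversible(toy_network(toy_params(R = 0)))
  P <- build_polytope(net0, toy_medium(toy_params(R = 0)), 10)
  v <- fba_solve(P)
  expect_equal(unname(v["v_atp"]), 2 * unname(v["v_g"]), tolerance = 1e-9)
  pV0 <- toy_params(V_g = 0)
  netV0 <- split_reversible(toy_network(pV0))
  PV0 <- build_polytope(netV0, toy_medium(pV0), 10)
  vv <- fba_solve(PV0)
  expect_equal(max(abs(vv)), 0, tolerance = 1e-10)
  expect_lt(attr(vv, "z"), 0)  # cannot cover maintenance
})

test_that("beta = 0 quadrature moments equal the exact polygon centroid", {
  for (xi in c(5, 10, 40)) {  # U = V_g regime and supply-limited regime
    U <- min(p_def$V_g, p_def$c_g / xi)
    ctr <- polygon_centroid(toy_polygon_vertices(U, p_def$R))$centroid
    m <- toy_moments(xi, 0)
    expect_equal(unname(m$mean["v_g"]), ctr[1], tolerance = 1e-9)
    expect_equal(unname(m$mean["v_atp"]), ctr[2], tolerance = 1e-9)
  }
})

test_that("quadrature moments converge monotonically to the FBA vertex", {
  xi <- 10
  vstar <- toy_fba_vertex(xi)
  betas <- c(10, 50, 200, 1000, 5000, 2e4) / p_def$lambda_m
  dist <- vapply(betas, function(b) {
    m <- toy_moments(xi, b)
    sqrt(sum((m$mean - vstar[names(m$mean)])^2))
  }, numeric(1))
  expect_true(all(diff(dist) < 0))
  expect_lt(dist[length(dist)], 1e-3)
  minf <- toy_moments(xi, Inf)
  expect_equal(minf$mean, vstar[names(minf$mean)], tolerance = 1e-12)
  expect_equal(max(minf$var), 0)
})

test_that("<z> is non-decreasing in beta and logZ non-increasing in xi", {
  zs <- vapply(c(0, 5, 20, 100, 500, 2000), function(b)
    toy_moments(10, b)$z_mean, numeric(1))
  expect_true(all(diff(zs) > 0))
  lz <- vapply(c(1, 10, 31, 60, 120, 400), function(x)
    toy_moments(x, 10)$logZ, numeric(1))
  expect_true(all(diff(lz) <= 1e-10))
})

test_that("quadrature agrees with rejection sampling within 3 MC errors", {
  P <- box_polytope(build_polytope(split_reversible(toy_network()),
                                   toy_medium(), 10))
  n <- 1e5
  for (b in c(0, 20, 300)) {
    m <- toy_moments(10, b)
    s <- rejection_sample(P, b, n = n, seed = 123)
    sm <- sample_moments(s, polytope = P)
    for (vn in c("v_g", "v_atp")) {
      col <- if (vn == "v_g") "v_g" else "v_atp"
      expect_lt(abs(sm$mean[[col]] - m$mean[[vn]]), 3 * sm$error_est[[col]])
    }
    expect_lt(abs(sm$z_mean - m$z_mean),
              3 * sqrt(sm$z_var / n) + 1e-12)
  }
})

test_that("medium depth at beta = Inf: closed form, e = 0, and c_g scaling", {
  expect_equal(toy_medium_depth_fba(), 38 * 15 / 1, tolerance = 1e-9)
  d0 <- toy_medium_depth_fba(toy_params(e = 0))
  expect_true(is.infinite(d0))
  expect_true(isTRUE(attr(d0, "open_ended")))
  d2 <- toy_medium_depth_fba(toy_params(c_g = 30))
  expect_equal(d2, 2 * toy_medium_depth_fba(), tolerance = 1e-6)
})
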