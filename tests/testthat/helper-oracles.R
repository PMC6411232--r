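# Independent oracles used across tests. These deliberately avoid the package
# code paths they are meant to check.

# Vertices of the 2-D toy region {0 <= x <= U, 2x <= t <= min(38x, 2x+18R)},
# enumerated by intersecting constraint lines and filtering, then ordered
# counter-clockwise around the centroid.
toy_polygon_vertices <- function(U, R) {
  lines <- list(
    c(1, 0, 0),        # x = 0
    c(1, 0, U),        # x = U
    c(-2, 1, 0),       # t = 2x
    c(-38, 1, 0),      # t = 38x
    c(-2, 1, 18 * R))  # t = 2x + 18R
  pts <- list()
  for (i in seq_along(lines)) for (j in seq_along(lines)) {
    if (j <= i) next
    A <- rbind(lines[[i]][1:2], lines[[j]][1:2])
    b <- c(lines[[i]][3], lines[[j]][3])
    if (abs(det(A)) < 1e-12) next
    pts[[length(pts) + 1L]] <- solve(A, b)
  }
  ok <- Filter(function(p) {
    x <- p[1]; t <- p[2]
    x >= -1e-9 && x <= U + 1e-9 && t >= 2 * x - 1e-9 &&
      t <= min(38 * x, 2 * x + 18 * R) + 1e-9
  }, pts)
  V <- unique(round(do.call(rbind, ok), 10))
  ctr <- colMeans(V)
  V[order(atan2(V[, 2] - ctr[2], V[, 1] - ctr[1])), , drop = FALSE]
}

# Exact polygon area and centroid by triangulation from the first vertex
# (shoelace), independent of any quadrature.
polygon_centroid <- function(V) {
  n <- nrow(V)
  A <- 0; cx <- 0; cy <- 0
  for (i in 2:(n - 1)) {
    x1 <- V[1, 1]; y1 <- V[1, 2]
    x2 <- V[i, 1]; y2 <- V[i, 2]
    x3 <- V[i + 1, 1]; y3 <- V[i + 1, 2]
    a <- 0.5 * abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
    A <- A + a
    cx <- cx + a * (x1 + x2 + x3) / 3
    cy <- cy + a * (y1 + y2 + y3) / 3
  }
  list(area = A, centroid = c(cx / A, cy / A))
}

# Truncated-normal moments by adaptive numerical integration (oracle for the
# closed-form kernel). Integrates in standardized coordinates with the peak
# density factored out so deep-tail truncations stay well scaled.
truncnorm_oracle <- function(mu, s2, a, b) {
  s <- sqrt(s2)
  al <- (a - mu) / s; be <- (b - mu) / s
  t0 <- if (al > 0) al else if (be < 0) be else 0  # closest point to the mode
  g <- function(t) exp(-(t^2 - t0^2) / 2)
  Z <- integrate(g, al, be, rel.tol = 1e-12, abs.tol = 0)$value
  m1 <- integrate(function(t) t * g(t), al, be, rel.tol = 1e-12,
                  abs.tol = 1e-13 * Z)$value / Z
  v1 <- integrate(function(t) (t - m1)^2 * g(t), al, be, rel.tol = 1e-11,
                  abs.tol = 1e-13 * Z)$value / Z
  c(mean = mu + s * m1, var = s2 * v1)
}

# A 3-metabolite, 2-path network with identical growth yield but different
# enzymatic costs (the lexicographic tie-break fixture).
two_path_network <- function(cost_a = 1, cost_b = 2, budget = Inf) {
  mets <- c("sub", "prod")
  rxns <- c("path_a", "path_b", "drain")
  S <- matrix(0, 2, 3, dimnames = list(mets, rxns))
  S["sub", "path_a"] <- -1; S["prod", "path_a"] <- 1
  S["sub", "path_b"] <- -1; S["prod", "path_b"] <- 1
  S["prod", "drain"] <- -1
  metabolic_network(mets, rxns, S, lb = c(0, 0, 0), ub = c(10, 10, 10),
                    exchange_ids = "sub",
                    excretable = c(sub = FALSE),
                    cost = c(path_a = cost_a, path_b = cost_b, drain = 0),
                    budget = budget,
                    biomass = list(kind = "affine", weights = c(drain = 1),
                                   e = 0, y = 1))
}

# A network whose maintenance demand cannot be met without uptake: one
# metabolite with e > 0 and no producing reaction once uptake is capped.
maintenance_network <- function(e = 1) {
  mets <- c("atp")
  rxns <- c("make_atp")
  S <- matrix(c(1), 1, 1, dimnames = list(mets, rxns))
  metabolic_network(mets, rxns, S, lb = 0, ub = 0.1,
                    exchange_ids = character(),
                    maintenance = c(atp = e),
                    biomass = list(kind = "affine",
                                   weights = c(make_atp = 1), e = 0, y = 1))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * max(1, abs(expected)))
}

# LP access for property tests (vertex probing in random directions)
lp_over_polytope_test <- function(P, obj, maximize = TRUE)
  maxentcc:::lp_over_polytope(P, obj, maximize = maximize)
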