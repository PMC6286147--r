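test_that("line-of-sight neighborhoods match the midpoint rule", {
  two <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(edges_matrix(find_neighbors(two)), cbind(1L, 2L))

  # the middle of three collinear cells sits exactly on the far pair's
  # midpoint, which blocks that edge (ties block)
  coll <- matrix(c(0, 0, 0, 2, 0, 0, 4, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(edges_matrix(find_neighbors(coll)),
               rbind(c(1L, 2L), c(2L, 3L)))

  set.seed(31)
  for (rep in 1:12) {
    n <- sample(20:60, 1)
    pos <- matrix(rnorm(3 * n) * 3, n, 3)
    expect_equal(edges_matrix(find_neighbors(pos)), brute_force_los(pos))
  }
  expect_equal(nrow(find_neighbors(matrix(0, 1, 3))), 0)
  expect_error(find_neighbors(rbind(c(0, 0, 0), c(0, 0, 0))), "coincident")
})

test_that("voronoi_cutoff mode equals brute-force Delaunay within the cutoff", {
  set.seed(17)
  for (rep in 1:3) {
    pos <- matrix(runif(30) * 6, 10, 3)
    ours <- edges_matrix(find_neighbors(pos, mode = "voronoi_cutoff",
                                        cutoff = 1e6))
    ref <- delaunay_brute(pos)
    ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
    expect_equal(ours, unname(ref))
  }
  # cutoff filters long Delaunay edges
  pos <- matrix(runif(30) * 6, 10, 3)
  all_e <- find_neighbors(pos, mode = "voronoi_cutoff", cutoff = 1e6)
  cut_e <- find_neighbors(pos, mode = "voronoi_cutoff", cutoff = 3)
  len <- sqrt(rowSums((pos[cut_e$i, , drop = FALSE] -
                       pos[cut_e$j, , drop = FALSE])^2))
  expect_true(all(len <= 3))
  expect_true(nrow(cut_e) <= nrow(all_e))
})

test_that("neighbor exchanges report gained and lost edges", {
  old <- find_neighbors(matrix(c(0, 0, 0, 2, 0, 0, 4, 0, 0), 3, 3,
                               byrow = TRUE))
  new <- find_neighbors(matrix(c(0, 0, 0, 2, 3, 0, 4, 0, 0), 3, 3,
                               byrow = TRUE))
  ex <- neighbor_exchanges(old, new)
  # moving the middle cell aside unblocks the outer pair: edge (1,3) gained
  expect_true(any(ex$event == "gained" & ex$i == 1 & ex$j == 3))
  expect_identical(nrow(neighbor_exchanges(old, old)), 0L)

  # intercalation during convergent extension produces exchange events
  set.seed(15)
  st <- make_hollow_sphere(150, pcp_whirl = TRUE, lambda = c(0.2, 0.5, 0.3))
  sim1 <- simulate_cells(st, 200, model_config(dt = 0.2, eta = 1e-4))
  sim2 <- simulate_cells(sim1$state, 200, model_config(dt = 0.2, eta = 1e-4))
  ex <- neighbor_exchanges(sim1$graph, sim2$graph)
  expect_gt(nrow(ex), 0)
  expect_true(all(ex$event %in% c("gained", "lost")))
})

test_that("polarity factors reproduce their extreme and degenerate cases", {
  z <- c(0, 0, 1); x <- c(1, 0, 0); y <- c(0, 1, 0)
  expect_identical(polarity_factor_s1(z, z, x), 1)
  expect_identical(polarity_factor_s1(z, -z, x), -1)
  expect_equal(polarity_factor_s1(x, rand_unit(), x), 0)
  expect_identical(polarity_factor_s2(z, x, z, x), 1)
  expect_equal(polarity_factor_s2(z, z, z, x), 0)
  expect_identical(polarity_factor_s3(y, y, x), 1)
  expect_identical(polarity_factor_s3(y, -y, x), -1)
  expect_error(polarity_factor_s1(2 * z, z, x), "unit norm")
})

test_that("polarity factors agree with the cross-product oracle and stay bounded", {
  set.seed(7)
  for (rep in 1:20) {
    p_i <- rand_unit(); p_j <- rand_unit()
    q_i <- rand_unit(); q_j <- rand_unit()
    rh <- rand_unit()
    expect_equal(polarity_factor_s1(p_i, p_j, rh),
                 sum(cross_ref(p_i, rh) * cross_ref(p_j, rh)),
                 tolerance = 1e-12)
    expect_equal(polarity_factor_s2(p_i, q_i, p_j, q_j),
                 sum(cross_ref(p_i, q_i) * cross_ref(p_j, q_j)),
                 tolerance = 1e-12)
    expect_equal(polarity_factor_s3(q_i, q_j, rh),
                 sum(cross_ref(q_i, rh) * cross_ref(q_j, rh)),
                 tolerance = 1e-12)
    # S1 is symmetric under swapping the cells with the reversed separation
    expect_equal(polarity_factor_s1(p_i, p_j, rh),
                 polarity_factor_s1(p_j, p_i, -rh), tolerance = 1e-12)
    vals <- c(polarity_factor_s1(p_i, p_j, rh),
              polarity_factor_s2(p_i, q_i, p_j, q_j),
              polarity_factor_s3(q_i, q_j, rh))
    expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
  }
})

test_that("coupling applies the mixed-cell mean rule and the angle gate", {
  expect_equal(coupling(1, 0, 0, c(1, 0, 0)), 1)
  # cells with different polarity types average their weights
  expect_equal(coupling(1, 1, 0, c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(coupling(0.5, -0.2, 0.1, c(0.2, 0.3, 0.5)),
               0.2 * 0.5 + 0.3 * -0.2 + 0.5 * 0.1)
  expect_equal(coupling(1, 0.5, 0, c(0.6, 0.4, 0), angle_gate = TRUE,
                        p_dot = -0.1), 0.4 * 0.5)
  expect_error(coupling(1, 0, 0, c(0.5, 0.4, 0.2)), "summing to 1")
})

test_that("pair potential matches high-precision evaluation", {
  expect_equal(pair_potential(2, S = 1, beta = 5), -0.534985, tolerance = 1e-6)
  expect_equal(pair_potential(100, S = 0), exp(-100))
  expect_lt(abs(pair_potential(60, S = 1)), 1e-5)
  expect_equal(pair_potential(1.5, S = 0.7, beta = 3, exponent = 4),
               exp(-1.5^4) - 0.7 * exp(-(1.5 / 3)^4))
  expect_error(pair_potential(0, S = 1), "positive")
})

test_that("equilibrium distance: closed form equals the numeric argmin", {
  expect_equal(equilibrium_distance(1, 5), 1.25 * log(5))
  expect_equal(round(equilibrium_distance(1, 5), 4), 2.0118)
  expect_equal(equilibrium_distance(5, 5), 0)
  expect_equal(equilibrium_distance(0.5, 5), 2.8782, tolerance = 1e-4)
  for (S in c(0.25, 0.5, 1)) for (beta in c(3, 5)) {
    coarse <- optimize(function(r) pair_potential(r, S, beta),
                       interval = c(1e-3, 60), tol = 1e-10)$minimum
    h <- 1e-5
    dV <- function(r) (pair_potential(r + h, S, beta) -
                       pair_potential(r - h, S, beta)) / (2 * h)
    num <- uniroot(dV, c(coarse - 0.1, coarse + 0.1), tol = 1e-12)$root
    expect_equal(equilibrium_distance(S, beta), num, tolerance = 1e-8)
  }
  # quartic variant: numerically located minimum is stationary
  r4 <- equilibrium_distance(1, 5, exponent = 4)
  h <- 1e-5
  expect_lt(abs(pair_potential(r4 + h, 1, 5, 4) -
                pair_potential(r4 - h, 1, 5, 4)) / (2 * h), 1e-6)
  expect_error(equilibrium_distance(0, 5), "positive")
})

test_that("analytic gradients match central finite differences", {
  set.seed(12)
  for (expo in c(1, 4)) {
    cfg <- model_config(potential_exponent = expo)
    for (rep in 1:20) {
      xi <- rnorm(3); xj <- xi + rand_unit() * runif(1, 0.8, 4)
      p_i <- rand_unit(); p_j <- rand_unit()
      q_i <- rand_unit(); q_j <- rand_unit()
      li <- runif(3); li <- li / sum(li)
      lj <- runif(3); lj <- lj / sum(lj)
      g <- pair_gradients(xi, xj, p_i, p_j, q_i, q_j, li, lj, cfg)
      fd <- list(
        dV_dri = num_grad(function(v) V_ref(v, xj, p_i, p_j, q_i, q_j, li, lj, expo = expo), xi),
        dV_drj = num_grad(function(v) V_ref(xi, v, p_i, p_j, q_i, q_j, li, lj, expo = expo), xj),
        dV_dpi = num_grad(function(v) V_ref(xi, xj, v, p_j, q_i, q_j, li, lj, expo = expo), p_i),
        dV_dpj = num_grad(function(v) V_ref(xi, xj, p_i, v, q_i, q_j, li, lj, expo = expo), p_j),
        dV_dqi = num_grad(function(v) V_ref(xi, xj, p_i, p_j, v, q_j, li, lj, expo = expo), q_i),
        dV_dqj = num_grad(function(v) V_ref(xi, xj, p_i, p_j, q_i, v, li, lj, expo = expo), q_j))
      scale <- max(abs(unlist(fd)), 1e-8)
      for (nm in names(fd))
        expect_lt(max(abs(g[[nm]] - fd[[nm]])) / scale, 1e-6)
      expect_equal(g$V, V_ref(xi, xj, p_i, p_j, q_i, q_j, li, lj, expo = expo),
                   tolerance = 1e-12)
    }
  }
})

test_that("pair force is antisymmetric and vanishes at the minimum", {
  r_star <- equilibrium_distance(1, 5)
  g <- pair_gradients(c(0, 0, 0), c(r_star, 0, 0), c(0, 0, 1), c(0, 0, 1),
                      c(0, 1, 0), c(0, 1, 0))
  expect_lt(max(abs(g$dV_dri)), 1e-9)
  set.seed(3)
  for (rep in 1:10) {
    xi <- rnorm(3); xj <- xi + rand_unit() * runif(1, 1, 4)
    g <- pair_gradients(xi, xj, rand_unit(), rand_unit(), rand_unit(),
                        rand_unit(), c(0.3, 0.3, 0.4))
    expect_equal(g$dV_dri, -g$dV_drj, tolerance = 1e-14)
  }
})

test_that("pair interaction is equivariant under global rotation", {
  set.seed(8)
  xi <- c(0.3, -1, 2); xj <- c(2.1, 0.4, 1.2)
  p_i <- rand_unit(); p_j <- rand_unit()
  q_i <- rand_unit(); q_j <- rand_unit()
  lam <- c(0.5, 0.3, 0.2)
  g0 <- pair_gradients(xi, xj, p_i, p_j, q_i, q_j, lam)
  Q <- rotation_matrix(1.1)
  gR <- pair_gradients(drop(Q %*% xi), drop(Q %*% xj), drop(Q %*% p_i),
                       drop(Q %*% p_j), drop(Q %*% q_i), drop(Q %*% q_j), lam)
  expect_equal(gR$V, g0$V, tolerance = 1e-9)
  expect_equal(gR$S, g0$S, tolerance = 1e-9)
  for (nm in c("dV_dri", "dV_dpi", "dV_dqi", "dV_dpj"))
    expect_equal(gR[[nm]], drop(Q %*% g0[[nm]]), tolerance = 1e-9)
})
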