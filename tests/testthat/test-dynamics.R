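test_that("an aligned pair at the equilibrium distance is stationary", {
  r_star <- equilibrium_distance(1, 5)
  st <- cell_state(matrix(c(0, 0, 0, r_star, 0, 0), 2, 3, byrow = TRUE),
                   ab = matrix(c(0, 0, 1, 0, 0, 1), 2, 3, byrow = TRUE))
  out <- step_cells(st, model_config(eta = 0))
  expect_lt(max(abs(positions(out) - positions(st))), 1e-9)
})

test_that("fixed-polarity cells keep their polarity bitwise", {
  set.seed(21)
  st <- make_bulk_aggregate(40)
  st$fixed <- TRUE
  sim <- simulate_cells(st, 30, model_config(eta = 0.05))
  expect_identical(ab_polarity(sim$state), ab_polarity(st))
  expect_identical(pcp_polarity(sim$state), pcp_polarity(st))
  expect_false(identical(positions(sim$state), positions(st)))
})

test_that("noiseless dynamics are gradient descent between neighbor exchanges", {
  set.seed(4)
  st <- make_bulk_aggregate(100)
  cfg <- model_config(eta = 0, dt = 0.1)
  # settle past the initial churn so the neighbor graph holds still long
  # enough for the descent property to be observable
  st <- simulate_cells(st, 300, cfg)$state
  prev_edges <- NULL
  prev_e <- NULL
  drops <- 0
  for (s in 1:60) {
    g <- find_neighbors(st)
    e <- mean(energy_per_cell(st, g, cfg))
    if (!is.null(prev_edges) && identical(edges_matrix(g), prev_edges)) {
      expect_lte(e, prev_e + 1e-10)
      drops <- drops + 1
    }
    prev_edges <- edges_matrix(g)
    prev_e <- e
    st <- step_cells(st, cfg)
  }
  expect_gt(drops, 10) # the check must actually have run
})

test_that("polarities stay unit norm and in-plane PCP stays orthogonal", {
  set.seed(6)
  st <- make_hollow_sphere(80, pcp_whirl = TRUE, lambda = c(0.4, 0.5, 0.1))
  sim <- simulate_cells(st, 40, model_config(eta = 0.01),
                        pcp_in_plane = TRUE)
  p <- ab_polarity(sim$state); q <- pcp_polarity(sim$state)
  expect_true(all(abs(sqrt(rowSums(p^2)) - 1) < 1e-12))
  expect_true(all(abs(sqrt(rowSums(q^2)) - 1) < 1e-12))
  expect_true(all(abs(rowSums(p * q)) < 1e-9))
})

test_that("noiseless field-free dynamics conserve the center of mass", {
  set.seed(13)
  st <- make_bulk_aggregate(60)
  sim <- simulate_cells(st, 100, model_config(eta = 0))
  expect_lt(max(abs(colMeans(positions(sim$state)) -
                    colMeans(positions(st)))), 1e-9)
})

test_that("trajectories are reproducible bit-for-bit under a fixed seed", {
  run_once <- function() {
    set.seed(99)
    st <- make_bulk_aggregate(50)
    simulate_cells(st, 25, model_config(eta = 0.01))$state
  }
  expect_identical(run_once(), run_once())
})

test_that("neighbor stride approximates stride-1 dynamics", {
  set.seed(14)
  st <- make_bulk_aggregate(60)
  st <- simulate_cells(st, 100, model_config(eta = 0))$state
  a <- simulate_cells(st, 20, model_config(eta = 0, neighbor_stride = 1))
  b <- simulate_cells(st, 20, model_config(eta = 0, neighbor_stride = 4))
  expect_lt(max(abs(positions(a$state) - positions(b$state))), 0.1)
})

test_that("pressure force points to the center of mass with magnitude P r / r_max", {
  pos <- rbind(c(4, 0, 0), c(-4, 0, 0), c(0, 1, 0), c(0, -1, 0))
  f <- pressure_force(pos, P = 0.5)
  # periphery cell feels exactly P toward the center
  expect_equal(f[1, ], c(-0.5, 0, 0))
  expect_equal(sqrt(sum(f[3, ]^2)), 0.5 * 1 / 4)
  expect_equal(pressure_force(pos, P = 0), matrix(0, 4, 3))
  center <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(pressure_force(center, P = 1), matrix(0, 2, 3))
})

test_that("gastrulation AB force decays with the Gaussian and is safe on-axis", {
  k <- 0.02; sigma <- 10
  f_axis <- gastrulation_ab_force(matrix(c(0, 0, 5), 1, 3), k, sigma)
  expect_equal(f_axis, matrix(0, 1, 3))
  f_far <- gastrulation_ab_force(matrix(c(10 * sigma, 0, 0), 1, 3), k, sigma)
  expect_lt(sqrt(sum(f_far^2)), 1e-10)
  f_near <- gastrulation_ab_force(matrix(c(1e-6, 0, 0), 1, 3), k, sigma)
  expect_equal(sqrt(sum(f_near^2)), k, tolerance = 1e-6)
  expect_equal(unname(f_near[1, ]) / sqrt(sum(f_near^2)), c(-1, 0, 0),
               tolerance = 1e-9)
  f_masked <- gastrulation_ab_force(rbind(c(2, 0, 0), c(3, 0, 0)), k, sigma,
                                    mask = c(FALSE, TRUE))
  expect_equal(f_masked[1, ], c(0, 0, 0))
  expect_gt(abs(f_masked[2, 1]), 0)
  expect_error(gastrulation_ab_force(matrix(1, 1, 3), k, sigma = 0), "sigma")
})

test_that("a radially fixed boundary field collapses a bulk into one shell", {
  set.seed(23)
  st <- make_bulk_aggregate(300)
  st <- apply_polarity_field(st, "radial_point", fix = TRUE)
  sim <- simulate_cells(st, 500, model_config(eta = 0.1, dt = 0.2,
                                              neighbor_stride = 2))
  pos <- positions(sim$state)
  rad <- sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2))
  expect_lt(sd(rad) / mean(rad), 0.05)
  expect_equal(count_shells(sim$state, sim$graph), 1)
})

test_that("invalid integration parameters are rejected", {
  expect_error(model_config(dt = 0), "positive")
  expect_error(model_config(beta = 1), "> 1")
  expect_error(model_config(potential_exponent = 2), "1 or 4")
})
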