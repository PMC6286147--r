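test_that("cell_state enforces its invariants", {
  pos <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  ab <- matrix(c(0, 0, 1, 0, 0, 1), 2, 3, byrow = TRUE)
  st <- cell_state(pos, ab = ab)
  expect_s3_class(st, "cell_state")
  expect_equal(rowSums(lambdas(st)), c(1, 1))
  expect_true(all(abs(sqrt(rowSums(pcp_polarity(st)^2)) - 1) < 1e-9))
  expect_error(cell_state(pos, ab = 2 * ab), "unit norm")
  expect_error(cell_state(pos, ab = ab, lambda = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(cell_state(matrix(c(0, 0, Inf, 1, 0, 0), 2, 3, byrow = TRUE),
                          ab = ab), "finite")
})

test_that("bulk aggregate generator matches the compact-aggregate spec", {
  set.seed(11)
  one <- make_bulk_aggregate(1)
  expect_equal(unname(positions(one)), matrix(0, 1, 3))
  expect_equal(sum(ab_polarity(one)^2), 1, tolerance = 1e-12)

  set.seed(5)
  st <- make_bulk_aggregate(400)
  expect_equal(n_cells(st), 400)
  pos <- positions(st)
  d <- as.matrix(dist(pos)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  # nearest-neighbor spacing about two cell radii
  expect_lt(abs(mean(nn) - 2), 0.4)
  expect_true(all(abs(sqrt(rowSums(ab_polarity(st)^2)) - 1) < 1e-9))
  expect_equal(unname(lambdas(st)[1, ]), c(1, 0, 0))
  expect_false(any(st$pcp_active))
  # AB directions should have no preferred orientation
  expect_lt(sqrt(sum(colMeans(ab_polarity(st))^2)), 0.15)

  set.seed(42); a <- make_bulk_aggregate(100)
  set.seed(42); b <- make_bulk_aggregate(100)
  expect_identical(a, b)
  expect_error(make_bulk_aggregate(0), ">= 1")
})

test_that("hollow sphere generator is deterministic, radial, and orthogonal", {
  st <- make_hollow_sphere(1000, pcp_whirl = TRUE)
  r <- sqrt(rowSums(positions(st)^2))
  expect_true(all(abs(r - r[1]) < 1e-9))
  p <- ab_polarity(st); q <- pcp_polarity(st)
  expect_true(all(abs(rowSums(p * q)) < 1e-9))
  expect_true(all(abs(rowSums(p * positions(st)) - r) < 1e-6))
  expect_identical(st, make_hollow_sphere(1000, pcp_whirl = TRUE))
  expect_error(make_hollow_sphere(3), ">= 4")
})

test_that("whirling PCP is azimuthal about the axis", {
  # hand evaluation of z-hat x r-hat at the equator point (R, 0, 0)
  q <- pcp_whirl_field(matrix(c(5, 0, 0), 1, 3))
  expect_equal(abs(drop(q %*% c(0, 1, 0))), 1, tolerance = 1e-12)
  expect_warning(pcp_whirl_field(matrix(c(0, 0, 3), 1, 3)), "axis")
})

test_that("polarity boundary fields follow the named symmetries", {
  pos <- matrix(c(3, 0, 0, 0, 2, 5, 1, 1, -2, -3, 0, 0, 0, -2, 5, -1, -1, 2),
                6, 3, byrow = TRUE)
  st <- cell_state(pos, ab = matrix(rep(c(1, 0, 0), 6), 6, 3, byrow = TRUE))

  rp <- apply_polarity_field(st, "radial_point", center = c(0, 0, 0))
  expect_equal(unname(ab_polarity(rp)[1, ]), c(1, 0, 0))
  expect_true(all(rp$fixed))

  ra <- apply_polarity_field(st, "radial_axis", center = c(0, 0, 0))
  expect_equal(unname(ab_polarity(ra)[2, ]), c(0, 1, 0))

  # cells 1 and 4 sit exactly in the z = 0 plane, triggering the tie-break
  expect_warning(
    pl <- apply_polarity_field(st, "planar", center = c(0, 0, 0), fix = FALSE),
    "symmetry locus")
  expect_equal(unname(ab_polarity(pl)[3, ]), c(0, 0, -1))
  expect_false(any(pl$fixed))

  on_axis <- cell_state(matrix(c(0, 0, 4, 1, 0, 0), 2, 3, byrow = TRUE),
                        ab = matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE))
  expect_warning(out <- apply_polarity_field(on_axis, "radial_axis",
                                             center = c(0, 0, 0)),
                 "symmetry locus")
  expect_equal(unname(ab_polarity(out)[1, ]), c(1, 0, 0))
})

test_that("generated aggregates are rotation-invariant in distribution", {
  set.seed(9)
  st <- make_bulk_aggregate(200)
  Q <- rotation_matrix(0.7)
  rot <- positions(st) %*% t(Q)
  # rigid rotation preserves the pair-distance distribution exactly
  expect_equal(sort(dist(rot)), sort(dist(positions(st))), tolerance = 1e-9)
  # and the generator itself is isotropic: position cloud has near-zero mean
  expect_lt(sqrt(sum(colMeans(positions(st))^2)), 1)
})

test_that("state CSV round-trips losslessly", {
  set.seed(2)
  st <- make_hollow_sphere(50, pcp_whirl = TRUE, lambda = c(0.4, 0.5, 0.1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_state_csv(st, f)
  back <- read_state_csv(f)
  expect_identical(positions(back), positions(st))
  expect_identical(ab_polarity(back), ab_polarity(st))
  expect_identical(lambdas(back), lambdas(st))
  expect_identical(back$pcp_active, st$pcp_active)
})
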