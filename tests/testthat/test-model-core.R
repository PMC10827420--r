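box30 <- domain_box(30)
geom <- fibre_geometry()

test_that("positions wrap into the half-open box by modular arithmetic", {
  expect_equal(wrap_position(c(0, 0, 0), box30), c(0, 0, 0))
  expect_equal(wrap_position(c(16, 0, 0), box30), c(-14, 0, 0))
  expect_equal(wrap_position(c(-15.5, 31, 0), box30), c(14.5, 1, 0))
  # half-open convention: +L/2 maps to -L/2
  expect_equal(wrap_position(c(15, -15, 0), box30), c(-15, -15, 0))
  m <- wrap_position(matrix(runif(60, -100, 100), ncol = 3), box30)
  expect_true(all(m >= -15 & m < 15))
  expect_error(wrap_position(c(NA, 0, 0), box30), "non-finite")
})

test_that("periodic displacement is the minimum image of the difference", {
  expect_equal(periodic_displacement(c(14, 0, 0), c(-14, 0, 0), box30),
               c(2, 0, 0))
  expect_equal(periodic_displacement(c(1, 2, 3), c(1, 2, 3), box30),
               c(0, 0, 0))
  expect_equal(periodic_displacement(c(0, 0, 0), c(7, -8, 3), box30),
               c(7, -8, 3))
  expect_error(periodic_displacement(c(Inf, 0, 0), c(0, 0, 0), box30),
               "non-finite")
})

test_that("displacement is insensitive to wrapping of either endpoint", {
  set.seed(41)
  for (r in 1:200) {
    a <- runif(3, -60, 60); b <- runif(3, -60, 60)
    expect_equal(periodic_displacement(a, wrap_position(b, box30), box30),
                 periodic_displacement(a, b, box30), tolerance = 1e-12)
  }
})

test_that("closest points handle overlap, symmetry and skew geometry", {
  # identical fibres: full overlap, distance zero
  r <- segment_closest_points(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              geom, box30)
  expect_equal(r$distance, 0)
  expect_equal(r$s1, 0)  # midpoint tie-break for the parallel continuum
  expect_equal(r$s2, 0)

  # perpendicular fibres offset along the common normal
  r <- segment_closest_points(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1.5),
                              c(0, 1, 0), geom, box30)
  expect_equal(r$s1, 0); expect_equal(r$s2, 0)
  expect_equal(r$distance, 1.5)

  # skew pair against the dense-grid oracle (2001 x 2001 single stage)
  x1 <- c(0, 0, 0); w1 <- c(1, 0, 0)
  x2 <- c(1, 2, 1); w2 <- c(0, 1, 0)
  r <- segment_closest_points(x1, w1, x2, w2, geom, box30)
  oracle <- grid_min_distance(x1, w1, x2, w2, geom, box30,
                              n_coarse = 2001, n_fine = 3)
  expect_equal(r$distance, oracle, tolerance = 1e-3)
})

test_that("closest-point distance matches grid minimisation on random pairs", {
  set.seed(7)
  for (k in 1:200) {
    x1 <- runif(3, -15, 15); x2 <- x1 + runif(3, -8, 8)
    w <- runit(2)
    r <- segment_closest_points(x1, w[1, ], x2, w[2, ], geom, box30)
    oracle <- grid_min_distance(x1, w[1, ], x2, w[2, ], geom, box30)
    expect_lt(abs(r$distance - oracle), 1e-3 * geom$l_fib)
  }
})

test_that("closest-point distance is translation invariant and symmetric", {
  set.seed(8)
  for (k in 1:200) {
    x1 <- runif(3, -15, 15); x2 <- x1 + runif(3, -8, 8)
    w <- runit(2)
    shift <- runif(3, -40, 40)
    r0 <- segment_closest_points(x1, w[1, ], x2, w[2, ], geom, box30)
    r1 <- segment_closest_points(wrap_position(x1 + shift, box30), w[1, ],
                                 wrap_position(x2 + shift, box30), w[2, ],
                                 geom, box30)
    expect_equal(r1$distance, r0$distance, tolerance = 1e-9)
    rs <- segment_closest_points(x2, w[2, ], x1, w[1, ], geom, box30)
    expect_equal(rs$distance, r0$distance, tolerance = 1e-12)
    expect_equal(rs$s1, r0$s2, tolerance = 1e-9)
    expect_equal(rs$s2, r0$s1, tolerance = 1e-9)
  }
})

test_that("domain types enforce their invariants", {
  expect_error(domain_box(-1), "positive")
  expect_equal(domain_box(2, 3, 4)$volume, 24)
  expect_error(fibre_geometry(l_fib = 0), "l_fib")
  expect_error(fibre_geometry(r_fib = -1), "r_fib")

  p <- model_params(nu_link = 0.1, chi_link = 0.5)
  expect_equal(p$nu_unlink, 0.1)
  expect_equal(model_params(nu_link = 2, chi_link = 1)$nu_unlink, 0)
  expect_error(model_params(chi_link = 1.5), "chi_link")
  expect_error(model_params(nu_link = -1), "nu_link")
  expect_error(model_params(alpha_rep = -0.1), "alpha_rep")
  expect_error(model_params(chi_link = 0, nu_link = 1), "inconsistent")

  expect_error(step_control(dx_max = 0), "dx_max")
  expect_error(step_control(dt_min = 1, dt_max = 0.1), "dt_min")

  st <- fibre_state(matrix(0, 2, 3), rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(st$n_fib, 2)
  expect_error(fibre_state(matrix(0, 1, 3), matrix(c(1, 1, 0), 1)), "unit")

  # a fibre must fit in half the box for unambiguous minimum images
  expect_error(run_simulation(model_params(n_fib = 2), domain_box(10)),
               "minimum-image")
})
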