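box30 <- domain_box(30)

test_that("a force-free step leaves the state unchanged except for time", {
  st <- fibre_state(rbind(c(-10, 0, 0), c(10, 0, 0)),
                    rbind(c(1, 0, 0), c(0, 1, 0)))
  p <- model_params(n_fib = 2)
  ctrl <- step_control()
  res <- euler_step(st, empty_links(), p, ctrl, box30)
  expect_equal(res$state$x, st$x)
  expect_equal(res$state$omega, st$omega)
  expect_equal(res$dt, ctrl$dt_max)
  expect_gt(res$state$t, st$t)
})

test_that("the adaptive step honours the displacement and rotation caps", {
  set.seed(31)
  b <- domain_box(15)
  st <- random_fibre_state(120, b)
  p <- model_params(n_fib = 120, nu_link = 0.5, chi_link = 0.5)
  links <- make_link_topology(st, "bernoulli", chi = 0.5, params = p, box = b,
                              seed = 32)
  ctrl <- step_control(dx_max = 0.05, dtheta_max = 0.05)
  for (k in 1:20) {
    res <- euler_step(st, links, p, ctrl, b)
    expect_lte(res$max_step_displacement, ctrl$dx_max * (1 + 1e-12))
    expect_lte(res$max_step_rotation, ctrl$dtheta_max * (1 + 1e-12))
    expect_lt(max(abs(sqrt(rowSums(res$state$omega^2)) - 1)), 1e-9)
    st <- res$state
  }
})

test_that("spring relaxation follows its closed-form exponential", {
  p <- model_params()
  p$alpha_rep <- 0; p$alpha_align <- 0; p$nu_link <- 0; p$nu_unlink <- 0
  fx <- make_two_fibre_fixture("rest", p$geometry, box30)
  ctrl <- step_control(dx_max = 1e-4 * p$geometry$r_fib, dtheta_max = 1e-4,
                       dt_min = 1e-12, dt_max = 100, dt_init = 1e-6)
  st <- fx$state
  rate <- 2 * p$alpha_rest / (p$mu_fib * p$geometry$l_fib)
  for (tt in c(0.5, 1.5, 3)) {
    res <- fibrenet:::advance_result(
      fibrenet:::advance_raw(st, fx$links, p, ctrl, box30,
                             t_target = tt, do_events = FALSE))
    st <- res$state
    d <- sqrt(sum(periodic_displacement(st$x[1, ], st$x[2, ], box30)^2))
    expect_equal(d, p$d_link_eq * (1 - exp(-rate * tt)), tolerance = 0.01)
  }
})

test_that("two-fibre relaxation times converge at first order in the step", {
  exact <- log(10) * 6 / 5
  err <- sapply(c(8e-4, 4e-4), function(res)
    abs(two_fibre_characteristic_time("rest", resolution = res) - exact))
  expect_gt(err[1] / err[2], 1.5)   # halving the caps roughly halves the error
  expect_lt(err[2] / exact, 0.005)
  # halving the step changes the answer by well under 0.5%
  t1 <- two_fibre_characteristic_time("rest", resolution = 4e-4)
  t2 <- two_fibre_characteristic_time("rest", resolution = 2e-4)
  expect_lt(abs(t1 - t2) / t2, 0.005)
})

test_that("a stiff configuration aborts instead of silently understepping", {
  fx <- make_two_fibre_fixture("rep", fibre_geometry(), box30)
  p <- model_params(n_fib = 2)
  # the overlapping pair needs dt ~ 1e-2; demanding dt >= 1 must fail
  ctrl <- step_control(dx_max = 0.01, dtheta_max = 0.01,
                       dt_min = 1, dt_max = 5, dt_init = 1)
  expect_error(euler_step(fx$state, fx$links, p, ctrl, box30), "dt_min")
})

test_that("the alignment torque monotonically deepens the nematic potential", {
  p <- model_params()
  p$alpha_rep <- 0; p$alpha_rest <- 0; p$nu_link <- 0; p$nu_unlink <- 0
  fx <- make_two_fibre_fixture("align", p$geometry, box30)
  st <- fx$state
  ctrl <- step_control(dx_max = 0.05, dtheta_max = 0.01, dt_max = 50)
  dots <- numeric(200)
  for (k in 1:200) {
    st <- euler_step(st, fx$links, p, ctrl, box30)$state
    dots[k] <- abs(sum(st$omega[1, ] * st$omega[2, ]))
  }
  expect_true(all(diff(dots) >= -1e-12))   # |cos theta| never decreases
  expect_gt(dots[200], dots[1])
})

test_that("degenerate simulations stay static", {
  # a single fibre has nothing to interact with
  p1 <- model_params(n_fib = 1, t_final = 50)
  tr <- run_simulation(p1, box30, seed = 1, n_frames = 3, quantify = FALSE)
  expect_equal(tr$frames[[1]]$state$x, tr$frames[[4]]$state$x)
  expect_equal(tr$frames[[1]]$state$omega, tr$frames[[4]]$state$omega)

  # no links, no linking, no repulsion: nothing moves
  set.seed(33)
  p <- model_params(n_fib = 40, nu_link = 0, chi_link = 0.5, t_final = 50)
  p$alpha_rep <- 0
  tr <- run_simulation(p, box30, seed = 2, init_links = FALSE, n_frames = 3,
                       quantify = FALSE)
  expect_equal(tr$frames[[1]]$state$x, tr$frames[[4]]$state$x)
  expect_equal(nrow(tr$frames[[4]]$links), 0)
})

test_that("identical seeds reproduce trajectories bit for bit", {
  p <- model_params(n_fib = 80, nu_link = 0.3, chi_link = 0.5, t_final = 30)
  b <- domain_box(15)
  tr1 <- run_simulation(p, b, seed = 9, n_frames = 5, log_events = TRUE)
  tr2 <- run_simulation(p, b, seed = 9, n_frames = 5, log_events = TRUE)
  last <- length(tr1$frames)
  expect_identical(tr1$frames[[last]]$state$x, tr2$frames[[last]]$state$x)
  expect_identical(tr1$frames[[last]]$state$omega,
                   tr2$frames[[last]]$state$omega)
  expect_identical(tr1$frames[[last]]$links, tr2$frames[[last]]$links)
  expect_identical(tr1$events, tr2$events)
})
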