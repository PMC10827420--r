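box30 <- domain_box(30)
geom <- fibre_geometry()

test_that("repulsion vanishes out of contact and pushes fibres apart in it", {
  # parallel fibres at axis distance 1.25 = 2.5 * r_fib: no contact
  r <- repulsion_force_torque(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1.25),
                              c(1, 0, 0), geom, 12.5, box30)
  expect_equal(r$f_on_1, c(0, 0, 0))
  expect_equal(r$t_on_2, c(0, 0, 0))

  set.seed(11)
  for (k in 1:50) {
    x1 <- runif(3, -5, 5)
    w <- runit(2)
    x2 <- x1 + runif(3, -0.6, 0.6)   # overlapping region
    r <- repulsion_force_torque(x1, w[1, ], x2, w[2, ], geom, 12.5, box30,
                                idx = c(1L, 2L))
    expect_equal(r$f_on_1 + r$f_on_2, c(0, 0, 0), tolerance = 1e-12)
    cp <- segment_closest_points(x1, w[1, ], x2, w[2, ], geom, box30)
    if (cp$distance > 1e-9 && cp$distance < 1) {
      # force on fibre 1 points away from fibre 2's closest point
      expect_lt(sum(r$f_on_1 * cp$u), 0)
      expect_gt(sqrt(sum(r$f_on_1^2)), 0)
    }
  }
})

test_that("crosslink spring is unloaded at d_link_eq and restoring otherwise", {
  link <- data.frame(fibre_a = 1L, fibre_b = 2L, s_a = 0, s_b = 0,
                     t_created = 0)
  # attachment distance exactly the unloaded length
  r <- spring_force_torque(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 0, 0),
                           link, geom, 5, 1, box30)
  expect_equal(r$f_on_1, c(0, 0, 0), tolerance = 1e-12)
  # stretched: force on 1 towards 2
  r <- spring_force_torque(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2.5), c(1, 0, 0),
                           link, geom, 5, 1, box30)
  expect_equal(r$f_on_1, c(0, 0, 5 * 1.5), tolerance = 1e-12)
  expect_equal(r$f_on_2, -r$f_on_1)
  # compressed: force on 1 away from 2
  r <- spring_force_torque(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0.4), c(1, 0, 0),
                           link, geom, 5, 1, box30)
  expect_lt(r$f_on_1[3], 0)
  # off-centre attachment generates a torque
  link2 <- data.frame(fibre_a = 1L, fibre_b = 2L, s_a = 2, s_b = 0,
                      t_created = 0)
  r <- spring_force_torque(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2.5), c(1, 0, 0),
                           link2, geom, 5, 1, box30)
  expect_gt(sqrt(sum(r$t_on_1^2)), 0)
  expect_error(spring_force_torque(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1),
                                   c(1, 0, 0),
                                   data.frame(fibre_a = 1L, fibre_b = 2L,
                                              s_a = 4, s_b = 0,
                                              t_created = 0),
                                   geom, 5, 1, box30),
               "abscissae")
})

test_that("alignment torque is nematic, pure, and vanishes when aligned", {
  w1 <- c(1, 0, 0)
  expect_equal(alignment_torque(w1, w1, 2)$t_on_1, c(0, 0, 0))
  expect_equal(alignment_torque(w1, -w1, 2)$t_on_1, c(0, 0, 0),
               tolerance = 1e-12)
  set.seed(12)
  for (k in 1:50) {
    w <- runit(2)
    a <- alignment_torque(w[1, ], w[2, ], 2)
    expect_equal(a$f_on_1, c(0, 0, 0))           # pure torque
    expect_equal(a$t_on_2, -a$t_on_1)            # equal and opposite
    flip <- alignment_torque(w[1, ], -w[2, ], 2)
    expect_equal(flip$t_on_1, a$t_on_1, tolerance = 1e-12)
    flip1 <- alignment_torque(-w[1, ], w[2, ], 2)
    expect_equal(flip1$t_on_1, a$t_on_1, tolerance = 1e-12)
  }
  # perpendicular fibres: the odd term leaves the saddle at a finite rate
  perp <- alignment_torque(c(1, 0, 0), c(0, 1, 0), 2)
  a <- align_blend_default()
  expect_equal(sqrt(sum(perp$t_on_1^2)), 2 * a / (1 + a), tolerance = 1e-12)
  # torque rotates fibre 1 towards its partner: d(w1)/dt ~ T x w1
  w1 <- c(1, 0, 0); w2 <- c(1, 1, 0) / sqrt(2)
  tq <- alignment_torque(w1, w2, 2)$t_on_1
  dw <- c(tq[2] * w1[3] - tq[3] * w1[2],
          tq[3] * w1[1] - tq[1] * w1[3],
          tq[1] * w1[2] - tq[2] * w1[1])
  expect_gt(sum(dw * (w2 - sum(w1 * w2) * w1)), 0)
})

test_that("accumulated forces equal the naive all-pairs oracle", {
  set.seed(13)
  st <- random_fibre_state(50, box30)
  p <- model_params(n_fib = 50, nu_link = 0.1, chi_link = 0.6)
  links <- make_link_topology(st, "bernoulli", chi = 0.6, params = p,
                              box = box30, seed = 14)
  expect_gt(nrow(links), 0)
  got <- accumulate_forces(st, links, p, box30)
  want <- naive_forces(st, links, p, box30)
  expect_equal(got$force, want$force, tolerance = 1e-10)
  expect_equal(got$torque, want$torque, tolerance = 1e-10)
  # internal forces cancel
  expect_equal(colSums(got$force), c(0, 0, 0), tolerance = 1e-9)

  # no contacts, no links: identically zero
  far <- fibre_state(rbind(c(-10, 0, 0), c(10, 0, 0)),
                     rbind(c(1, 0, 0), c(0, 1, 0)))
  z <- accumulate_forces(far, empty_links(), p, box30)
  expect_equal(z$force, matrix(0, 2, 3))
  expect_equal(z$torque, matrix(0, 2, 3))
})
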