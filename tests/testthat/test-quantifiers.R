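box30 <- domain_box(30)
geom <- fibre_geometry()

test_that("fibre volume fraction and regime labels match the worked values", {
  expect_equal(round(fibre_density(3000, geom, box30), 2), 0.58)
  expect_equal(round(fibre_density(1500, geom, box30), 2), 0.29)
  expect_equal(fibre_density(0, geom, box30), 0)
  expect_equal(density_regime(c(0.29, 0.58, 0.95)),
               c("sparse", "dense", "hyperdense"))
})

test_that("links per fibre counts links over fibres", {
  set.seed(51)
  st <- random_fibre_state(100, box30)
  lk <- make_link_topology(st, "perfect_matching", params = model_params(),
                           box = box30)
  expect_equal(links_per_fibre(lk, 100), 0.5)
  expect_equal(links_per_fibre(empty_links(), 100), 0)
  expect_equal(links_per_fibre(data.frame(x = numeric(2100)), 3000), 0.7)
  expect_error(links_per_fibre(empty_links(), 0), "n_fib")
})

test_that("alignment indicator hits the uniform/planar/unidirectional anchors", {
  set.seed(52)
  uni <- make_orientation_field("uniform", 1e4)$omega
  pla <- make_orientation_field("planar", 1e4)$omega
  one <- make_orientation_field("unidirectional", 1e4)$omega
  expect_lt(alignment_indicator(uni), 0.5)        # randomly oriented
  expect_lt(alignment_indicator(uni), 0.15)       # and close to 0 at n = 1e4
  expect_equal(alignment_indicator(pla), 1 / sqrt(2), tolerance = 0.03)
  expect_equal(alignment_indicator(one), 1)
  near <- make_orientation_field("concentration", 1e4, kappa = 20)$omega
  expect_gt(alignment_indicator(near), 0.8)       # nearly unidirectional
})

test_that("alignment indicator grows monotonically from disorder to order", {
  set.seed(53)
  vals <- sapply(c(0, 1, 3, 8, 30), function(k)
    alignment_indicator(make_orientation_field("concentration", 5000,
                                               kappa = k)$omega))
  expect_true(all(diff(vals) > 0))
})

test_that("local alignment is rotation- and sign-invariant", {
  set.seed(54)
  b <- domain_box(15)
  st <- random_fibre_state(60, b)
  p <- model_params(n_fib = 60)
  al <- local_alignment(st, p, b)
  # flipping individual directions changes nothing (non-oriented fibres)
  flip <- sample(c(-1, 1), 60, replace = TRUE)
  st2 <- fibre_state(st$x, st$omega * flip)
  expect_equal(local_alignment(st2, p, b), al, tolerance = 1e-9)
  # the indicator itself is invariant under a global rotation of the
  # direction set (the periodic box fixes the neighbourhoods, not the score)
  rot <- random_rotation()
  w <- runit(200)
  expect_equal(alignment_indicator(w %*% t(rot)), alignment_indicator(w),
               tolerance = 1e-9)
  expect_equal(alignment_indicator(w * sample(c(-1, 1), 200, TRUE)),
               alignment_indicator(w), tolerance = 1e-9)

  # parallel cluster: everyone fully aligned
  n <- 20
  xs <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, -1, 1))
  stp <- fibre_state(xs, matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE))
  expect_equal(local_alignment(stp, model_params(n_fib = n), b),
               rep(1, n), tolerance = 1e-9)
  # isolated fibres have undefined local alignment (axes perpendicular to
  # their separation so the segment distance really is 7)
  iso <- fibre_state(rbind(c(-3.5, 0, 0), c(3.5, 0, 0)),
                     rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_true(all(is.na(local_alignment(iso, model_params(n_fib = 2), b))))
  expect_error(mean_alignment(iso, model_params(n_fib = 2), b), "defined")
})

test_that("mean alignment is the mean of the defined per-fibre values", {
  set.seed(55)
  b <- domain_box(15)
  st <- random_fibre_state(150, b)
  p <- model_params(n_fib = 150)
  al <- local_alignment(st, p, b)
  expect_equal(mean_alignment(st, p, b), mean(al, na.rm = TRUE))
  expect_lt(mean_alignment(st, p, b), 0.7)   # disordered stays under threshold
})

test_that("stereographic projection maps pole to centre and equator to rim", {
  axis <- c(0, 0, 1)
  expect_equal(unname(drop(stereographic_projection(rbind(c(0, 0, 1)), axis))),
               c(0, 0))
  pr <- stereographic_projection(rbind(c(1, 0, 0), c(0, -1, 0)), axis)
  expect_equal(sqrt(rowSums(pr^2)), c(1, 1))
  # antipodal directions project to the same point
  pr2 <- stereographic_projection(rbind(c(0.6, 0, 0.8), c(-0.6, 0, -0.8)),
                                  axis)
  expect_equal(pr2[1, ], pr2[2, ])
  # a perfectly aligned system lands on one point at the centre
  one <- make_orientation_field("unidirectional", 50, axis = c(1, 1, 1))$omega
  pc <- stereographic_projection(one)
  expect_lt(max(abs(pc)), 1e-9)
  # A_max is invariant under rotations about the reference axis
  set.seed(56)
  w <- runit(2000)
  a1 <- covariance_ellipse_semi_major(stereographic_projection(w, c(0, 0, 1)))
  th <- 0.7
  rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  a2 <- covariance_ellipse_semi_major(
    stereographic_projection(w %*% t(rz), c(0, 0, 1)))
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("covariance ellipse axis calibrates against known clouds", {
  expect_equal(covariance_ellipse_semi_major(matrix(0.3, 10, 2)), 0)
  expect_error(covariance_ellipse_semi_major(matrix(0, 2, 2)), "3 points")
  set.seed(57)
  th <- runif(1e5, 0, 2 * pi); r <- sqrt(runif(1e5))
  expect_equal(covariance_ellipse_semi_major(cbind(r * cos(th), r * sin(th))),
               1, tolerance = 0.01)          # uniform disk: 2*sqrt(1/4)
  g <- matrix(rnorm(2e5, sd = 0.2), ncol = 2)
  expect_equal(covariance_ellipse_semi_major(g), 0.4, tolerance = 0.01)
})

test_that("state classification reproduces the three labelled cells", {
  expect_equal(classify_state(0.9, 0.3), "aligned")
  expect_equal(classify_state(0.8, 0.6), "curved")
  expect_equal(classify_state(0.4, 0.8), "unorganized")
  expect_equal(classify_state(0.4, 0.3), "unnamed")
  # totality: every finite pair maps to exactly one label
  g <- expand.grid(al = seq(0, 1, 0.1), am = seq(0, 1.4, 0.1))
  lab <- classify_state(g$al, g$am)
  expect_true(all(lab %in% c("aligned", "curved", "unorganized", "unnamed")))
  expect_error(classify_state(NA, 1), "finite")
})

test_that("ensemble summary uses the population SD over replicates", {
  s <- ensemble_summary(c(0.8, 0.9), c(0.5, 0.7))
  expect_equal(s$al_mean, 0.85)
  expect_equal(s$al_sd, 0.05)
  expect_equal(s$nlink_sd, 0.1)
  expect_error(ensemble_summary(0.8, 0.5), "replicates")
})

test_that("tau_Al recovers the time constant of saturating growth", {
  t <- seq(0, 1000, by = 10)
  al <- 0.9 * (1 - exp(-t / 100))
  tau <- fit_tau_al(t, al)
  expect_equal(as.numeric(tau), -100 * log(0.37), tolerance = 0.05)
  # constant series: already at its asymptote
  expect_equal(as.numeric(fit_tau_al(t, rep(0.7, length(t)))), 0)
  # robust to mild noise
  set.seed(58)
  tau_n <- fit_tau_al(t, al + rnorm(length(t), sd = 0.01 * 0.9))
  expect_equal(as.numeric(tau_n), as.numeric(tau), tolerance = 0.1)
  # a series still rising steeply cannot be extrapolated
  expect_error(fit_tau_al(t, 0.001 * t), "saturate")
})

test_that("log-law fit recovers exact coefficients and flags the drop", {
  n <- c(0.1, 0.15, 0.22, 0.33, 0.5, 0.65)
  al <- 0.037 * log(n) + 1.006
  f <- fit_log_law(n, al)
  expect_equal(f$alpha, 0.037, tolerance = 1e-10)
  expect_equal(f$beta, 1.006, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_true(is.na(f$n_critic))
  # append an over-connected branch that falls off the line
  n2 <- c(n, 0.8, 1.1)
  al2 <- c(al, 0.6, 0.45)
  f2 <- fit_log_law(n2, al2)
  expect_equal(f2$n_critic, 0.8)
  expect_equal(f2$alpha, 0.037, tolerance = 1e-10)
  expect_error(fit_log_law(c(0.1, 0.2, 0.3), c(1, 1, 1)), "at least")
})
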