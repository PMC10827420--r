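# Independent oracles used across the suite.  These deliberately avoid the
# package's closest-point algebra and force accumulation paths.

# Brute-force closest distance between two centred segments by dense grid
# minimisation over both abscissae.  Uses the same convention as the
# implementation (minimum image applied to the centre displacement, the
# segments treated as rigid around it), so it isolates the minimisation.
grid_min_distance <- function(x1, w1, x2, w2, geometry, box,
                              n_coarse = 201, n_fine = 81) {
  h <- geometry$l_fib / 2
  d12 <- periodic_displacement(x1, x2, box)
  a1 <- sum(w1 * d12); a2 <- sum(w2 * d12); b <- sum(w1 * w2)
  c0 <- sum(d12^2)
  dist2 <- function(s1, s2) {
    # |d12 + s2 w2 - s1 w1|^2 expanded
    outer(s1^2, rep(1, length(s2))) + outer(rep(1, length(s1)), s2^2) +
      c0 - 2 * outer(s1 * a1, rep(1, length(s2))) +
      2 * outer(rep(1, length(s1)), s2 * a2) - 2 * outer(s1, s2) * b
  }
  stage <- function(lo1, hi1, lo2, hi2, n) {
    s1 <- seq(lo1, hi1, length.out = n)
    s2 <- seq(lo2, hi2, length.out = n)
    d2 <- dist2(s1, s2)
    k <- arrayInd(which.min(d2), dim(d2))
    list(min = sqrt(max(0, min(d2))), s1 = s1[k[1]], s2 = s2[k[2]],
         step1 = (hi1 - lo1) / (n - 1), step2 = (hi2 - lo2) / (n - 1))
  }
  c1 <- stage(-h, h, -h, h, n_coarse)
  f <- stage(max(-h, c1$s1 - 2 * c1$step1), min(h, c1$s1 + 2 * c1$step1),
             max(-h, c1$s2 - 2 * c1$step2), min(h, c1$s2 + 2 * c1$step2),
             n_fine)
  min(c1$min, f$min)
}

# Naive all-pairs force/torque sum built from the exported elementary pair
# operations (O(N^2), no neighbour search).
naive_forces <- function(state, links, params, box) {
  n <- state$n_fib
  f <- matrix(0, n, 3); tq <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- repulsion_force_torque(state$x[i, ], state$omega[i, ],
                                  state$x[j, ], state$omega[j, ],
                                  params$geometry, params$alpha_rep, box,
                                  idx = c(i, j))
      f[i, ] <- f[i, ] + r$f_on_1; f[j, ] <- f[j, ] + r$f_on_2
      tq[i, ] <- tq[i, ] + r$t_on_1; tq[j, ] <- tq[j, ] + r$t_on_2
    }
  }
  for (l in seq_len(nrow(links))) {
    a <- links$fibre_a[l]; b <- links$fibre_b[l]
    s <- spring_force_torque(state$x[a, ], state$omega[a, ],
                             state$x[b, ], state$omega[b, ], links[l, ],
                             params$geometry, params$alpha_rest,
                             params$d_link_eq, box)
    al <- alignment_torque(state$omega[a, ], state$omega[b, ],
                           params$alpha_align, params$align_blend)
    f[a, ] <- f[a, ] + s$f_on_1; f[b, ] <- f[b, ] + s$f_on_2
    tq[a, ] <- tq[a, ] + s$t_on_1 + al$t_on_1
    tq[b, ] <- tq[b, ] + s$t_on_2 + al$t_on_2
  }
  list(force = f, torque = tq)
}

# random unit vectors
runit <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
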