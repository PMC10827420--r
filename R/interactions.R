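pair_ft_zero <- function() {
  list(f_on_1 = c(0, 0, 0), f_on_2 = c(0, 0, 0),
       t_on_1 = c(0, 0, 0), t_on_2 = c(0, 0, 0))
}

cross3_r <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Hertz-type repulsion between two fibres
#'
#' Fibres are soft spherocylinders: when the axes come closer than the
#' fibre diameter `2 r_fib` the pair experiences an elastic contact force
#' `F = alpha_rep * sqrt(2 r_fib) * (2 r_fib - d)^(3/2)` along the
#' closest-point separation, applied at the closest points (which also
#' produces a torque about each centre). The force is identically zero out
#' of contact. If the closest points coincide (`d = 0`) the direction is
#' undefined and a deterministic pseudo-random unit vector seeded by the
#' fibre index pair is used, so runs stay reproducible.
#'
#' @param x1,omega1,x2,omega2 Centres and unit directions of the pair.
#' @param geometry A [fibre_geometry()].
#' @param alpha_rep Repulsion magnitude.
#' @param box A [domain_box()].
#' @param idx Integer pair `(i, j)` used only for the zero-distance
#'   fallback direction.
#' @return `list(f_on_1, f_on_2, t_on_1, t_on_2)` (forces and torques).
#' @export
repulsion_force_torque <- function(x1, omega1, x2, omega2, geometry,
                                   alpha_rep, box, idx = c(1L, 2L)) {
  cp <- segment_closest_points(x1, omega1, x2, omega2, geometry, box)
  two_r <- 2 * geometry$r_fib
  if (cp$distance >= two_r || alpha_rep <= 0) return(pair_ft_zero())
  fmag <- alpha_rep * sqrt(two_r) * (two_r - cp$distance)^1.5
  dir <- if (cp$distance > 1e-12) cp$u / cp$distance
         else fallback_dir_cpp(idx[1], idx[2])
  f1 <- -fmag * dir
  f2 <- -f1
  list(f_on_1 = f1, f_on_2 = f2,
       t_on_1 = cp$s1 * cross3_r(omega1, f1),
       t_on_2 = cp$s2 * cross3_r(omega2, f2))
}

#' Crosslink spring force
#'
#' A crosslink is a linear spring of stiffness `alpha_rest` and unloaded
#' length `d_link_eq` connecting the attachment points `x_i + s_i omega_i`
#' fixed on each fibre at link creation. The force acts along the
#' minimum-image vector between the attachment points: attractive when the
#' spring is stretched, repulsive when compressed, zero at the unloaded
#' length; applied at the attachment points it also torques each fibre.
#'
#' @inheritParams repulsion_force_torque
#' @param link One-row link table (`fibre_a, fibre_b, s_a, s_b, t_created`).
#' @param alpha_rest Spring stiffness.
#' @param d_link_eq Unloaded length.
#' @return `list(f_on_1, f_on_2, t_on_1, t_on_2)`.
#' @export
spring_force_torque <- function(x1, omega1, x2, omega2, link, geometry,
                                alpha_rest, d_link_eq, box) {
  if (abs(link$s_a) > geometry$l_fib / 2 + 1e-12 ||
      abs(link$s_b) > geometry$l_fib / 2 + 1e-12)
    stop("attachment abscissae outside the fibre")
  if (alpha_rest <= 0) return(pair_ft_zero())
  p1 <- x1 + link$s_a * omega1
  p2 <- x2 + link$s_b * omega2
  disp <- periodic_displacement(p1, p2, box)
  len <- sqrt(sum(disp^2))
  fmag <- alpha_rest * (len - d_link_eq)
  dir <- if (len > 1e-12) disp / len
         else fallback_dir_cpp(link$fibre_a, link$fibre_b)
  f1 <- fmag * dir
  f2 <- -f1
  list(f_on_1 = f1, f_on_2 = f2,
       t_on_1 = link$s_a * cross3_r(omega1, f1),
       t_on_2 = link$s_b * cross3_r(omega2, f2))
}

#' Nematic alignment torque at a crosslink
#'
#' Linked fibres feel a pure torque (no force) that rotates each towards
#' the nearer of its partner's two orientations: with `c = omega1 . omega2`,
#' `T_on_1 = alpha_align/(1+a) * (c + a*sign(c)) * (omega1 x omega2)` and
#' `T_on_2 = -T_on_1`, where `a` is the calibrated odd-term weight
#' ([align_blend_default()]). The torque vanishes at relative angle 0 (mod
#' pi) and is invariant under flipping the sign of either direction. At
#' exactly perpendicular directions the quadratic part vanishes but the odd
#' term does not (with `sign(0)` taken as `+1`), so the perpendicular
#' configuration is left at a finite rate.
#'
#' @param omega1,omega2 Unit directions of the linked pair.
#' @param alpha_align Torque magnitude.
#' @param align_blend Odd-term weight.
#' @return `list(f_on_1, f_on_2, t_on_1, t_on_2)` with zero forces.
#' @export
alignment_torque <- function(omega1, omega2, alpha_align,
                             align_blend = align_blend_default()) {
  if (alpha_align <= 0) return(pair_ft_zero())
  cc <- sum(omega1 * omega2)
  sg <- if (cc >= 0) 1 else -1
  g <- alpha_align / (1 + align_blend) * (cc + align_blend * sg)
  tq <- g * cross3_r(omega1, omega2)
  list(f_on_1 = c(0, 0, 0), f_on_2 = c(0, 0, 0),
       t_on_1 = tq, t_on_2 = -tq)
}

#' Total forces and torques on every fibre
#'
#' Sums the elementary repulsion contributions over all pairs within
#' contact range and the spring and alignment contributions over all
#' crosslinked pairs. The neighbour search is a prefiltered pair scan whose
#' result is identical to the naive all-pairs sum.
#'
#' @param state A [fibre_state()].
#' @param links Link table.
#' @param params A [model_params()].
#' @param box A [domain_box()].
#' @return `list(force, torque)`, two `n x 3` matrices.
#' @export
accumulate_forces <- function(state, links, params, box) {
  links <- as_link_table(links, state$n_fib, params$geometry$l_fib)
  forces_cpp(state$x, state$omega,
             as.integer(links$fibre_a), as.integer(links$fibre_b),
             links$s_a, links$s_b,
             params_for_cpp(params), box$lengths)
}
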