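#' Periodic cuboid simulation domain
#'
#' The domain is the cuboid `[-Lx/2, Lx/2) x [-Ly/2, Ly/2) x [-Lz/2, Lz/2)`
#' with periodic boundary conditions: a fibre leaving through one face
#' re-enters through the opposite one, and all pair interactions use the
#' minimum-image (periodicised Euclidean) distance.
#'
#' @param lx,ly,lz Strictly positive side lengths (length units); `ly` and
#'   `lz` default to `lx` (cubic box).
#' @return A `domain_box` object with elements `lengths` (numeric 3-vector)
#'   and `volume`.
#' @examples
#' domain_box(30)
#' @export
domain_box <- function(lx, ly = lx, lz = lx) {
  l <- c(lx, ly, lz)
  if (!is.numeric(l) || length(l) != 3 || any(!is.finite(l)) || any(l <= 0))
    stop("box side lengths must be finite and strictly positive")
  structure(list(lengths = as.numeric(l), volume = prod(l)),
            class = "domain_box")
}

#' @export
print.domain_box <- function(x, ...) {
  cat(sprintf("periodic box %g x %g x %g (volume %g)\n",
              x$lengths[1], x$lengths[2], x$lengths[3], x$volume))
  invisible(x)
}

#' Fibre unit geometry
#'
#' A fibre unit is a rigid spherocylinder: a segment of length `l_fib`
#' (the axis) with circular cross-section of radius `r_fib`. Two fibres are
#' in steric contact when their axes are closer than `2 * r_fib`.
#'
#' @param l_fib Fibre length (length units), default 6.
#' @param r_fib Fibre radius (length units), default 0.5 (aspect ratio 6).
#' @return A `fibre_geometry` object.
#' @export
fibre_geometry <- function(l_fib = 6, r_fib = 0.5) {
  if (!is.finite(l_fib) || l_fib <= 0) stop("l_fib must be > 0")
  if (!is.finite(r_fib) || r_fib <= 0) stop("r_fib must be > 0")
  structure(list(l_fib = as.numeric(l_fib), r_fib = as.numeric(r_fib)),
            class = "fibre_geometry")
}

#' Calibrated weight of the odd term in the crosslink alignment torque
#'
#' The alignment torque exerted across a crosslink between fibres with
#' directions `w1`, `w2` (dot product `c`) is
#' `T = alpha_align / (1 + a) * (c + a * sign(c)) * (w1 x w2)`,
#' the negative gradient of the nematic potential
#' `V = -alpha_align / (1 + a) * (c^2 / 2 + a * |c|)`.
#' The quadratic (Maier-Saupe-type) part alone has zero torque for
#' perpendicular fibres, so the worst-case relaxation never starts; the
#' small odd `sign` term removes that saddle. The weight `a` is fixed by
#' requiring that two perpendicular centre-crosslinked fibres reach a
#' relative angle of 0.9 degrees at exactly
#' `4.27 * mu_fib * l_fib^3 / alpha_align`, the published characteristic
#' alignment time. `align_blend_calibrate()` recomputes `a` from the
#' closed-form relaxation integral; `align_blend_default()` returns the
#' frozen value.
#'
#' @return A scalar weight in (0, 1).
#' @examples
#' align_blend_default()
#' @export
align_blend_default <- function() 0.0132410133681319

#' @rdname align_blend_default
#' @param target Dimensionless relaxation-time constant (default 4.27).
#' @param theta_final Target relative angle in radians (default 0.9 degrees).
#' @export
align_blend_calibrate <- function(target = 4.27, theta_final = 0.9 * pi / 180) {
  # time constant for theta' = -(2/(1+a)) (cos theta + a) sin theta is
  # (1+a)/2 * int_0^{cos(theta_f)} dc / ((1-c^2)(c+a))
  tconst <- function(a) {
    i0 <- stats::integrate(function(c) 1 / ((1 - c^2) * (c + a)),
                           0, cos(theta_final), rel.tol = 1e-12)$value
    (1 + a) * i0 / 2
  }
  stats::uniroot(function(a) tconst(a) - target, c(1e-5, 1), tol = 1e-14)$root
}

#' Model parameters
#'
#' Collects all physical and kinetic parameters of the fibre network model.
#' Units follow the mass/length/time (M, L, T) scaling of the model: forces
#' and torques are per unit overlap or angle, and `mu_fib` is the friction
#' coefficient of the overdamped dynamics (`mu_fib = 1` defines the
#' simulation time unit U_t).
#'
#' The linked fibre fraction `chi_link = nu_link / (nu_link + nu_unlink)`
#' is the stationary probability that an eligible (close enough) fibre pair
#' is crosslinked; `nu_unlink` is derived from `nu_link` and `chi_link`.
#'
#' @param n_fib Number of fibre units.
#' @param geometry A [fibre_geometry()].
#' @param alpha_rep Repulsion force magnitude (M L^-1 T^-2).
#' @param alpha_rest Crosslink spring stiffness (M T^-2).
#' @param alpha_align Crosslink alignment torque magnitude (M L^2 T^-2).
#' @param d_link_max Perception distance for link creation (L).
#' @param d_link_eq Unloaded crosslink length (L).
#' @param nu_link Linking frequency (T^-1), >= 0.
#' @param chi_link Equilibrium linked fraction in \[0, 1\].
#' @param mu_fib Friction coefficient (M L^-1 T^-1), default 1.
#' @param t_final Total simulated time (T).
#' @param align_blend Odd-term weight of the alignment torque; see
#'   [align_blend_default()].
#' @return A `fib_params` object (list) with the derived `nu_unlink`.
#' @examples
#' p <- model_params(n_fib = 1500, nu_link = 0.1, chi_link = 0.5)
#' p$nu_unlink  # 0.1 * (1 - 0.5) / 0.5
#' @export
model_params <- function(n_fib = 1500,
                         geometry = fibre_geometry(),
                         alpha_rep = 12.5,
                         alpha_rest = 5.0,
                         alpha_align = 2.0,
                         d_link_max = 1.0,
                         d_link_eq = 1.0,
                         nu_link = 0.1,
                         chi_link = 0.5,
                         mu_fib = 1.0,
                         t_final = 5e4,
                         align_blend = align_blend_default()) {
  stopifnot(inherits(geometry, "fibre_geometry"))
  if (!is.finite(n_fib) || n_fib < 0 || n_fib != round(n_fib))
    stop("n_fib must be a non-negative integer")
  for (nm in c("alpha_rep", "alpha_rest", "alpha_align")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0) stop(nm, " must be >= 0")
  }
  if (!is.finite(d_link_max) || d_link_max < 0) stop("d_link_max must be >= 0")
  if (!is.finite(d_link_eq) || d_link_eq < 0) stop("d_link_eq must be >= 0")
  if (!is.finite(nu_link) || nu_link < 0) stop("nu_link must be >= 0")
  if (!is.finite(chi_link) || chi_link < 0 || chi_link > 1)
    stop("chi_link must lie in [0, 1]")
  if (chi_link == 0 && nu_link > 0)
    stop("chi_link = 0 is inconsistent with nu_link > 0")
  if (!is.finite(mu_fib) || mu_fib <= 0) stop("mu_fib must be > 0")
  if (!is.finite(t_final) || t_final < 0) stop("t_final must be >= 0")
  nu_unlink <- if (chi_link > 0) nu_link * (1 - chi_link) / chi_link else 0
  structure(list(
    n_fib = as.integer(n_fib), geometry = geometry,
    alpha_rep = alpha_rep, alpha_rest = alpha_rest, alpha_align = alpha_align,
    d_link_max = d_link_max, d_link_eq = d_link_eq,
    nu_link = nu_link, chi_link = chi_link, nu_unlink = nu_unlink,
    mu_fib = mu_fib, t_final = t_final, align_blend = align_blend),
    class = "fib_params")
}

#' @export
print.fib_params <- function(x, ...) {
  cat(sprintf(paste0(
    "fibre network parameters: N_fib=%d, L_fib=%g, R_fib=%g\n",
    "  alpha_rep=%g alpha_rest=%g alpha_align=%g\n",
    "  d_link_max=%g d_link_eq=%g nu_link=%g chi_link=%g (nu_unlink=%g)\n",
    "  mu_fib=%g T_final=%g\n"),
    x$n_fib, x$geometry$l_fib, x$geometry$r_fib,
    x$alpha_rep, x$alpha_rest, x$alpha_align,
    x$d_link_max, x$d_link_eq, x$nu_link, x$chi_link, x$nu_unlink,
    x$mu_fib, x$t_final))
  invisible(x)
}

#' Adaptive time-step control
#'
#' The integrator chooses each step as
#' `dt = min(dt_max, dx_max / max|v|, dtheta_max / max|domega/dt|)` so no
#' fibre moves further than `dx_max` or turns more than `dtheta_max` in one
#' step; an error is raised if the required step falls below `dt_min`
#' (stiff configuration).
#'
#' @param dx_max Maximum per-step displacement (L).
#' @param dtheta_max Maximum per-step rotation (radians).
#' @param dt_min,dt_max Hard bounds on the step (T).
#' @param dt_init Nominal initial step; must lie in `[dt_min, dt_max]`.
#' @return A `step_control` object.
#' @export
step_control <- function(dx_max = 0.05, dtheta_max = 0.05,
                         dt_min = 1e-9, dt_max = 5, dt_init = 1e-3) {
  if (!is.finite(dx_max) || dx_max <= 0) stop("dx_max must be > 0")
  if (!is.finite(dtheta_max) || dtheta_max <= 0) stop("dtheta_max must be > 0")
  if (!is.finite(dt_min) || dt_min <= 0 || !is.finite(dt_max) || dt_max <= 0)
    stop("dt bounds must be > 0")
  if (dt_min > dt_max) stop("dt_min must be <= dt_max")
  if (dt_init < dt_min || dt_init > dt_max)
    stop("dt_init must lie in [dt_min, dt_max]")
  structure(list(dx_max = dx_max, dtheta_max = dtheta_max,
                 dt_min = dt_min, dt_max = dt_max, dt_init = dt_init),
            class = "step_control")
}

# flatten parameters for the C++ kernels
params_for_cpp <- function(params) {
  list(l_fib = params$geometry$l_fib, r_fib = params$geometry$r_fib,
       alpha_rep = params$alpha_rep, alpha_rest = params$alpha_rest,
       alpha_align = params$alpha_align, align_blend = params$align_blend,
       d_link_max = params$d_link_max, d_link_eq = params$d_link_eq,
       nu_link = params$nu_link, nu_unlink = params$nu_unlink,
       mu_fib = params$mu_fib)
}

# minimum-image images are unambiguous only while a fibre (plus its radius)
# fits in half the box
check_geometry_box <- function(geometry, box) {
  if (geometry$l_fib + 2 * geometry$r_fib >= min(box$lengths) / 2)
    stop("l_fib + 2*r_fib must be < min(box)/2 for the minimum-image ",
         "convention to be unambiguous")
  invisible(TRUE)
}
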