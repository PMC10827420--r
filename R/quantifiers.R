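#' Fibre volume fraction
#'
#' Ratio of the total (non-overlapping) fibre volume to the domain volume:
#' `phi = n_fib * (pi r^2 l + 4/3 pi r^3) / (Lx Ly Lz)` -- each fibre is a
#' spherocylinder of length `l_fib` and radius `r_fib`.
#'
#' @param n_fib Number of fibres.
#' @param geometry A [fibre_geometry()].
#' @param box A [domain_box()].
#' @return The volume fraction `phi_fib`.
#' @examples
#' fibre_density(3000, fibre_geometry(6, 0.5), domain_box(30))  # 0.58
#' @export
fibre_density <- function(n_fib, geometry, box) {
  if (box$volume <= 0) stop("box volume must be positive")
  r <- geometry$r_fib
  v_fib <- pi * r^2 * geometry$l_fib + 4 / 3 * pi * r^3
  n_fib * v_fib / box$volume
}

#' Density regime label
#'
#' Compares the volume fraction with the packing densities of
#' spherocylinders: random packing `~0.4` and ordered packing `0.89`.
#' Systems below 0.4 are `sparse`, between 0.4 and 0.89 `dense`, above
#' `hyperdense`.
#'
#' @param phi Volume fraction(s).
#' @return Character vector of regime labels.
#' @export
density_regime <- function(phi) {
  ifelse(phi < 0.4, "sparse", ifelse(phi <= 0.89, "dense", "hyperdense"))
}

#' Links per fibre
#'
#' `N_linkperfib = N_links / N_fib`; equals 0.5 when every fibre belongs to
#' exactly one link (perfect matching). The emergent critical value for
#' alignment is about 0.7.
#'
#' @param links Link table (or anything with `nrow`).
#' @param n_fib Number of fibres (> 0).
#' @return Links per fibre.
#' @export
links_per_fibre <- function(links, n_fib) {
  if (n_fib <= 0) stop("n_fib must be > 0")
  nrow(links) / n_fib
}

eigen_sym3 <- function(m6) {
  # m6 = (xx, yy, zz, xy, xz, yz)
  m <- matrix(c(m6[1], m6[4], m6[5],
                m6[4], m6[2], m6[6],
                m6[5], m6[6], m6[3]), 3, 3)
  eigen(m, symmetric = TRUE, only.values = TRUE)$values
}

#' Alignment indicator of a direction set
#'
#' The eigenvalue-spread anisotropy `sqrt(l1 - l3)` of the second-moment
#' tensor `mean(omega omega^T)` of a set of unit directions: 0 when the
#' directions are uniformly distributed on the sphere (all eigenvalues
#' 1/3), `1/sqrt(2) ~ 0.707` when they are uniform in a plane (1/2, 1/2,
#' 0), and 1 when they are all parallel. [local_alignment()] applies this
#' score to each fibre's neighbourhood.
#'
#' @param omega n x 3 matrix of unit directions (n >= 1).
#' @return A value in `[0, 1]`.
#' @examples
#' alignment_indicator(rbind(c(1, 0, 0), c(1, 0, 0)))  # 1
#' @export
alignment_indicator <- function(omega) {
  omega <- rbind(omega)
  m <- crossprod(omega) / nrow(omega)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, ev[1] - ev[3]))
}

#' Local alignment indicator
#'
#' For each fibre `k`, let `M_k` be the mean of `omega omega^T` over the
#' fibre and its neighbours (fibres within segment distance
#' `2 r_fib + d_link_max`, i.e. the contact-plus-perception shell), with
#' eigenvalues `l1 >= l2 >= l3`. The indicator is the eigenvalue-spread
#' anisotropy `Al_k = sqrt(l1 - l3)`: 0 for uniformly distributed
#' neighbour directions (eigenvalues all 1/3), `1/sqrt(2) ~ 0.7` for
#' directions uniform in a plane (eigenvalues 1/2, 1/2, 0) and 1 when all
#' neighbours share the fibre's direction. It is invariant under global
#' rotations and under any per-fibre sign flip. Fibres with no neighbour
#' get `NA` and are excluded from [mean_alignment()].
#'
#' @param state A [fibre_state()].
#' @param params A [model_params()].
#' @param box A [domain_box()].
#' @param cutoff Neighbourhood radius; default `2 r_fib + d_link_max`.
#' @return Numeric vector of `Al_k` in `[0, 1]` (NA where undefined).
#' @export
local_alignment <- function(state, params, box, cutoff = NULL) {
  if (is.null(cutoff))
    cutoff <- 2 * params$geometry$r_fib + params$d_link_max
  res <- local_moment_cpp(state$x, state$omega, params$geometry$l_fib,
                          cutoff, box$lengths)
  n <- state$n_fib
  al <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (res$n_neighbours[k] == 0) next
    ev <- eigen_sym3(res$moment[k, ])
    al[k] <- sqrt(max(0, ev[1] - ev[3]))
  }
  al
}

#' Mean local alignment Al_sim
#'
#' Arithmetic mean of the local alignment indicator over all fibres with a
#' defined value (at least one neighbour).
#'
#' @inheritParams local_alignment
#' @return `Al_sim` in `[0, 1]`.
#' @export
mean_alignment <- function(state, params, box, cutoff = NULL) {
  al <- local_alignment(state, params, box, cutoff)
  if (all(is.na(al))) stop("no fibre has a defined local alignment")
  mean(al, na.rm = TRUE)
}

#' Nematic order tensor
#'
#' `Q = mean(omega omega^T) - I/3` over all fibres; its principal
#' eigenvector is the (sign-ambiguous) global director.
#'
#' @param omega n x 3 matrix of unit directions (or a [fibre_state()]).
#' @return `list(Q, eigenvalues, director)`.
#' @export
nematic_tensor <- function(omega) {
  if (inherits(omega, "fibre_state")) omega <- omega$omega
  m <- crossprod(omega) / nrow(omega)
  q <- m - diag(3) / 3
  e <- eigen(m, symmetric = TRUE)
  list(Q = q, eigenvalues = e$values, director = e$vectors[, 1])
}

#' Stereographic projection of fibre directions
#'
#' Each direction is flipped onto the half-sphere around the reference axis
#' (`omega . axis >= 0`) and projected from the antipode of the axis onto
#' the unit disk: a direction along the axis maps to the disk centre, an
#' equatorial direction to the rim. By default the axis is the principal
#' eigenvector of the nematic tensor, so aligned systems concentrate near
#' the centre regardless of the laboratory frame.
#'
#' @param omega n x 3 matrix of unit directions (or a [fibre_state()]).
#' @param axis Reference axis (default: data-driven director).
#' @return n x 2 matrix of points in the closed unit disk.
#' @export
stereographic_projection <- function(omega, axis = NULL) {
  if (inherits(omega, "fibre_state")) omega <- omega$omega
  omega <- rbind(omega)
  if (is.null(axis)) axis <- nematic_tensor(omega)$director
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame (e1, e2, axis); deterministic helper vector
  helper <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- helper - sum(helper * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  z <- drop(omega %*% axis)
  flip <- ifelse(z < 0, -1, 1)
  z <- abs(z)
  px <- flip * drop(omega %*% e1) / (1 + z)
  py <- flip * drop(omega %*% e2) / (1 + z)
  cbind(px, py)
}

#' Covariance-ellipse semi-major axis A_max
#'
#' Twice the square root of the largest eigenvalue of the 2 x 2 covariance
#' matrix of the projected points (the 2-sigma ellipse). Points uniform on
#' the unit disk give `A_max ~ 1` (per-axis variance 1/4); a value below
#' 0.45 means the 2-sigma ellipse covers under about 20% of the disk area
#' (0.45^2 = 0.2025), the global-alignment criterion.
#'
#' @param points n x 2 matrix of projected points (n >= 3).
#' @return `A_max >= 0` (0 for coincident points).
#' @export
covariance_ellipse_semi_major <- function(points) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  ctr <- sweep(points, 2, colMeans(points))
  cv <- crossprod(ctr) / n
  2 * sqrt(max(0, max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)))
}

#' Classify a network state
#'
#' Three-way classification from the local quantifier `Al_sim` and the
#' global quantifier `A_max`: `aligned` (local and global alignment,
#' `Al_sim >= 0.7` and `A_max <= 0.45`), `curved` (local but not global,
#' `Al_sim >= 0.7`, `A_max > 0.45`), `unorganized` (`Al_sim < 0.7`,
#' `A_max > 0.45`); the remaining cell (global but not local) is labelled
#' `unnamed`.
#'
#' @param al_sim Mean local alignment value(s).
#' @param a_max Covariance-ellipse semi-major axis value(s).
#' @return Character vector of state labels.
#' @examples
#' classify_state(c(0.9, 0.8, 0.4), c(0.3, 0.6, 0.8))
#' @export
classify_state <- function(al_sim, a_max) {
  if (any(!is.finite(al_sim)) || any(!is.finite(a_max)))
    stop("quantifiers must be finite")
  ifelse(al_sim >= 0.7,
         ifelse(a_max <= 0.45, "aligned", "curved"),
         ifelse(a_max <= 0.45, "unnamed", "unorganized"))
}

#' Per-frame order summary
#'
#' Computes all frame quantifiers at once: `Al_sim`, links per fibre,
#' `A_max` of the stereographic projection, and the state label.
#'
#' @param state A [fibre_state()].
#' @param links Link table.
#' @param params A [model_params()].
#' @param box A [domain_box()].
#' @return One-row `data.frame` with `t, al_sim, n_linkperfib, a_max,
#'   state_label, n_links`.
#' @export
order_summary <- function(state, links, params, box) {
  al <- mean_alignment(state, params, box)
  amax <- covariance_ellipse_semi_major(stereographic_projection(state))
  data.frame(t = state$t, al_sim = al,
             n_linkperfib = links_per_fibre(links, state$n_fib),
             a_max = amax, state_label = classify_state(al, amax),
             n_links = nrow(links))
}

#' Replicate ensemble summary
#'
#' Mean and population standard deviation of the equilibrium `Al_sim` and
#' `N_linkperfib` over replicate runs with identical parameters.
#'
#' @param al_sim Equilibrium `Al_sim` of each replicate (length >= 2).
#' @param n_linkperfib Equilibrium links per fibre of each replicate.
#' @return `list(al_mean, al_sd, nlink_mean, nlink_sd, n_replicates)`.
#' @export
ensemble_summary <- function(al_sim, n_linkperfib) {
  if (length(al_sim) < 2 || length(al_sim) != length(n_linkperfib))
    stop("need >= 2 replicates with matching lengths")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(al_mean = mean(al_sim), al_sd = pop_sd(al_sim),
       nlink_mean = mean(n_linkperfib), nlink_sd = pop_sd(n_linkperfib),
       n_replicates = length(al_sim))
}

#' Time constant of the alignment growth
#'
#' Fits the saturating form `A(t) = A_inf - (A_inf - A_0) exp(-t / tau)`
#' to an alignment time series and returns `tau_Al`, the time at which the
#' fitted curve reaches 63% of its fitted asymptote `A_inf`. A constant
#' series returns 0; a series that has not begun to plateau (last-decile
#' trend still a sizeable fraction of the total rise) raises an error.
#'
#' @param t Frame times.
#' @param al Alignment values (same length).
#' @param level Fraction of the asymptote defining the time constant
#'   (default 0.63).
#' @return `tau_Al`, with the fit as attribute `"fit"`.
#' @export
fit_tau_al <- function(t, al, level = 0.63) {
  stopifnot(length(t) == length(al), length(t) >= 4)
  o <- order(t)
  t <- t[o]; al <- al[o]
  rng <- diff(range(al))
  if (rng < 1e-12) return(structure(0, fit = NULL))
  # plateau check: compare the late-time slope-driven change to the rise
  n <- length(t)
  tail_idx <- t >= t[1] + 0.8 * (t[n] - t[1])
  if (sum(tail_idx) >= 2) {
    tail_change <- abs(mean(al[tail_idx]) - al[n])
    late_rise <- abs(al[n] - stats::quantile(al, 0.5, names = FALSE))
    if (late_rise > 0.35 * rng && tail_change > 0.05 * rng)
      stop("series does not appear to saturate; cannot estimate tau_Al")
  }
  a0 <- al[1]; ainf <- max(al)
  tau0 <- t[which.max(al >= a0 + 0.63 * (ainf - a0))]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- stats::median(t)
  resid_fn <- function(par)
    al - (par[1] - (par[1] - par[2]) * exp(-t / par[3]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(ainf = ainf, a0 = a0, tau = tau0),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("saturating fit failed: ", conditionMessage(e)))
  cf <- as.list(fit$par)
  if (cf[["tau"]] <= 0 || cf[["ainf"]] <= 0)
    stop("saturating fit did not converge to a growing curve")
  if (cf[["tau"]] > 0.7 * (t[n] - t[1]))
    stop("series does not appear to saturate within its span")
  target <- level * cf[["ainf"]]
  tau_al <- if (cf[["a0"]] >= target) 0 else
    -cf[["tau"]] * log((cf[["ainf"]] - target) / (cf[["ainf"]] - cf[["a0"]]))
  structure(tau_al, fit = fit)
}

#' Logarithmic law of alignment versus connectivity
#'
#' Below a critical number of links per fibre, the equilibrium mean
#' alignment follows `Al_mean ~ alpha * log(N_linkperfib) + beta`
#' (natural logarithm); above it, alignment drops abruptly. The fit is a
#' least-squares line in `log(N_linkperfib)` restricted to the
#' below-threshold branch, detected by walking the points in increasing
#' connectivity and flagging the first point whose alignment falls more
#' than `drop_frac` (relative) below the running fit; that point's
#' `N_linkperfib` is the `N_critic` estimate.
#'
#' @param n_linkperfib Links-per-fibre values (> 0).
#' @param al_mean Matching equilibrium alignment values.
#' @param drop_frac Relative shortfall declaring the drop (default 0.1).
#' @param min_points Minimum points fitted before testing for the drop.
#' @return `list(alpha, beta, r_squared, n_critic, n_used, fit)`;
#'   `n_critic` is `NA` when no drop is detected.
#' @export
fit_log_law <- function(n_linkperfib, al_mean, drop_frac = 0.1,
                        min_points = 4) {
  stopifnot(length(n_linkperfib) == length(al_mean))
  if (any(n_linkperfib <= 0)) stop("n_linkperfib must be > 0")
  if (length(n_linkperfib) < min_points)
    stop("need at least ", min_points, " points")
  o <- order(n_linkperfib)
  x <- log(n_linkperfib[o]); y <- al_mean[o]
  n <- length(x)
  cutoff <- n
  for (i in seq(min_points, n - 1)) {
    f <- lm(y[1:i] ~ x[1:i])
    pred <- coef(f)[1] + coef(f)[2] * x[i + 1]
    if (y[i + 1] < pred * (1 - drop_frac)) { cutoff <- i; break }
  }
  xf <- x[1:cutoff]; yf <- y[1:cutoff]
  fit <- lm(yf ~ xf)
  tss <- sum((yf - mean(yf))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  n_critic <- if (cutoff < n) n_linkperfib[o][cutoff + 1] else NA_real_
  list(alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
       r_squared = r2, n_critic = n_critic, n_used = cutoff, fit = fit)
}
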