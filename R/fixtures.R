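unit3 <- function(v) v / sqrt(sum(v^2))

orthobasis <- function(axis) {
  axis <- unit3(axis)
  helper <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit3(helper - sum(helper * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2, axis = axis)
}

lattice_positions <- function(n, box) {
  m <- ceiling(n^(1 / 3))
  g <- (seq_len(m) - (m + 1) / 2) / m
  pts <- as.matrix(expand.grid(g * box$lengths[1], g * box$lengths[2],
                               g * box$lengths[3]))
  pts[seq_len(n), , drop = FALSE]
}

#' Synthetic orientation fields with known ground truth
#'
#' Seeded generators of fibre states whose direction statistics are known
#' exactly, used to validate the order quantifiers without running
#' simulations:
#' \describe{
#'   \item{`uniform`}{directions uniform on the (projective) sphere --
#'     nematic eigenvalues 1/3, 1/3, 1/3;}
#'   \item{`unidirectional`}{all directions equal to `axis` -- eigenvalues
#'     1, 0, 0;}
#'   \item{`planar`}{directions uniform in the plane perpendicular to
#'     `axis` -- eigenvalues 1/2, 1/2, 0;}
#'   \item{`concentration`}{Watson-type axially symmetric family with
#'     density proportional to `exp(kappa * (omega . axis)^2)`,
#'     interpolating uniform (`kappa = 0`) to unidirectional
#'     (`kappa -> Inf`), monotone in the order parameter.}
#' }
#'
#' @param kind One of the generator kinds above.
#' @param n Number of fibres.
#' @param box A [domain_box()].
#' @param seed Optional seed.
#' @param axis Symmetry axis (default z).
#' @param kappa Concentration parameter (required for `concentration`,
#'   must be >= 0).
#' @param positions `"random"` (uniform in the box) or `"lattice"`.
#' @return A [fibre_state()].
#' @export
make_orientation_field <- function(kind = c("uniform", "unidirectional",
                                            "planar", "concentration"),
                                   n, box = domain_box(30), seed = NULL,
                                   axis = c(0, 0, 1), kappa = NULL,
                                   positions = c("random", "lattice")) {
  kind <- match.arg(kind)
  positions <- match.arg(positions)
  if (!is.null(seed)) set.seed(seed)
  b <- orthobasis(axis)
  w <- switch(kind,
    uniform = {
      m <- matrix(rnorm(3 * n), ncol = 3)
      m / sqrt(rowSums(m^2))
    },
    unidirectional = matrix(b$axis, n, 3, byrow = TRUE),
    planar = {
      phi <- runif(n, 0, 2 * pi)
      outer(cos(phi), b$e1) + outer(sin(phi), b$e2)
    },
    concentration = {
      if (is.null(kappa) || !is.finite(kappa) || kappa < 0)
        stop("concentration kind needs kappa >= 0")
      z <- numeric(n)
      got <- 0
      while (got < n) {         # rejection from uniform with exp(kappa z^2)
        m <- max(n - got, 64)
        cand <- runif(m, -1, 1)
        keep <- runif(m) < exp(kappa * (cand^2 - 1))
        acc <- cand[keep]
        take <- min(length(acc), n - got)
        if (take > 0) z[(got + 1):(got + take)] <- acc[seq_len(take)]
        got <- got + take
      }
      phi <- runif(n, 0, 2 * pi)
      r <- sqrt(pmax(0, 1 - z^2))
      outer(z, b$axis) + outer(r * cos(phi), b$e1) + outer(r * sin(phi), b$e2)
    })
  x <- if (positions == "lattice") lattice_positions(n, box)
       else cbind(runif(n, -box$lengths[1] / 2, box$lengths[1] / 2),
                  runif(n, -box$lengths[2] / 2, box$lengths[2] / 2),
                  runif(n, -box$lengths[3] / 2, box$lengths[3] / 2))
  fibre_state(x, w, t = 0)
}

#' Worst-case two-fibre fixtures
#'
#' The initial conditions used to define the characteristic interaction
#' times: `rep` -- two fully overlapped parallel fibres (identical centre
#' and direction), no link; `rest` -- the same pair crosslinked at their
#' centres (`s_a = s_b = 0`); `align` -- two perpendicular fibres crossing
#' at their centres, crosslinked there.
#'
#' @param kind One of `"rep"`, `"rest"`, `"align"`.
#' @param geometry A [fibre_geometry()] (kept for interface symmetry).
#' @param box A [domain_box()].
#' @return `list(state, links)`.
#' @export
make_two_fibre_fixture <- function(kind = c("rep", "rest", "align"),
                                   geometry = fibre_geometry(),
                                   box = domain_box(30)) {
  kind <- match.arg(kind)
  x <- matrix(0, 2, 3)
  w <- switch(kind,
    rep = rbind(c(1, 0, 0), c(1, 0, 0)),
    rest = rbind(c(1, 0, 0), c(1, 0, 0)),
    align = rbind(c(1, 0, 0), c(0, 1, 0)))
  links <- if (kind == "rep") empty_links() else
    data.frame(fibre_a = 1L, fibre_b = 2L, s_a = 0, s_b = 0, t_created = 0)
  list(state = fibre_state(x, w, t = 0, box = box), links = links)
}

#' Synthetic link topologies
#'
#' `perfect_matching` pairs fibres (1,2), (3,4), ... so every fibre belongs
#' to exactly one link (`N_linkperfib = 0.5`); `bernoulli` links each
#' eligible pair (segment distance <= `d_link_max`) independently with
#' probability `chi` -- this is also how initial links are seeded in
#' [run_simulation()]. Attachment abscissae are the closest-point abscissae
#' of each pair.
#'
#' @param state A [fibre_state()].
#' @param kind `"perfect_matching"` or `"bernoulli"`.
#' @param chi Link probability for `bernoulli`.
#' @param params A [model_params()].
#' @param box A [domain_box()].
#' @param seed Optional seed.
#' @return A link table.
#' @export
make_link_topology <- function(state, kind = c("perfect_matching", "bernoulli"),
                               chi = NULL, params = model_params(),
                               box = domain_box(30), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "perfect_matching") {
    n <- state$n_fib
    if (n %% 2 != 0) stop("perfect matching needs an even number of fibres")
    a <- seq(1, n, by = 2)
    b <- a + 1
    sa <- sb <- numeric(length(a))
    for (k in seq_along(a)) {
      cp <- segment_closest_points(state$x[a[k], ], state$omega[a[k], ],
                                   state$x[b[k], ], state$omega[b[k], ],
                                   params$geometry, box)
      sa[k] <- cp$s1; sb[k] <- cp$s2
    }
    data.frame(fibre_a = a, fibre_b = b, s_a = sa, s_b = sb,
               t_created = state$t)
  } else {
    if (is.null(chi) || chi < 0 || chi > 1) stop("bernoulli needs chi in [0, 1]")
    pairs <- eligible_pairs(state, params, box)
    if (nrow(pairs) == 0 || chi == 0) return(empty_links())
    hit <- runif(nrow(pairs)) < chi
    data.frame(fibre_a = pairs$i[hit], fibre_b = pairs$j[hit],
               s_a = pairs$s1[hit], s_b = pairs$s2[hit],
               t_created = state$t)
  }
}
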