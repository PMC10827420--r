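#' Fibre pairs eligible for link creation
#'
#' A pair is eligible when the minimum-image distance between the two axis
#' segments is at most the perception distance `d_link_max` and the pair is
#' not already linked. The scan uses a centre-distance prefilter but the
#' result is identical to an all-pairs scan.
#'
#' @param state A [fibre_state()].
#' @param params A [model_params()] (supplies geometry and `d_link_max`).
#' @param box A [domain_box()].
#' @param links Optional link table; linked pairs are excluded.
#' @return A `data.frame` with columns `i, j` (i < j), the closest-point
#'   abscissae `s1, s2` and `distance`.
#' @export
eligible_pairs <- function(state, params, box, links = NULL) {
  res <- neighbour_pairs_cpp(state$x, state$omega, params$geometry$l_fib,
                             params$d_link_max, box$lengths)
  out <- data.frame(i = res$i, j = res$j, s1 = res$s1, s2 = res$s2,
                    distance = res$distance)
  if (!is.null(links) && nrow(links)) {
    key <- paste(out$i, out$j)
    lkey <- paste(links$fibre_a, links$fibre_b)
    out <- out[!(key %in% lkey), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Sample link-creation events
#'
#' Each eligible pair links independently with probability
#' `1 - exp(-nu_link * dt)` (Bernoulli thinning of the Poisson linking
#' process over one step). New links attach at the pair's current closest
#' points.
#'
#' @param pairs Eligible pairs as returned by [eligible_pairs()].
#' @param nu_link Linking frequency (>= 0).
#' @param dt Time step (> 0).
#' @param t Creation time stamp for the new links.
#' @return A link table of the newly created links.
#' @export
sample_link_events <- function(pairs, nu_link, dt, t = 0) {
  if (nu_link < 0) stop("nu_link must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  n <- nrow(pairs)
  if (n == 0 || nu_link == 0) return(empty_links())
  p <- 1 - exp(-nu_link * dt)
  hit <- runif(n) < p
  if (!any(hit)) return(empty_links())
  data.frame(fibre_a = pairs$i[hit], fibre_b = pairs$j[hit],
             s_a = pairs$s1[hit], s_b = pairs$s2[hit], t_created = t)
}

#' Sample link-removal events
#'
#' Each existing link is removed independently with probability
#' `1 - exp(-nu_unlink * dt)`; removal does not depend on the spring
#' extension (no force-dependent unbinding).
#'
#' @param links Link table.
#' @param nu_unlink Unlinking frequency (>= 0).
#' @param dt Time step (> 0).
#' @return Integer indices (rows of `links`) of the links to delete.
#' @export
sample_unlink_events <- function(links, nu_unlink, dt) {
  if (nu_unlink < 0) stop("nu_unlink must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  n <- nrow(links)
  if (n == 0 || nu_unlink == 0) return(integer())
  p <- 1 - exp(-nu_unlink * dt)
  which(runif(n) < p)
}

#' Equilibrium linked fraction
#'
#' The stationary probability that an eligible pair is linked under the
#' two-state link/unlink birth-death process:
#' `chi_link = nu_link / (nu_link + nu_unlink)`.
#'
#' @param nu_link,nu_unlink Non-negative rates, not both zero.
#' @return The stationary linked fraction.
#' @examples
#' equilibrium_linked_fraction(1, 1)  # 0.5
#' @export
equilibrium_linked_fraction <- function(nu_link, nu_unlink) {
  if (nu_link < 0 || nu_unlink < 0) stop("rates must be >= 0")
  if (nu_link + nu_unlink == 0)
    stop("equilibrium fraction undefined when both rates are zero")
  nu_link / (nu_link + nu_unlink)
}

#' Link kinetics on a frozen configuration
#'
#' Runs only the link/unlink birth-death process on a fixed geometry: the
#' eligible pair set is computed once, then each pair's linked indicator
#' evolves as a two-state Markov chain with per-step probabilities
#' `1 - exp(-nu dt)`. Useful for checking stationarity against
#' [equilibrium_linked_fraction()].
#'
#' @param state A [fibre_state()] (never moved).
#' @param params A [model_params()].
#' @param box A [domain_box()].
#' @param t_total Total simulated kinetic time.
#' @param dt Kinetic step; default `0.05 / max(nu_link, nu_unlink)`.
#' @param burn_in Time discarded before averaging.
#' @param seed Optional seed.
#' @return `list(mean_linked_fraction, trace, n_eligible, chi_link)`; the
#'   trace holds the linked fraction after every step.
#' @export
simulate_link_kinetics <- function(state, params, box, t_total,
                                   dt = NULL, burn_in = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (params$nu_link <= 0) stop("nu_link must be > 0 for frozen kinetics")
  rate <- max(params$nu_link, params$nu_unlink)
  if (is.null(dt)) dt <- 0.05 / rate
  pairs <- eligible_pairs(state, params, box)
  m <- nrow(pairs)
  if (m == 0) stop("no eligible pairs in this configuration")
  p_on <- 1 - exp(-params$nu_link * dt)
  p_off <- 1 - exp(-params$nu_unlink * dt)
  n_steps <- ceiling(t_total / dt)
  linked <- rep(FALSE, m)
  trace <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    u <- runif(m)
    linked <- ifelse(linked, u >= p_off, u < p_on)
    trace[s] <- mean(linked)
  }
  keep <- seq_len(n_steps) > burn_in / dt
  list(mean_linked_fraction = mean(trace[keep]), trace = trace,
       n_eligible = m, chi_link = params$chi_link, dt = dt)
}
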