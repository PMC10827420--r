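advance_raw <- function(state, links, params, ctrl, box, t_target,
                        max_steps = .Machine$integer.max, do_events = TRUE,
                        log_events = FALSE) {
  links <- as_link_table(links, state$n_fib, params$geometry$l_fib)
  advance_cpp(state$x, state$omega,
              as.integer(links$fibre_a), as.integer(links$fibre_b),
              links$s_a, links$s_b, links$t_created,
              state$t, t_target, as.integer(max_steps),
              params_for_cpp(params), unclass(ctrl), box$lengths,
              do_events, log_events)
}

advance_result <- function(res) {
  state <- structure(list(x = res$X, omega = res$W, t = res$t,
                          n_fib = nrow(res$X)),
                     class = "fibre_state")
  links <- data.frame(fibre_a = res$fibre_a, fibre_b = res$fibre_b,
                      s_a = res$s_a, s_b = res$s_b, t_created = res$t_created)
  events <- data.frame(t = res$event_t,
                       event = ifelse(res$event_type > 0, "link", "unlink"),
                       fibre_a = res$event_a, fibre_b = res$event_b)
  list(state = state, links = links, events = events,
       steps = res$steps, dt_last = res$dt_last,
       max_step_displacement = res$max_step_displacement,
       max_step_rotation = res$max_step_rotation)
}

#' Single adaptive Euler step
#'
#' Performs one deterministic step of the overdamped dynamics (no link
#' events): positions move by `dt * F / (mu_fib * l_fib)` and are wrapped;
#' directions move by `dt * (T x omega) / (mu_fib * l_fib^3)` and are
#' renormalised. The step `dt` is chosen adaptively (see [step_control()]).
#'
#' @param state A [fibre_state()].
#' @param links Link table.
#' @param params A [model_params()].
#' @param ctrl A [step_control()].
#' @param box A [domain_box()].
#' @return `list(state, dt, max_step_displacement, max_step_rotation)`.
#' @export
euler_step <- function(state, links, params, ctrl, box) {
  check_geometry_box(params$geometry, box)
  res <- advance_result(advance_raw(state, links, params, ctrl, box,
                                    t_target = Inf, max_steps = 1,
                                    do_events = FALSE))
  list(state = res$state, dt = res$dt_last,
       max_step_displacement = res$max_step_displacement,
       max_step_rotation = res$max_step_rotation)
}

default_ctrl <- function(params) {
  step_control(dx_max = 0.1 * params$geometry$r_fib, dtheta_max = 0.05,
               dt_min = 1e-9, dt_max = 5, dt_init = 1e-3)
}

#' Run a full network simulation
#'
#' Starts from a uniformly random state (or a supplied one), optionally
#' seeds an initial crosslink set by linking every eligible pair with
#' probability `chi_link`, then advances the coupled overdamped/jump system
#' to `t_final`, recording frames at (by default) logarithmically spaced
#' times -- the order quantifiers evolve logarithmically, so late times need
#' sparse sampling only. Fully reproducible from the seed.
#'
#' @param params A [model_params()].
#' @param box A [domain_box()].
#' @param ctrl A [step_control()]; default caps displacement at
#'   `0.1 * r_fib` and rotation at 0.05 rad per step.
#' @param seed Integer seed; when given, `set.seed(seed)` is called so the
#'   whole run (insemination, initial links, events) is reproducible.
#' @param state Optional initial [fibre_state()] (overrides insemination).
#' @param links Optional initial link table (overrides `init_links`).
#' @param init_links Link each initially eligible pair with probability
#'   `chi_link` (default `TRUE`); this also gives non-dynamical networks
#'   (`nu_link = 0`) their fixed link set.
#' @param n_frames Number of recorded frames.
#' @param frame_times Explicit frame times (overrides `n_frames`).
#' @param quantify Compute the per-frame [order_summary()] (default `TRUE`).
#' @param log_events Keep the link/unlink event log.
#' @return A `fib_trajectory`: list with `frames` (each `list(state,
#'   links)`), `summary` (one row per frame), `events`, `params`, `box`,
#'   `ctrl`, `seed`.
#' @export
run_simulation <- function(params, box, ctrl = NULL, seed = NULL,
                           state = NULL, links = NULL, init_links = TRUE,
                           n_frames = 40, frame_times = NULL,
                           quantify = TRUE, log_events = FALSE) {
  check_geometry_box(params$geometry, box)
  if (is.null(ctrl)) ctrl <- default_ctrl(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- random_fibre_state(params$n_fib, box)
  if (is.null(links)) {
    links <- if (init_links && params$chi_link > 0 && state$n_fib > 1)
      make_link_topology(state, "bernoulli", chi = params$chi_link,
                         params = params, box = box)
    else empty_links()
  }
  if (is.null(frame_times)) {
    t1 <- params$t_final / 500
    frame_times <- if (params$t_final > 0)
      unique(c(exp(seq(log(t1), log(params$t_final), length.out = n_frames))))
    else numeric()
  }
  frame_times <- sort(frame_times[frame_times > state$t])

  frames <- vector("list", length(frame_times) + 1)
  summaries <- vector("list", length(frame_times) + 1)
  events <- list()
  frames[[1]] <- list(state = state, links = links)
  if (quantify)
    summaries[[1]] <- order_summary(state, links, params, box)
  for (k in seq_along(frame_times)) {
    res <- advance_result(advance_raw(state, links, params, ctrl, box,
                                      t_target = frame_times[k],
                                      do_events = TRUE,
                                      log_events = log_events))
    state <- res$state
    links <- res$links
    if (log_events) events[[k]] <- res$events
    frames[[k + 1]] <- list(state = state, links = links)
    if (quantify)
      summaries[[k + 1]] <- order_summary(state, links, params, box)
  }
  summary <- if (quantify) do.call(rbind, summaries) else NULL
  structure(list(frames = frames, summary = summary,
                 events = if (log_events) do.call(rbind, events) else NULL,
                 params = params, box = box, ctrl = ctrl, seed = seed),
            class = "fib_trajectory")
}

#' @export
print.fib_trajectory <- function(x, ...) {
  n <- length(x$frames)
  last <- x$frames[[n]]
  cat(sprintf("fibre trajectory: %d fibres, %d frames, t in [%g, %g]\n",
              last$state$n_fib, n, x$frames[[1]]$state$t, last$state$t))
  if (!is.null(x$summary)) {
    s <- x$summary[nrow(x$summary), ]
    cat(sprintf("  final: Al_sim=%.3f  N_linkperfib=%.3f  A_max=%.3f  (%s)\n",
                s$al_sim, s$n_linkperfib, s$a_max, s$state_label))
  }
  invisible(x)
}

#' Characteristic two-fibre interaction times
#'
#' Integrates the worst-case two-fibre configuration under a single
#' interaction and returns the time at which the pair reaches 99% of its
#' equilibrium state:
#' \describe{
#'   \item{`"rep"`}{fully overlapped parallel fibres, repulsion only, until
#'     the centre distance reaches `0.99 * 2 r_fib`;}
#'   \item{`"rest"`}{fully overlapped fibres crosslinked at their centres,
#'     spring only, until the centre distance reaches `0.99 * d_link_eq`
#'     (closed form `ln(10) mu_fib l_fib / alpha_rest`);}
#'   \item{`"align"`}{perpendicular fibres crosslinked at their centres,
#'     alignment torque only, until the relative angle reaches 0.9 degrees
#'     (calibrated to `4.27 mu_fib l_fib^3 / alpha_align`).}
#' }
#' The crossing time is linearly interpolated between the bracketing steps.
#'
#' @param interaction One of `"rep"`, `"rest"`, `"align"`.
#' @param params A [model_params()]; only the relevant magnitude is used,
#'   the other interactions are switched off.
#' @param box A [domain_box()]; default 30^3.
#' @param resolution Per-step displacement cap as a fraction of `r_fib`
#'   (and rotation cap in radians x 1e-0); smaller is more accurate.
#' @param max_time Error if the criterion is not met by this time.
#' @return The elapsed time (in simulation time units).
#' @export
two_fibre_characteristic_time <- function(interaction = c("rep", "rest", "align"),
                                          params = model_params(),
                                          box = domain_box(30),
                                          resolution = 1e-4,
                                          max_time = 1e5) {
  interaction <- match.arg(interaction)
  relevant <- switch(interaction, rep = params$alpha_rep,
                     rest = params$alpha_rest, align = params$alpha_align)
  if (relevant <= 0) stop("the selected interaction has zero magnitude")
  p <- params
  p$alpha_rep <- if (interaction == "rep") params$alpha_rep else 0
  p$alpha_rest <- if (interaction == "rest") params$alpha_rest else 0
  p$alpha_align <- if (interaction == "align") params$alpha_align else 0
  p$nu_link <- 0; p$nu_unlink <- 0
  fx <- make_two_fibre_fixture(interaction, p$geometry, box)
  state <- fx$state
  links <- fx$links
  ctrl <- step_control(dx_max = resolution * p$geometry$r_fib,
                       dtheta_max = resolution,
                       dt_min = 1e-12, dt_max = 1e4, dt_init = 1e-6)

  target <- switch(interaction,
    rep = 0.99 * 2 * p$geometry$r_fib,
    rest = 0.99 * p$d_link_eq,
    align = NA_real_)
  measure <- function(st) {
    if (interaction == "align") {
      cc <- abs(sum(st$omega[1, ] * st$omega[2, ]))
      acos(min(1, cc))
    } else {
      sqrt(sum(periodic_displacement(st$x[1, ], st$x[2, ], box)^2))
    }
  }
  # rep/rest: distance grows to target; align: angle falls to 0.9 degrees
  crossed <- if (interaction == "align") {
    target <- 0.9 * pi / 180
    function(v) v <= target
  } else function(v) v >= target

  v_prev <- measure(state)
  t_prev <- state$t
  # advance in small step batches; the criterion crossing is interpolated
  # between batch ends, whose spacing is tiny at these step caps
  repeat {
    res <- advance_result(advance_raw(state, links, p, ctrl, box,
                                      t_target = Inf, max_steps = 16,
                                      do_events = FALSE))
    state <- res$state
    v <- measure(state)
    if (crossed(v)) {
      if (v == v_prev) return(state$t)
      frac <- (target - v_prev) / (v - v_prev)
      return(t_prev + frac * (state$t - t_prev))
    }
    if (state$t > max_time)
      stop("99% criterion not reached within max_time = ", max_time)
    if (state$t == t_prev)
      stop("integration stalled before reaching the criterion")
    v_prev <- v
    t_prev <- state$t
  }
}
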