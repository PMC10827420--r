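#' Replicate runs with derived seeds
#'
#' Runs `n` simulations with identical parameters and seeds
#' `base_seed + 1, ..., base_seed + n`, returning the final-frame
#' quantifiers of each run.
#'
#' @param params A [model_params()].
#' @param box A [domain_box()].
#' @param n Number of replicates.
#' @param base_seed Base seed.
#' @param ... Passed to [run_simulation()].
#' @return `data.frame` with one row per replicate (seed and final
#'   quantifiers) plus the trajectories as attribute `"trajectories"`.
#' @export
run_replicates <- function(params, box, n = 2, base_seed = 1, ...) {
  rows <- vector("list", n)
  trajs <- vector("list", n)
  for (r in seq_len(n)) {
    tr <- run_simulation(params, box, seed = base_seed + r, ...)
    s <- tr$summary[nrow(tr$summary), ]
    rows[[r]] <- cbind(replicate = r, seed = base_seed + r, s)
    trajs[[r]] <- tr
  }
  structure(do.call(rbind, rows), trajectories = trajs)
}

#' Parameter sweep over link kinetics and system size
#'
#' Executes the grid `nu_link x chi_link x n_fib` with `replicates` runs
#' per cell. Every run gets a distinct derived seed (`seed + run index`) so
#' the sweep is reproducible and any single run can be re-executed in
#' isolation. Per-run failures are recorded and the sweep continues. When
#' `config$output$dir` is set, each finished run writes a one-row
#' checkpoint CSV there and is skipped on re-run (resume).
#'
#' @param config A `fib_config` with a non-`NULL` `sweep` section.
#' @param quiet Suppress progress messages.
#' @return `list(runs, cells)`: per-run rows (`nu_link, chi_link, n_fib,
#'   replicate, seed, al_sim, n_linkperfib, a_max, state_label, status`)
#'   and per-cell aggregates (`pct_aligned`, `pct_curved`,
#'   `pct_unorganized`, `al_mean/sd`, `nlink_mean/sd`).
#' @export
run_sweep <- function(config, quiet = TRUE) {
  if (is.null(config$sweep)) stop("config has no sweep section")
  sw <- config$sweep
  grid <- expand.grid(
    nu_link = if (is.null(sw$nu_link)) config$params$nu_link else sw$nu_link,
    chi_link = if (is.null(sw$chi_link)) config$params$chi_link else sw$chi_link,
    n_fib = if (is.null(sw$n_fib)) config$params$n_fib else sw$n_fib)
  out_dir <- config$output$dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  run_idx <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(config$replicates)) {
      run_idx <- run_idx + 1L
      seed_r <- config$seed + run_idx
      ckpt <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("run_%04d.csv", run_idx)) else NULL
      if (!is.null(ckpt) && file.exists(ckpt)) {
        rows[[run_idx]] <- read.csv(ckpt)
        next
      }
      p <- config$params
      p$nu_link <- grid$nu_link[g]
      p$chi_link <- grid$chi_link[g]
      p$n_fib <- as.integer(grid$n_fib[g])
      p$nu_unlink <- if (p$chi_link > 0)
        p$nu_link * (1 - p$chi_link) / p$chi_link else 0
      row <- tryCatch({
        tr <- run_simulation(p, config$box, ctrl = config$ctrl, seed = seed_r,
                             n_frames = config$output$n_frames)
        s <- tr$summary[nrow(tr$summary), ]
        data.frame(nu_link = p$nu_link, chi_link = p$chi_link,
                   n_fib = p$n_fib, replicate = r, seed = seed_r,
                   t = s$t, al_sim = s$al_sim,
                   n_linkperfib = s$n_linkperfib, a_max = s$a_max,
                   state_label = s$state_label, status = "ok")
      }, error = function(e) {
        data.frame(nu_link = p$nu_link, chi_link = p$chi_link,
                   n_fib = p$n_fib, replicate = r, seed = seed_r,
                   t = NA_real_, al_sim = NA_real_,
                   n_linkperfib = NA_real_, a_max = NA_real_,
                   state_label = NA_character_,
                   status = paste("error:", conditionMessage(e)))
      })
      if (!is.null(ckpt)) write.csv(row, ckpt, row.names = FALSE)
      if (!quiet)
        message(sprintf("run %d/%d: nu=%g chi=%g n=%d -> %s", run_idx,
                        nrow(grid) * config$replicates, p$nu_link,
                        p$chi_link, p$n_fib, row$state_label))
      rows[[run_idx]] <- row
    }
  }
  runs <- do.call(rbind, rows)
  ok <- runs[runs$status == "ok", , drop = FALSE]
  cells <- do.call(rbind, lapply(
    split(ok, interaction(ok$nu_link, ok$chi_link, ok$n_fib, drop = TRUE)),
    function(d) {
      pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
      data.frame(nu_link = d$nu_link[1], chi_link = d$chi_link[1],
                 n_fib = d$n_fib[1], n_runs = nrow(d),
                 pct_aligned = 100 * mean(d$state_label == "aligned"),
                 pct_curved = 100 * mean(d$state_label == "curved"),
                 pct_unorganized = 100 * mean(d$state_label == "unorganized"),
                 al_mean = mean(d$al_sim), al_sd = pop_sd(d$al_sim),
                 nlink_mean = mean(d$n_linkperfib),
                 nlink_sd = pop_sd(d$n_linkperfib))
    }))
  rownames(cells) <- NULL
  list(runs = runs, cells = cells)
}
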