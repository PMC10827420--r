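config_defaults <- function() {
  list(
    params = list(n_fib = 1500, l_fib = 6, r_fib = 0.5,
                  alpha_rep = 12.5, alpha_rest = 5.0, alpha_align = 2.0,
                  d_link_max = 1.0, d_link_eq = 1.0,
                  nu_link = 0.1, chi_link = 0.5, mu_fib = 1.0,
                  t_final = 5e4),
    box = list(lx = 30, ly = 30, lz = 30),
    control = list(dx_max = 0.05, dtheta_max = 0.05,
                   dt_min = 1e-9, dt_max = 5, dt_init = 1e-3),
    output = list(n_frames = 40),
    replicates = 1,
    seed = 1,
    sweep = NULL
  )
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key", if (length(bad) > 1) "s", " in ",
         where, ": ", paste(bad, collapse = ", "))
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, by extension) configuration and returns a fully
#' validated `fib_config`. Unset fields take the model's reference values
#' (fibre length 6, radius 0.5, repulsion 12.5, spring 5.0, alignment 2.0,
#' perception and unloaded link length 1.0, cubic box of side 30, total
#' time 5e4). Unknown keys are rejected with the offending name. Sweep
#' grids must stay within the reference exploration ranges
#' (`nu_link` in \[0, 10\], `chi_link` in \[0.1, 0.9\], `n_fib` in
#' \[1500, 3000\]) unless `sweep$allow_outside: true` is set.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; an empty or
#'   missing document gives the full default configuration.
#' @return A `fib_config` list: `params` ([model_params()]), `box`
#'   ([domain_box()]), `ctrl` ([step_control()]), `output`, `replicates`,
#'   `seed`, `sweep`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_config(raw)
}

#' @rdname load_config
#' @param x A plain nested list with the configuration fields.
#' @export
as_config <- function(x = list()) {
  def <- config_defaults()
  check_keys(x, names(def), "config")
  for (sec in c("params", "box", "control"))
    if (!is.null(x[[sec]])) check_keys(x[[sec]], names(def[[sec]]), sec)
  if (!is.null(x$output)) check_keys(x$output, c("n_frames", "dir"), "output")
  merged <- def
  for (sec in names(x)) {
    merged[[sec]] <- if (is.list(def[[sec]]) && !is.null(x[[sec]]))
      modifyList(def[[sec]], x[[sec]]) else x[[sec]]
  }
  p <- merged$params
  params <- model_params(
    n_fib = p$n_fib, geometry = fibre_geometry(p$l_fib, p$r_fib),
    alpha_rep = p$alpha_rep, alpha_rest = p$alpha_rest,
    alpha_align = p$alpha_align, d_link_max = p$d_link_max,
    d_link_eq = p$d_link_eq, nu_link = p$nu_link, chi_link = p$chi_link,
    mu_fib = p$mu_fib, t_final = p$t_final)
  box <- domain_box(merged$box$lx, merged$box$ly, merged$box$lz)
  ctrl <- do.call(step_control, merged$control)
  sweep <- merged$sweep
  if (!is.null(sweep)) {
    check_keys(sweep, c("nu_link", "chi_link", "n_fib", "allow_outside"),
               "sweep")
    allow <- isTRUE(sweep$allow_outside)
    if (!allow) {
      if (!is.null(sweep$nu_link) &&
          (any(sweep$nu_link < 0) || any(sweep$nu_link > 10)))
        stop("sweep nu_link outside [0, 10]; set allow_outside to override")
      if (!is.null(sweep$chi_link) &&
          (any(sweep$chi_link < 0.1) || any(sweep$chi_link > 0.9)))
        stop("sweep chi_link outside [0.1, 0.9]; set allow_outside to override")
      if (!is.null(sweep$n_fib) &&
          (any(sweep$n_fib < 1500) || any(sweep$n_fib > 3000)))
        stop("sweep n_fib outside [1500, 3000]; set allow_outside to override")
    }
  }
  if (!is.numeric(merged$replicates) || merged$replicates < 1)
    stop("replicates must be >= 1")
  structure(list(params = params, box = box, ctrl = ctrl,
                 output = merged$output,
                 replicates = as.integer(merged$replicates),
                 seed = as.integer(merged$seed), sweep = sweep),
            class = "fib_config")
}

#' Save a configuration to YAML
#'
#' Writes the fully resolved configuration; loading it back gives an
#' identical object, so every artefact can embed its provenance.
#'
#' @param config A `fib_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  p <- config$params
  plain <- list(
    params = list(n_fib = p$n_fib, l_fib = p$geometry$l_fib,
                  r_fib = p$geometry$r_fib, alpha_rep = p$alpha_rep,
                  alpha_rest = p$alpha_rest, alpha_align = p$alpha_align,
                  d_link_max = p$d_link_max, d_link_eq = p$d_link_eq,
                  nu_link = p$nu_link, chi_link = p$chi_link,
                  mu_fib = p$mu_fib, t_final = p$t_final),
    box = as.list(setNames(config$box$lengths, c("lx", "ly", "lz"))),
    control = unclass(config$ctrl),
    output = config$output,
    replicates = config$replicates,
    seed = config$seed,
    sweep = config$sweep)
  plain <- plain[!vapply(plain, is.null, logical(1))]
  yaml::write_yaml(plain, path)
  invisible(path)
}
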