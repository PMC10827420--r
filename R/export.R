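write_vtk_frame <- function(state, al, geometry, path) {
  n <- state$n_fib
  h <- geometry$l_fib / 2
  p1 <- state$x - h * state$omega
  p2 <- state$x + h * state$omega
  al[!is.finite(al)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("fibre network frame t=%g", state$t),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", 2 * n)), con)
  pts <- matrix(rbind(t(p1), t(p2)), ncol = 3, byrow = TRUE)
  writeLines(apply(pts, 1, function(r) paste(format(r, digits = 10),
                                             collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", n, 3 * n), con)
  idx <- cbind(2, seq(0, 2 * n - 1, by = 2), seq(1, 2 * n - 1, by = 2))
  writeLines(apply(idx, 1, paste, collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", 2 * n),
               "SCALARS local_alignment double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(rep(al, each = 2), digits = 10), con)
  invisible(path)
}

#' Export trajectory frames
#'
#' Writes each recorded frame as a CSV fibre table (`fibre_id, x, y, z, ux,
#' uy, uz, t, al_k`, directions in canonical sign) and/or a legacy-ASCII
#' VTK polydata file (one polyline per fibre, local alignment as point
#' data) suitable for 3D viewers.
#'
#' @param traj A `fib_trajectory` from [run_simulation()].
#' @param dir Output directory (created if needed).
#' @param format Subset of `c("csv", "vtk")`.
#' @param prefix File name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
export_frames <- function(traj, dir, format = c("csv", "vtk"),
                          prefix = "frame") {
  format <- match.arg(format, several.ok = TRUE)
  if (!all(format %in% c("csv", "vtk"))) stop("unknown format")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    al <- local_alignment(fr$state, traj$params, traj$box)
    if ("csv" %in% format) {
      w <- canonical_directions(fr$state$omega)
      d <- data.frame(fibre_id = seq_len(fr$state$n_fib),
                      x = fr$state$x[, 1], y = fr$state$x[, 2],
                      z = fr$state$x[, 3],
                      ux = w[, 1], uy = w[, 2], uz = w[, 3],
                      t = fr$state$t, al_k = al)
      f <- file.path(dir, sprintf("%s_%04d.csv", prefix, k))
      write.csv(d, f, row.names = FALSE)
      files <- c(files, f)
    }
    if ("vtk" %in% format) {
      f <- file.path(dir, sprintf("%s_%04d.vtk", prefix, k))
      write_vtk_frame(fr$state, al, traj$params$geometry, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
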