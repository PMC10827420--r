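#' Fibre state
#'
#' The instantaneous state of the network: fibre centres `x` (n x 3, inside
#' the half-open periodic box) and non-oriented unit directions `omega`
#' (n x 3; `omega` and `-omega` describe the same fibre). The internal
#' dynamics keeps whatever sign the directions evolve into; a canonical
#' sign (first nonzero component positive) is applied only when writing
#' snapshots.
#'
#' @param x n x 3 matrix of centre positions.
#' @param omega n x 3 matrix of unit directions (normalised on input check,
#'   tolerance 1e-9).
#' @param t Current time.
#' @param box Optional [domain_box()]; when supplied, positions are wrapped
#'   into it.
#' @return A `fibre_state` object with elements `x`, `omega`, `t`, `n_fib`.
#' @export
fibre_state <- function(x, omega, t = 0, box = NULL) {
  x <- rbind(x); omega <- rbind(omega)
  storage.mode(x) <- "double"; storage.mode(omega) <- "double"
  if (ncol(x) != 3 || ncol(omega) != 3 || nrow(x) != nrow(omega))
    stop("x and omega must be n x 3 matrices with matching rows")
  if (nrow(x) > 0) {
    if (any(!is.finite(x)) || any(!is.finite(omega)))
      stop("non-finite coordinates in fibre state")
    nrm <- sqrt(rowSums(omega^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("directions must be unit vectors (tolerance 1e-9)")
  }
  if (!is.null(box)) x <- wrap_position(x, box)
  structure(list(x = x, omega = omega, t = as.numeric(t),
                 n_fib = nrow(x)),
            class = "fibre_state")
}

#' @export
print.fibre_state <- function(x, ...) {
  cat(sprintf("fibre state: %d fibres at t = %g\n", x$n_fib, x$t))
  invisible(x)
}

#' Uniform random initial state
#'
#' Positions uniform in the periodic box, directions uniform on the
#' projective (half) sphere, matching the model's random insemination.
#'
#' @param n Number of fibres.
#' @param box A [domain_box()].
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A [fibre_state()].
#' @export
random_fibre_state <- function(n, box, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  l <- box$lengths
  x <- cbind(runif(n, -l[1] / 2, l[1] / 2),
             runif(n, -l[2] / 2, l[2] / 2),
             runif(n, -l[3] / 2, l[3] / 2))
  w <- matrix(rnorm(3 * n), ncol = 3)
  w <- w / sqrt(rowSums(w^2))
  fibre_state(x, w, t = 0)
}

#' Empty crosslink table
#'
#' Crosslinks are rows `(fibre_a < fibre_b, s_a, s_b, t_created)`: the
#' attachment abscissae `s_a`, `s_b` along each fibre axis are fixed when
#' the link is created and advect rigidly with their fibres.
#'
#' @return A zero-row link `data.frame`.
#' @export
empty_links <- function() {
  data.frame(fibre_a = integer(), fibre_b = integer(),
             s_a = numeric(), s_b = numeric(), t_created = numeric())
}

as_link_table <- function(links, n_fib, l_fib) {
  if (is.null(links)) return(empty_links())
  links <- as.data.frame(links)
  need <- c("fibre_a", "fibre_b", "s_a", "s_b", "t_created")
  if (!all(need %in% names(links)))
    stop("link table needs columns: ", paste(need, collapse = ", "))
  links <- links[need]
  if (nrow(links)) {
    if (any(links$fibre_a >= links$fibre_b))
      stop("links must have fibre_a < fibre_b")
    if (any(links$fibre_a < 1) || any(links$fibre_b > n_fib))
      stop("link fibre indices out of range")
    key <- paste(links$fibre_a, links$fibre_b)
    if (anyDuplicated(key)) stop("duplicate link for a fibre pair")
    if (any(abs(links$s_a) > l_fib / 2 + 1e-12) ||
        any(abs(links$s_b) > l_fib / 2 + 1e-12))
      stop("attachment abscissae outside [-l_fib/2, l_fib/2]")
  }
  links
}

# canonical non-oriented representative: first nonzero component positive
canonical_directions <- function(omega) {
  s <- sign(omega[, 1])
  z1 <- s == 0
  if (any(z1)) {
    s[z1] <- sign(omega[z1, 2])
    z2 <- z1 & (s == 0)
    if (any(z2)) s[z2] <- sign(omega[z2, 3])
  }
  s[s == 0] <- 1
  omega * s
}

#' Write/read state snapshots as CSV
#'
#' `write_snapshot()` writes `<prefix>_fibres.csv` (columns `fibre_id, x, y,
#' z, ux, uy, uz, t`, directions in canonical sign) and
#' `<prefix>_links.csv` (`link_id, fibre_a, fibre_b, s_a, s_b, t_created`);
#' `read_snapshot()` reads them back.
#'
#' @param state A [fibre_state()].
#' @param links A link table (or `NULL` for none).
#' @param prefix File path prefix.
#' @return `write_snapshot()` returns the two file paths invisibly;
#'   `read_snapshot()` returns `list(state, links)`.
#' @export
write_snapshot <- function(state, links, prefix) {
  w <- canonical_directions(state$omega)
  fib <- data.frame(fibre_id = seq_len(state$n_fib),
                    x = state$x[, 1], y = state$x[, 2], z = state$x[, 3],
                    ux = w[, 1], uy = w[, 2], uz = w[, 3],
                    t = state$t)
  if (is.null(links)) links <- empty_links()
  lk <- cbind(link_id = seq_len(nrow(links)), links)
  pf <- paste0(prefix, "_fibres.csv")
  pl <- paste0(prefix, "_links.csv")
  write.csv(fib, pf, row.names = FALSE)
  write.csv(lk, pl, row.names = FALSE)
  invisible(c(fibres = pf, links = pl))
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(prefix) {
  fib <- read.csv(paste0(prefix, "_fibres.csv"))
  lk <- read.csv(paste0(prefix, "_links.csv"))
  state <- fibre_state(as.matrix(fib[, c("x", "y", "z")]),
                       as.matrix(fib[, c("ux", "uy", "uz")]),
                       t = fib$t[1])
  links <- lk[, c("fibre_a", "fibre_b", "s_a", "s_b", "t_created")]
  list(state = state, links = links)
}
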