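#' Finite-difference derivative estimates with index-range bookkeeping
#'
#' Estimates the time derivative of every state component from the uniform
#' samples of a trajectory, using one of three standard stencils:
#'
#' * order 1: `(x^(m+1) - x^m) / dt`, defined for `m = 0..M-1` (the one-sided
#'   difference; at interior points this is the same stencil as
#'   `(x^m - x^(m-1)) / dt` re-indexed, and it covers the full stated range
#'   including `m = 0`);
#' * order 2: central `(x^(m+1) - x^(m-1)) / (2 dt)`, `m = 1..M-1`;
#' * order 4: five-point `(-x^(m+2) + 8 x^(m+1) - 8 x^(m-1) + x^(m-2)) /
#'   (12 dt)`, `m = 2..M-2`.
#'
#' Sample indices `m` follow the time-label convention `t_m = m dt`,
#' `m = 0..M`. No smoothing is applied; because of numerical cancellation
#' the relative error of any stencil is bounded below by amplified round-off
#' of order `eps / dt`, so it cannot be driven arbitrarily low by refining
#' the grid.
#'
#' @param traj a `trajectory` (see [simulate_trajectory()]).
#' @param order stencil order: 1, 2 or 4.
#' @return An object of class `derivative_estimate`: list with `values`
#'   (`(m_max - m_min + 1) x N x n` array), `m_min`, `m_max`, `order`.
#' @seealso [exact_derivatives()] for the measured-derivative regime.
#' @examples
#' tr <- simulate_trajectory(lv_model(r = 1, k = 1), hyper_structure(2, 1),
#'                           c(0.5, 0.5), t_max = 2, M = 20)
#' fd <- finite_difference(tr, order = 2)
#' c(fd$m_min, fd$m_max)  # 1, M - 1
#' @export
finite_difference <- function(traj, order = c(2, 1, 4)) {
  stopifnot(inherits(traj, "trajectory"))
  order <- as.integer(order[1L])
  if (!order %in% c(1L, 2L, 4L)) stop("`order` must be 1, 2 or 4", call. = FALSE)
  M <- traj$M
  if (order == 4L && M < 4L) stop("order-4 stencil needs M >= 4", call. = FALSE)
  if (order == 2L && M < 2L) stop("order-2 stencil needs M >= 2", call. = FALSE)
  x <- traj$states
  dt <- traj$dt
  # rows of `x` are m + 1 (R subscripts of the 0-based sample index m)
  vals <- switch(as.character(order),
    "1" = (x[2:(M + 1), , , drop = FALSE] - x[1:M, , , drop = FALSE]) / dt,
    "2" = (x[3:(M + 1), , , drop = FALSE] - x[1:(M - 1), , , drop = FALSE]) /
      (2 * dt),
    "4" = (-x[5:(M + 1), , , drop = FALSE] + 8 * x[4:M, , , drop = FALSE] -
             8 * x[2:(M - 2), , , drop = FALSE] + x[1:(M - 3), , , drop = FALSE]) /
      (12 * dt)
  )
  rng <- switch(as.character(order),
                "1" = c(0L, M - 1L), "2" = c(1L, M - 1L), "4" = c(2L, M - 2L))
  new_derivative_estimate(vals, rng[1L], rng[2L], order)
}

new_derivative_estimate <- function(values, m_min, m_max, order) {
  stopifnot(dim(values)[1L] == m_max - m_min + 1L)
  structure(list(values = values, m_min = as.integer(m_min),
                 m_max = as.integer(m_max), order = order),
            class = "derivative_estimate")
}

#' Exact (measured) derivatives of a trajectory
#'
#' Wraps the derivative samples stored in a trajectory simulated with
#' `with_derivatives = TRUE` as a `derivative_estimate` covering the full
#' sample range `m = 0..M`.
#'
#' @param traj a `trajectory` carrying derivative samples.
#' @return A `derivative_estimate` with `order = "exact"`.
#' @export
exact_derivatives <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$derivatives)) {
    stop("trajectory carries no derivative samples; simulate with `with_derivatives = TRUE`",
         call. = FALSE)
  }
  rng <- traj$deriv_range
  new_derivative_estimate(traj$derivatives, rng[1L], rng[2L], "exact")
}

#' @export
print.derivative_estimate <- function(x, ...) {
  cat(sprintf("<derivative_estimate> order %s, samples m = %d..%d\n",
              as.character(x$order), x$m_min, x$m_max))
  invisible(x)
}
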