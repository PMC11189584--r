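#' Assemble the per-node regression problems
#'
#' Turns a sampled trajectory and a derivative estimate into one linear
#' system per node, `Y_i = Phi_i A_i`. For each retained sample index `m`
#' (the derivative estimate's range) and each coupled state component, the
#' response row is `z_i^m - f_i(x_i^m)` and the design row holds
#' `g^(d)(x_i^m, x_j1^m, ...)` for every hyperedge slot of the node's
#' [column_index()] layout. Rows are ordered by time index, then by coupled
#' component; each problem has `Mtilde = (m_max - m_min + 1) * n_g` rows and
#' `H = count_unknowns(N, max_order, convention)` columns.
#'
#' A `candidates` structure restricts the search: only hyperedge slots
#' present in it (per focal node) get a column, so `H` shrinks accordingly
#' (e.g. limiting order-2 interactions to the triangles of a known pairwise
#' backbone).
#'
#' @param traj a `trajectory`.
#' @param deriv a `derivative_estimate` whose index range lies within the
#'   trajectory.
#' @param model a [model_spec()] defining `g^(d)` for `d <= max_order`.
#' @param max_order highest interaction order to reconstruct.
#' @param convention neighbor-tuple convention of the unknowns.
#' @param candidates optional [hyper_structure()] whose entries whitelist
#'   the allowed hyperedge slots.
#' @return List of `node_problem` objects (one per node), each with fields
#'   `node`, `Y`, `Phi`, `column_index`, `n_g`, `m_range`.
#' @export
assemble_problems <- function(traj, deriv, model, max_order,
                              convention = c("unordered", "ordered"),
                              candidates = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(traj, "trajectory"), inherits(deriv, "derivative_estimate"),
            inherits(model, "model_spec"))
  if (max_order > model$max_order) {
    stop("model defines no coupling function of the requested order", call. = FALSE)
  }
  if (deriv$m_min < 0L || deriv$m_max > traj$M || deriv$m_min > deriv$m_max) {
    stop("derivative index range outside the trajectory", call. = FALSE)
  }
  if (!is.null(candidates)) stopifnot(inherits(candidates, "hyper_structure"))
  n_nodes <- dim(traj$states)[2L]
  n <- model$state_dim
  comps <- model$coupled_components
  n_g <- length(comps)
  rows <- (deriv$m_min:deriv$m_max) + 1L          # R rows of the state array
  n_t <- length(rows)
  if (n_t == 0L) stop("empty time range", call. = FALSE)

  # per-node state and derivative slices over the retained samples
  S <- lapply(seq_len(n_nodes), function(i) {
    matrix(traj$states[rows, i, ], nrow = n_t, ncol = n)
  })
  drows <- rows - 1L + 1L - deriv$m_min           # rows within the estimate
  lapply(seq_len(n_nodes), function(i) {
    ci <- column_index(n_nodes, max_order, i, convention)
    if (!is.null(candidates)) {
      allowed <- names(flatten(candidates, i))[flatten(candidates, i) != 0]
      ci <- ci[ci$label %in% allowed, , drop = FALSE]
    }
    H <- nrow(ci)
    z <- matrix(deriv$values[drows, i, ], nrow = n_t, ncol = n)
    f <- model$local(S[[i]], rep(i, n_t))
    ymat <- (z - f)[, comps, drop = FALSE]        # n_t x n_g
    Y <- as.vector(t(ymat))                       # time-major, component-minor
    Phi <- matrix(0, n_t * n_g, H)
    for (col in seq_len(H)) {
      d <- ci$order[col]
      nbs <- lapply(seq_len(d), function(q) S[[ci[[paste0("n", q)]][col]]])
      g <- model$coupling[[d]](S[[i]], nbs)[, comps, drop = FALSE]
      Phi[, col] <- as.vector(t(g))
    }
    if (any(!is.finite(Phi)) || any(!is.finite(Y))) {
      stop(sprintf("non-finite design/response entries for node %d", i),
           call. = FALSE)
    }
    structure(list(node = i, Y = Y, Phi = Phi, column_index = ci,
                   n_g = n_g, m_range = c(deriv$m_min, deriv$m_max)),
              class = "node_problem")
  })
}

#' @export
print.node_problem <- function(x, ...) {
  cat(sprintf("<node_problem> node %d: %d rows x %d unknowns (m = %d..%d, n_g = %d)\n",
              x$node, nrow(x$Phi), ncol(x$Phi), x$m_range[1L], x$m_range[2L],
              x$n_g))
  invisible(x)
}
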