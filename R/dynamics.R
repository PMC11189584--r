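#' Evaluate the coupled right-hand side
#'
#' Computes `f_i(x_i) + sum_d sum_tuples a^(d)_[i; j1..jd]
#' g^(d)(x_i, x_j1, ..., x_jd)` for every node at one state. Under the
#' unordered convention each stored tuple is applied exactly once (the
#' symmetric `j < k` sum of product-form models). The map is linear in the
#' structure's weights, which is precisely what makes the reconstruction
#' problem linear.
#'
#' @param model a [model_spec()].
#' @param structure a [hyper_structure()] with `max_order <= model$max_order`.
#' @param state `N x n` state matrix (a vector is accepted when `n = 1`).
#' @return `N x n` matrix of time derivatives.
#' @examples
#' m <- lv_model(r = 1, k = 1)
#' empty <- hyper_structure(2, 1)
#' # single logistic node at x = 0.5: dx/dt = 0.25
#' evaluate_rhs(lv_model(r = c(1, 1), k = c(1, 1)), empty, c(0.5, 0.5))
#' @export
evaluate_rhs <- function(model, structure, state) {
  rhs <- rhs_function(model, structure)
  rhs(as_state_matrix(state, structure$n_nodes, model$state_dim))
}

as_state_matrix <- function(state, n_nodes, state_dim) {
  if (is.null(dim(state))) {
    if (length(state) != n_nodes * state_dim) {
      stop("state has wrong length", call. = FALSE)
    }
    state <- matrix(state, nrow = n_nodes, ncol = state_dim, byrow = TRUE)
  }
  if (nrow(state) != n_nodes || ncol(state) != state_dim) {
    stop("state has wrong shape", call. = FALSE)
  }
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  state
}

# Precompiled evaluator: gathers per-order index vectors once, then each call
# is a handful of vectorized ops plus a rowsum() accumulation per component.
rhs_function <- function(model, structure) {
  stopifnot(inherits(model, "model_spec"), inherits(structure, "hyper_structure"))
  if (structure$max_order > model$max_order) {
    stop("structure has interactions of higher order than the model defines",
         call. = FALSE)
  }
  n_nodes <- structure$n_nodes
  n <- model$state_dim
  e <- structure$entries
  orders <- sort(unique(e$order))
  blocks <- lapply(orders, function(d) {
    ed <- e[e$order == d, , drop = FALSE]
    list(d = d, focal = ed$node, w = ed$weight,
         nb = lapply(seq_len(d), function(j) ed[[paste0("n", j)]]))
  })
  comps <- seq_len(n)
  function(state) {
    out <- model$local(state, seq_len(n_nodes))
    for (b in blocks) {
      xi <- state[b$focal, , drop = FALSE]
      nbs <- lapply(b$nb, function(idx) state[idx, , drop = FALSE])
      g <- model$coupling[[b$d]](xi, nbs)
      for (comp in comps) {
        v <- b$w * g[, comp]
        if (all(v == 0)) next
        rs <- rowsum(v, b$focal)
        out[as.integer(rownames(rs)), comp] <-
          out[as.integer(rownames(rs)), comp] + rs[, 1L]
      }
    }
    out
  }
}

#' Simulate the coupled system on a uniform sampling grid
#'
#' Integrates the model on a given structure with an adaptive explicit
#' Dormand-Prince Runge-Kutta scheme (`deSolve::ode(method = "ode45")`,
#' default absolute and relative tolerance `1e-12`) and samples the solution
#' at the `M + 1` uniformly spaced times `t_m = m * t_max / M`, `m = 0..M`.
#' With `transient > 0` the system is first evolved for that long from `x0`
#' and the window is restarted at the evolved state (times are reported
#' relative to the window start). With `with_derivatives = TRUE` the exact
#' right-hand side at every sample is stored alongside the states -- the
#' "derivatives are measurable" regime.
#'
#' @inheritParams evaluate_rhs
#' @param x0 `N x n` initial state (vector accepted when `n = 1`).
#' @param t_max length of the sampling window.
#' @param M number of sampling intervals (`M + 1` samples); at least 4.
#' @param with_derivatives store exact derivatives at the samples.
#' @param rtol,atol integration tolerances.
#' @param transient time to evolve and discard before the window.
#' @return An object of class `trajectory`: list with `times` (length
#'   `M + 1`), `states` (`(M+1) x N x n` array), `derivatives` (same shape or
#'   `NULL`), `dt`, `M`, and `meta`.
#' @examples
#' m <- lv_model(r = 1, k = 1)
#' tr <- simulate_trajectory(m, hyper_structure(2, 1), c(0.5, 0.5),
#'                           t_max = 30, M = 10)
#' tr$states[11, , 1]  # both nodes at carrying capacity 1
#' @export
simulate_trajectory <- function(model, structure, x0, t_max, M,
                                with_derivatives = FALSE,
                                rtol = 1e-12, atol = 1e-12, transient = 0) {
  M <- as.integer(M)
  if (M < 4L) stop("`M` must be at least 4", call. = FALSE)
  stop_if_not_scalar_number(t_max, "t_max")
  if (t_max <= 0) stop("`t_max` must be positive", call. = FALSE)
  x0 <- as_state_matrix(x0, structure$n_nodes, model$state_dim)
  times <- seq(0, t_max, length.out = M + 1L)
  states <- integrate_states(model, structure, x0, times, rtol, atol, transient)
  derivs <- NULL
  if (isTRUE(with_derivatives)) {
    rhs <- rhs_function(model, structure)
    derivs <- states
    for (m in seq_len(dim(states)[1L])) {
      derivs[m, , ] <- rhs(matrix(states[m, , ], nrow = structure$n_nodes))
    }
  }
  new_trajectory(times, states, derivs,
                 meta = list(model = model$name, rtol = rtol, atol = atol,
                             transient = transient))
}

new_trajectory <- function(times, states, derivatives = NULL, meta = list(),
                           deriv_range = NULL) {
  dt <- diff(times)
  if (max(abs(dt - dt[1L])) > 1e-12 * max(abs(dt))) {
    stop("sampling grid is not uniform", call. = FALSE)
  }
  structure(list(times = times, states = states, derivatives = derivatives,
                 deriv_range = deriv_range %||%
                   (if (is.null(derivatives)) NULL else c(0L, length(times) - 1L)),
                 dt = dt[1L], M = length(times) - 1L, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("<trajectory> %s: N = %d nodes, n = %d, M = %d (dt = %.6g)%s\n",
              x$meta$model %||% "?", d[2L], d[3L], x$M, x$dt,
              if (is.null(x$derivatives)) "" else ", with derivatives"))
  invisible(x)
}

# capacity of the static parameter buffer in src/compiled_rhs.c
PARMS_CAP <- 25000L

# Pack model + structure into the flat parameter vector the compiled
# right-hand sides expect (zero-padded to the fixed buffer length), or NULL
# when the combination has no compiled form.
pack_compiled_parms <- function(model, structure) {
  if (is.null(model$compiled)) return(NULL)
  e <- structure$entries
  if (any(e$order > 2L)) return(NULL)
  e1 <- e[e$order == 1L, , drop = FALSE]
  e2 <- e[e$order == 2L, , drop = FALSE]
  head <- if (identical(model$compiled, "lv")) {
    if (length(model$params$r) != structure$n_nodes) return(NULL)
    c(structure$n_nodes, model$params$r, model$params$k)
  } else if (identical(model$compiled, "rossler")) {
    with(model$params, c(structure$n_nodes, a, b, c, sigma1, sigma2))
  } else {
    return(NULL)
  }
  p <- c(head,
         nrow(e1), as.vector(t(cbind(e1$node, e1$n1, e1$weight))),
         nrow(e2), as.vector(t(cbind(e2$node, e2$n1, e2$n2, e2$weight))))
  if (length(p) > PARMS_CAP) return(NULL)
  c(p, numeric(PARMS_CAP - length(p)))
}

# Integrate and return states sampled at `times` (shifted past a transient).
# Shared by simulate_trajectory() and the sweep machinery, which requests a
# union of several uniform grids from a single integration. Built-in models
# integrate through the compiled right-hand side; anything else falls back
# to the interpreted evaluator (the two agree to round-off; see tests).
integrate_states <- function(model, structure, x0, times, rtol, atol,
                             transient = 0) {
  n_nodes <- structure$n_nodes
  n <- model$state_dim
  parms <- pack_compiled_parms(model, structure)
  if (!is.null(parms)) {
    run <- function(y0, times) {
      deSolve::ode(y = y0, times = times,
                   func = paste0("hordyn_", model$compiled, "_derivs"),
                   parms = parms, dllname = "hordyn",
                   initfunc = paste0("hordyn_", model$compiled, "_init"),
                   method = "ode45", rtol = rtol, atol = atol,
                   maxsteps = 1e6)
    }
  } else {
    rhs <- rhs_function(model, structure)
    dfun <- function(t, y, parms) {
      list(as.vector(t(rhs(matrix(y, nrow = n_nodes, byrow = TRUE)))))
    }
    run <- function(y0, times) {
      deSolve::ode(y = y0, times = times, func = dfun, parms = NULL,
                   method = "ode45", rtol = rtol, atol = atol,
                   maxsteps = 1e6)
    }
  }
  y0 <- as.vector(t(x0))
  if (transient > 0) {
    # a moderately dense output grid keeps the rk stepper well-behaved
    pre_times <- seq(0, transient, length.out = 65L)
    pre <- run(y0, pre_times)
    check_integration(pre, pre_times)
    y0 <- as.numeric(pre[nrow(pre), -1L])
  }
  sol <- run(y0, times)
  check_integration(sol, times)
  arr <- array(NA_real_, dim = c(length(times), n_nodes, n))
  for (m in seq_along(times)) {
    arr[m, , ] <- matrix(as.numeric(sol[m, -1L]), nrow = n_nodes, byrow = TRUE)
  }
  arr
}

check_integration <- function(sol, times) {
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    bad <- if (nrow(sol) < length(times)) times[nrow(sol) + 1L] else
      sol[which(!is.finite(sol), arr.ind = TRUE)[1L, 1L], 1L]
    stop(sprintf("integration failed near t = %.6g (blow-up or step-size collapse)",
                 bad), call. = FALSE)
  }
  invisible(sol)
}

#' Read and write sampled trajectories as delimited text
#'
#' One row per time sample: a `time` column followed by node-major state
#' columns `x<node>_<component>`. Floats are written with 17 significant
#' digits so the round trip is exact to double precision. Derivative samples,
#' if present, go to a parallel file `<path>.deriv` in the same layout.
#'
#' @param traj a `trajectory`.
#' @param path file path for the state table.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$states)
  tab <- traj_table(traj$times, traj$states)
  meta <- sprintf("# hordyn trajectory v1\tmodel=%s\tn_nodes=%d\tstate_dim=%d\tM=%d",
                  traj$meta$model %||% "unknown", d[2L], d[3L], traj$M)
  write_float_table(tab, path, meta)
  if (!is.null(traj$derivatives)) {
    rng <- traj$deriv_range
    rows <- (rng[1L]:rng[2L]) + 1L
    dtab <- traj_table(traj$times[rows],
                       traj$derivatives[seq_along(rows), , , drop = FALSE])
    dmeta <- sprintf("# hordyn trajectory derivatives v1\tm_min=%d\tm_max=%d",
                     rng[1L], rng[2L])
    write_float_table(dtab, paste0(path, ".deriv"), dmeta)
  }
  invisible(path)
}

traj_table <- function(times, states) {
  d <- dim(states)
  cols <- list(time = times)
  for (i in seq_len(d[2L])) {
    for (comp in seq_len(d[3L])) {
      cols[[sprintf("x%d_%d", i, comp)]] <- states[, i, comp]
    }
  }
  as.data.frame(cols)
}

write_float_table <- function(tab, path, meta_line) {
  fmt <- vapply(tab, function(col) format(col, digits = 17, trim = TRUE),
                character(nrow(tab)))
  if (nrow(tab) == 1L) fmt <- matrix(fmt, nrow = 1L)
  lines <- c(meta_line, paste(names(tab), collapse = "\t"),
             apply(fmt, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# hordyn trajectory")) {
    stop("not a hordyn trajectory file", call. = FALSE)
  }
  kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  n_nodes <- as.integer(meta[["n_nodes"]])
  n <- as.integer(meta[["state_dim"]])
  states <- array(NA_real_, dim = c(nrow(tab), n_nodes, n))
  for (i in seq_len(n_nodes)) {
    for (comp in seq_len(n)) {
      states[, i, comp] <- tab[[sprintf("x%d_%d", i, comp)]]
    }
  }
  derivatives <- NULL
  deriv_range <- NULL
  dpath <- paste0(path, ".deriv")
  if (file.exists(dpath)) {
    dfirst <- readLines(dpath, n = 1L)
    dkv <- strsplit(strsplit(dfirst, "\t")[[1]][-1], "=")
    dmeta <- stats::setNames(vapply(dkv, `[`, "", 2), vapply(dkv, `[`, "", 1))
    dtab <- utils::read.table(dpath, header = TRUE, sep = "\t", skip = 1L)
    derivatives <- array(NA_real_, dim = c(nrow(dtab), n_nodes, n))
    for (i in seq_len(n_nodes)) {
      for (comp in seq_len(n)) {
        derivatives[, i, comp] <- dtab[[sprintf("x%d_%d", i, comp)]]
      }
    }
    deriv_range <- c(as.integer(dmeta[["m_min"]]), as.integer(dmeta[["m_max"]]))
  }
  new_trajectory(tab$time, states, derivatives,
                 meta = list(model = meta[["model"]]),
                 deriv_range = deriv_range)
}
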