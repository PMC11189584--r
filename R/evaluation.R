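#' Discrepancy of a reconstruction
#'
#' The per-node squared residuals `E_i = ||Y_i - Phi_i A_i||_2^2` and their
#' sum `E` over nodes: the objective the per-node least-squares solves
#' minimize.
#'
#' @param problems list of `node_problem`s.
#' @param estimates list of `coefficient_vector`s (or plain numeric vectors)
#'   parallel to `problems`.
#' @return List with `E` (total) and `E_i` (per node).
#' @export
discrepancy <- function(problems, estimates) {
  if (length(problems) != length(estimates)) {
    stop("`problems` and `estimates` lengths differ", call. = FALSE)
  }
  E_i <- vapply(seq_along(problems), function(i) {
    p <- problems[[i]]
    v <- estimates[[i]]
    if (inherits(v, "coefficient_vector")) v <- v$values
    if (length(v) != ncol(p$Phi)) {
      stop(sprintf("estimate %d has length %d, expected %d",
                   i, length(v), ncol(p$Phi)), call. = FALSE)
    }
    sum((p$Y - p$Phi %*% v)^2)
  }, numeric(1))
  list(E = sum(E_i), E_i = E_i)
}

#' Relative reconstruction error against a known structure
#'
#' Compares estimated coefficient vectors with the generating ones:
#' `error^2 = sum_i ||A_i - Ahat_i||^2 / sum_i ||A_i||^2`, pooling all nodes
#' and all interaction orders. The measure is scale-aware (invariant under a
#' common rescaling of truth and estimate) and equals 0 for perfect
#' recovery, 1 for an all-zero estimate.
#'
#' @param truth the generating [hyper_structure()] (must be non-empty).
#' @param estimate a `hyperfit`, or an `H x N` coefficient matrix in the
#'   truth's layout.
#' @return The reconstruction error (non-negative scalar).
#' @export
reconstruction_error <- function(truth, estimate) {
  stopifnot(inherits(truth, "hyper_structure"))
  n <- truth$n_nodes
  cf <- if (inherits(estimate, "hyperfit")) {
    if (estimate$n_nodes != n || estimate$max_order != truth$max_order ||
        estimate$convention != truth$convention) {
      stop("fit and truth have different column layouts", call. = FALSE)
    }
    estimate$coefficients
  } else {
    as.matrix(estimate)
  }
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    a <- flatten(truth, i)
    if (length(a) != nrow(cf)) {
      stop("estimate rows do not match the truth's column layout", call. = FALSE)
    }
    num <- num + sum((a - cf[, i])^2)
    den <- den + sum(a^2)
  }
  if (den == 0) {
    stop("empty truth: reconstruction error is undefined (zero denominator)",
         call. = FALSE)
  }
  sqrt(num / den)
}

#' Reconstruction-error sweep over the sampling budget
#'
#' Measures the reconstruction error as a function of the ratio `M / H`
#' between the trajectory length and the number of unknowns per node, the
#' sampling budget normalized by problem size. For each grid ratio the
#' sample count is `M = ceiling(ratio * H)`; within a replicate all ratios
#' are served by a single high-accuracy integration evaluated on the union
#' of the uniform grids, so refining `M` refines the sampling interval
#' `dt = t_max / M` at a fixed window. Replicates redraw the stochastic
#' fixture elements (structure and/or initial state, via the function
#' arguments) and the curve reports the median error with the interquartile
#' range.
#'
#' @param model a [model_spec()].
#' @param structure a [hyper_structure()], or a `function(seed)` returning
#'   one (redrawn per replicate).
#' @param x0 initial state, or a `function(seed)` returning one.
#' @param ratios strictly increasing positive grid of `M / H` values.
#' @param solver,deriv_order solver name and derivative mode (`"exact"`,
#'   1, 2 or 4) as in [reconstruct()].
#' @param replicates number of replicate draws.
#' @param seed base RNG seed; replicate `r` uses `seed + r - 1`.
#' @param t_max,transient sampling window and discarded lead-in time.
#' @param convention neighbor-tuple convention of the unknowns.
#' @param candidates optional whitelist, as in [reconstruct()].
#' @param rtol,atol integration tolerances.
#' @param ... further solver options for [reconstruct()].
#' @return An object of class `error_curve`: data frame with columns
#'   `ratio`, `M`, `error` (median), `q25`, `q75`, with the full replicate
#'   error matrix in `attr(, "replicate_errors")` and the configuration in
#'   `attr(, "config")`.
#' @export
sweep_ratio <- function(model, structure, x0, ratios,
                        solver = "ols", deriv_order = "exact",
                        replicates = 1L, seed = NULL,
                        t_max, transient = 0,
                        convention = c("unordered", "ordered"),
                        candidates = NULL, rtol = 1e-12, atol = 1e-12, ...) {
  convention <- match.arg(convention)
  ratios <- as.numeric(ratios)
  if (any(ratios <= 0) || any(diff(ratios) <= 0)) {
    stop("`ratios` must be positive and strictly increasing", call. = FALSE)
  }
  structure_fn <- if (is.function(structure)) structure else function(s) structure
  x0_fn <- if (is.function(x0)) x0 else function(s) x0
  errs <- matrix(NA_real_, length(ratios), replicates)
  Ms <- NULL
  for (rep in seq_len(replicates)) {
    rep_seed <- if (is.null(seed)) NULL else seed + rep - 1L
    hs <- structure_fn(rep_seed)
    x0r <- x0_fn(rep_seed)
    H <- count_unknowns(hs$n_nodes, hs$max_order, convention)
    Ms <- pmax(4L, as.integer(ceiling(ratios * H)))
    trajs <- simulate_grid_family(model, hs, x0r, t_max, Ms,
                                  with_derivatives = identical(deriv_order, "exact"),
                                  rtol = rtol, atol = atol,
                                  transient = transient)
    for (g in seq_along(ratios)) {
      fit <- reconstruct(trajs[[g]], model, max_order = hs$max_order,
                         solver = solver, deriv = deriv_order,
                         convention = convention, candidates = candidates, ...)
      errs[g, rep] <- reconstruction_error(hs, fit)
    }
  }
  out <- data.frame(
    ratio = ratios,
    M = Ms,
    error = apply(errs, 1L, stats::median),
    q25 = apply(errs, 1L, stats::quantile, probs = 0.25),
    q75 = apply(errs, 1L, stats::quantile, probs = 0.75)
  )
  attr(out, "replicate_errors") <- errs
  attr(out, "config") <- list(model = model$name, solver = solver,
                              deriv_order = deriv_order,
                              replicates = replicates, seed = seed,
                              t_max = t_max, transient = transient,
                              convention = convention)
  class(out) <- c("error_curve", "data.frame")
  out
}

# One integration serving several uniform grids on the same window: sample
# times are reduced fractions m/M of t_max, so shared points are computed
# bit-identically and the union grid can be matched exactly.
simulate_grid_family <- function(model, structure, x0, t_max, Ms,
                                 with_derivatives = TRUE,
                                 rtol = 1e-12, atol = 1e-12, transient = 0) {
  x0 <- as_state_matrix(x0, structure$n_nodes, model$state_dim)
  gcd <- function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }
  frac_time <- function(m, M) {
    g <- vapply(m, gcd, numeric(1), b = M)
    g[m == 0] <- M
    (t_max * (m / g)) / (M / g)
  }
  grids <- lapply(Ms, function(M) frac_time(0:M, M))
  union_times <- sort(unique(unlist(grids)))
  states <- integrate_states(model, structure, x0, union_times, rtol, atol,
                             transient)
  derivs <- NULL
  if (with_derivatives) {
    rhs <- rhs_function(model, structure)
    derivs <- states
    for (m in seq_along(union_times)) {
      derivs[m, , ] <- rhs(matrix(states[m, , ], nrow = structure$n_nodes))
    }
  }
  lapply(seq_along(Ms), function(g) {
    pos <- match(grids[[g]], union_times)
    stopifnot(!anyNA(pos))
    new_trajectory(
      times = seq(0, t_max, length.out = Ms[g] + 1L),
      states = states[pos, , , drop = FALSE],
      derivatives = if (with_derivatives) derivs[pos, , , drop = FALSE],
      meta = list(model = model$name, rtol = rtol, atol = atol,
                  transient = transient))
  })
}

#' Smallest sampling ratio achieving near-exact recovery
#'
#' The "drop point" of an error curve: the smallest grid ratio whose
#' (median) error falls below `threshold`.
#'
#' @param curve an `error_curve`.
#' @param threshold recovery threshold on the error (default `1e-6`).
#' @return The ratio, or `NA` if no grid point qualifies.
#' @export
drop_point <- function(curve, threshold = 1e-6) {
  stopifnot(inherits(curve, "error_curve"))
  hit <- which(curve$error < threshold)
  if (!length(hit)) return(NA_real_)
  curve$ratio[min(hit)]
}

#' Log-log slope of an error curve
#'
#' Ordinary least-squares slope of `log(error)` versus `log(M/H)` over a
#' ratio range, estimating the power-law exponent of the error decay.
#' Points at or below `floor` (exact-recovery plateau, floored at `1e-16`
#' for plotting) are excluded and reported.
#'
#' @param curve an `error_curve`.
#' @param range optional `c(lo, hi)` ratio range to fit over.
#' @param floor exclusion floor for (near-)zero errors.
#' @return The fitted exponent, with the excluded ratios in
#'   `attr(, "excluded")` and the intercept in `attr(, "intercept")`.
#' @export
fit_loglog_slope <- function(curve, range = NULL, floor = 1e-16) {
  stopifnot(inherits(curve, "error_curve"))
  keep <- curve$error > floor
  if (!is.null(range)) {
    keep <- keep & curve$ratio >= range[1L] & curve$ratio <= range[2L]
  }
  excluded <- curve$ratio[!keep & (is.null(range) |
                                     (curve$ratio >= (range[1L] %||% -Inf) &
                                        curve$ratio <= (range[2L] %||% Inf)))]
  if (sum(keep) < 3L) {
    stop("need at least 3 positive-error points in range to fit a slope",
         call. = FALSE)
  }
  fit <- stats::lm(log(error) ~ log(ratio), data = curve[keep, ])
  out <- unname(stats::coef(fit)[2L])
  attr(out, "intercept") <- unname(stats::coef(fit)[1L])
  attr(out, "excluded") <- excluded
  out
}

#' @export
plot.error_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  err <- pmax(x$error, 1e-16)
  if (add) {
    graphics::lines(x$ratio, err, type = "b", pch = 16, col = col, ...)
  } else {
    graphics::plot(x$ratio, err, log = "xy", type = "b", pch = 16, col = col,
                   xlab = "M / H", ylab = "reconstruction error", ...)
  }
  invisible(x)
}

#' Write an error curve as CSV
#'
#' Columns `ratio`, `M`, `error`, `q25`, `q75`, followed by one column per
#' replicate error.
#'
#' @param curve an `error_curve`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_error_curve <- function(curve, path) {
  stopifnot(inherits(curve, "error_curve"))
  tab <- as.data.frame(curve)
  reps <- attr(curve, "replicate_errors")
  if (!is.null(reps)) {
    colnames(reps) <- paste0("rep", seq_len(ncol(reps)))
    tab <- cbind(tab, reps)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
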