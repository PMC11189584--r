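#' Reconstruct pairwise and higher-order interactions from a trajectory
#'
#' The package's fitting function. Given a sampled trajectory and the model
#' of the local dynamics and coupling functions, it assembles one linear
#' system per node (see [assemble_problems()]) and solves each independently
#' -- the directed treatment, in which every node's discrepancy
#' `E_i = ||Y_i - Phi_i A_i||^2` is minimized on its own -- with the chosen
#' solver: minimal-norm ordinary least squares, non-negative least squares,
#' or the Signal Lasso.
#'
#' @param traj a `trajectory` from [simulate_trajectory()] or
#'   [read_trajectory()].
#' @param model the [model_spec()] of the (known) local dynamics and
#'   couplings.
#' @param max_order highest interaction order to reconstruct (default: all
#'   orders the model defines).
#' @param solver `"ols"`, `"nnls"` or `"signal_lasso"`.
#' @param deriv `"exact"` to use measured derivative samples, a
#'   finite-difference order (1, 2 or 4), or a ready-made
#'   `derivative_estimate`.
#' @param convention neighbor-tuple convention of the unknowns.
#' @param candidates optional [hyper_structure()] whitelisting hyperedge
#'   slots (shrinks the search space).
#' @param ... solver options passed on to [solve_ols()], [solve_nnls()] or
#'   [solve_signal_lasso()] (`rank_tol`, `alpha`, `beta`, `max_iter`, `tol`).
#' @return An object of class `hyperfit` with methods `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict`, `simulate` and `plot`.
#'   `coef()` returns the full `H x N` coefficient matrix (rows in
#'   [column_index()] order, zeros outside any candidate whitelist);
#'   `$discrepancy` holds the per-node `E_i` and their sum.
#' @examples
#' hs <- build_lv_hypergraph(seed = 1)
#' m <- lv_model()
#' tr <- simulate_trajectory(m, hs, lv_parameters()$x0, t_max = 20, M = 200,
#'                           with_derivatives = TRUE)
#' fit <- reconstruct(tr, m, solver = "ols")
#' coef_entry(fit, 2, c(3, 7))  # recovers 0.0062
#' @export
reconstruct <- function(traj, model, max_order = model$max_order,
                        solver = c("ols", "nnls", "signal_lasso"),
                        deriv = "exact",
                        convention = c("unordered", "ordered"),
                        candidates = NULL, ...) {
  solver <- match.arg(solver)
  convention <- match.arg(convention)
  est <- resolve_derivatives(traj, deriv)
  problems <- assemble_problems(traj, est, model, max_order, convention,
                                candidates)
  fit_problems(problems, model, traj, est, solver, convention, max_order, ...)
}

resolve_derivatives <- function(traj, deriv) {
  if (inherits(deriv, "derivative_estimate")) return(deriv)
  if (identical(deriv, "exact")) return(exact_derivatives(traj))
  if (is.numeric(deriv) && length(deriv) == 1L) {
    return(finite_difference(traj, deriv))
  }
  stop("`deriv` must be \"exact\", a stencil order (1, 2, 4), or a derivative_estimate",
       call. = FALSE)
}

fit_problems <- function(problems, model, traj, est, solver, convention,
                         max_order, ...) {
  dots <- list(...)
  solve_one <- switch(solver,
    ols = function(p) solve_ols(p, rank_tol = dots$rank_tol),
    nnls = function(p) solve_nnls(p),
    signal_lasso = function(p) {
      do.call(solve_signal_lasso,
              c(list(p), dots[intersect(names(dots),
                                        c("alpha", "beta", "max_iter", "tol"))]))
    })
  estimates <- lapply(problems, solve_one)
  n_nodes <- length(problems)
  full_ci <- column_index(n_nodes, max_order, 1L, convention)
  H_full <- nrow(full_ci)
  coefs <- matrix(0, H_full, n_nodes,
                  dimnames = list(NULL, paste0("node", seq_len(n_nodes))))
  resid <- vector("list", n_nodes)
  fitted <- vector("list", n_nodes)
  E_i <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    ci <- problems[[i]]$column_index
    pos <- match(ci$label, column_index(n_nodes, max_order, i, convention)$label)
    coefs[pos, i] <- estimates[[i]]$values
    fitted[[i]] <- drop(problems[[i]]$Phi %*% estimates[[i]]$values)
    resid[[i]] <- problems[[i]]$Y - fitted[[i]]
    E_i[i] <- sum(resid[[i]]^2)
  }
  rownames(coefs) <- paste0("slot", seq_len(H_full))
  structure(list(
    coefficients = coefs,
    estimates = estimates,
    residuals = resid,
    fitted = fitted,
    discrepancy = list(E = sum(E_i), E_i = E_i),
    solver = solver,
    convention = convention,
    max_order = max_order,
    model = model,
    n_nodes = n_nodes,
    n_g = problems[[1L]]$n_g,
    m_range = problems[[1L]]$m_range,
    M = traj$M,
    dt = traj$dt,
    deriv_order = if (inherits(est, "derivative_estimate")) est$order else est,
    H = H_full,
    restricted = any(vapply(problems, function(p) nrow(p$column_index), 0L) <
                       H_full)
  ), class = "hyperfit")
}

# row labels of the coefficient matrix follow the focal node's own layout;
# give the generic (node-independent) slot description instead
coef_slot_labels <- function(fit, node) {
  column_index(fit$n_nodes, fit$max_order, node, fit$convention)$label
}

#' @export
print.hyperfit <- function(x, ...) {
  cat(sprintf("<hyperfit> %s reconstruction of %d nodes (model %s)\n",
              x$solver, x$n_nodes, x$model$name))
  cat(sprintf("  H = %d unknowns/node, %s tuples, M = %d samples, derivatives: %s\n",
              x$H, x$convention, x$M, as.character(x$deriv_order)))
  cat(sprintf("  total discrepancy E = %.4g\n", x$discrepancy$E))
  invisible(x)
}

#' @export
summary.hyperfit <- function(object, ...) {
  cf <- coef(object)
  out <- list(
    solver = object$solver,
    n_nodes = object$n_nodes,
    H = object$H,
    M = object$M,
    deriv_order = object$deriv_order,
    E = object$discrepancy$E,
    E_i = object$discrepancy$E_i,
    coef_range = range(cf),
    n_above_half = sum(cf >= 0.5)
  )
  class(out) <- "summary.hyperfit"
  out
}

#' @export
print.summary.hyperfit <- function(x, ...) {
  cat(sprintf("Reconstruction by %s: %d nodes, H = %d unknowns per node\n",
              x$solver, x$n_nodes, x$H))
  cat(sprintf("M = %d samples, derivatives: %s\n", x$M,
              as.character(x$deriv_order)))
  cat(sprintf("Discrepancy E = %.6g (per-node median %.3g)\n",
              x$E, stats::median(x$E_i)))
  cat(sprintf("Coefficients in [%.4g, %.4g]; %d at or above 0.5\n",
              x$coef_range[1L], x$coef_range[2L], x$n_above_half))
  invisible(x)
}

#' @export
coef.hyperfit <- function(object, ...) {
  cf <- object$coefficients
  dimnames(cf) <- list(NULL, paste0("node", seq_len(object$n_nodes)))
  # row labels are node-relative (each column follows its own node's layout);
  # the full per-node label matrix travels in the "labels" attribute
  labs <- vapply(seq_len(object$n_nodes), function(i) coef_slot_labels(object, i),
                 character(object$H))
  attr(cf, "labels") <- labs
  rownames(cf) <- labs[, 1L]
  cf
}

#' Coefficient of one hyperedge slot of one node
#'
#' Convenience accessor: reads the estimated coefficient of focal node
#' `node` for neighbors `neighbors` at order `length(neighbors)`.
#'
#' @param fit a `hyperfit`.
#' @param node focal node index.
#' @param neighbors neighbor indices of the hyperedge.
#' @return The estimated coefficient (a single number).
#' @export
coef_entry <- function(fit, node, neighbors) {
  stopifnot(inherits(fit, "hyperfit"))
  d <- length(neighbors)
  if (fit$convention == "unordered") neighbors <- sort(neighbors)
  lab <- paste0("d", d, ":", paste(neighbors, collapse = ","))
  labs <- coef_slot_labels(fit, node)
  pos <- match(lab, labs)
  if (is.na(pos)) stop(sprintf("no slot %s for node %d", lab, node), call. = FALSE)
  unname(fit$coefficients[pos, node])
}

#' @export
residuals.hyperfit <- function(object, ...) {
  do.call(cbind, object$residuals)
}

#' @export
fitted.hyperfit <- function(object, ...) {
  do.call(cbind, object$fitted)
}

#' @export
#' @rdname reconstruct
#' @param object,x a `hyperfit`.
#' @param state state matrix at which to evaluate the reconstructed
#'   right-hand side (for `predict`).
predict.hyperfit <- function(object, state, ...) {
  evaluate_rhs(object$model, as_structure(object), state)
}

#' @export
#' @rdname reconstruct
#' @param nsim,seed standard [stats::simulate()] arguments (one trajectory
#'   per `nsim`).
#' @param x0 initial state for simulation.
#' @param t_max,M sampling window and interval count for simulation.
simulate.hyperfit <- function(object, nsim = 1, seed = NULL, x0, t_max, M, ...) {
  with_seed(seed, {
    out <- lapply(seq_len(nsim), function(s) {
      simulate_trajectory(object$model, as_structure(object), x0, t_max, M, ...)
    })
    if (nsim == 1L) out[[1L]] else out
  })
}

#' @export
#' @rdname reconstruct
#' @param threshold optional highlighting threshold for the coefficient dot
#'   plot (for `plot`).
plot.hyperfit <- function(x, threshold = 0.5, ...) {
  cf <- as.vector(x$coefficients)
  graphics::plot(seq_along(cf), cf, pch = 16, cex = 0.4,
                 col = ifelse(cf >= threshold, "firebrick", "steelblue"),
                 xlab = "coefficient slot (all nodes)",
                 ylab = "estimated coefficient",
                 main = sprintf("%s estimates (M/H = %.2f)",
                                x$solver, x$M / x$H), ...)
  graphics::abline(h = c(0, 1), lty = 3, col = "grey50")
  invisible(x)
}

#' Reconstructed structure from a fit
#'
#' Turns the coefficient matrix of a `hyperfit` into a [hyper_structure()].
#' With `binarize` set, coefficients at or above the threshold become weight
#' 1 and the rest are dropped -- support recovery for unweighted structures
#' (the 0.5 midpoint of \{0, 1\} is the conventional choice). Otherwise
#' exact zeros are dropped and all remaining weights kept.
#'
#' @param fit a `hyperfit`.
#' @param binarize optional support-recovery threshold.
#' @return A directed [hyper_structure()].
#' @export
as_structure <- function(fit, binarize = NULL) {
  stopifnot(inherits(fit, "hyperfit"))
  entries <- NULL
  for (i in seq_len(fit$n_nodes)) {
    v <- fit$coefficients[, i]
    if (!is.null(binarize)) v <- as.numeric(v >= binarize)
    ent <- unflatten(v, i, fit$n_nodes, fit$max_order, fit$convention)
    entries <- rbind(entries, ent)
  }
  hyper_structure(fit$n_nodes, fit$max_order, entries,
                  convention = fit$convention, directed = TRUE)
}

#' Symmetrize a directed reconstruction
#'
#' Per-node (directed) estimation of an undirected ground truth yields one
#' independent coefficient per focal-node rotation of each hyperedge; when
#' the data determine the problem these agree almost exactly. `symmetrize()`
#' averages the rotations of every hyperedge into a single undirected weight
#' and reports the largest within-hyperedge spread (max minus min) as an
#' asymmetry diagnostic.
#'
#' @param fit a `hyperfit` (or a directed [hyper_structure()]).
#' @param drop_tol hyperedges whose averaged weight has absolute value at or
#'   below this are dropped (default 0: drop only exact zeros).
#' @return An undirected [hyper_structure()]; the asymmetry diagnostic is in
#'   `attr(, "asymmetry")`.
#' @export
symmetrize <- function(fit, drop_tol = 0) {
  hs <- if (inherits(fit, "hyperfit")) as_structure(fit) else fit
  stopifnot(inherits(hs, "hyper_structure"))
  n <- hs$n_nodes
  ncols <- neighbor_cols(hs$max_order)
  e <- hs$entries
  key <- vapply(seq_len(nrow(e)), function(r) {
    d <- e$order[r]
    members <- sort(c(e$node[r], as.integer(e[r, ncols[seq_len(d)]])))
    paste0(d, ":", paste(members, collapse = ","))
  }, character(1))
  groups <- split(seq_len(nrow(e)), key)
  rows <- list()
  asym <- 0
  for (g in groups) {
    d <- e$order[g[1L]]
    members <- sort(unique(c(e$node[g[1L]],
                             as.integer(e[g[1L], ncols[seq_len(d)]]))))
    # rotations absent from the entry table count as zeros
    w_all <- c(e$weight[g], rep(0, (d + 1L) - length(g)))
    w <- mean(w_all)
    asym <- max(asym, max(w_all) - min(w_all))
    if (abs(w) <= drop_tol) next
    for (focal in members) {
      nb <- setdiff(members, focal)
      row <- c(list(order = d, node = focal),
               stats::setNames(as.list(c(nb, rep(NA_integer_,
                                                 hs$max_order - d))), ncols),
               list(weight = w))
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else NULL
  out <- hyper_structure(n, hs$max_order, entries, convention = hs$convention,
                         directed = FALSE)
  attr(out, "asymmetry") <- asym
  out
}

#' Serialize a reconstruction result
#'
#' Writes the reconstructed structure as a hyperedge-list TSV (see
#' [write_hyperedge_tsv()]) plus a JSON sidecar `<path>.json` with solver
#' metadata and the per-node discrepancies.
#'
#' @param fit a `hyperfit`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(fit, path) {
  stopifnot(inherits(fit, "hyperfit"))
  write_hyperedge_tsv(as_structure(fit), path)
  meta <- list(schema = "hordyn/reconstruction/v1",
               solver = fit$solver,
               model = fit$model$name,
               convention = fit$convention,
               max_order = fit$max_order,
               M = fit$M, H = fit$H, n_g = fit$n_g,
               m_range = fit$m_range,
               deriv_order = as.character(fit$deriv_order),
               E = fit$discrepancy$E,
               E_i = fit$discrepancy$E_i,
               solver_meta = lapply(fit$estimates, `[[`, "meta"))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}
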