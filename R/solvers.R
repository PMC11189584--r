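new_coefficient_vector <- function(node, values, labels, meta = list()) {
  structure(list(node = node,
                 values = stats::setNames(as.numeric(values), labels),
                 meta = meta),
            class = "coefficient_vector")
}

#' @export
print.coefficient_vector <- function(x, ...) {
  nz <- sum(x$values != 0)
  cat(sprintf("<coefficient_vector> node %d: %d coefficients (%d non-zero)\n",
              x$node, length(x$values), nz))
  invisible(x)
}

# Orthogonal reduction of a tall least-squares problem: ||A x - b|| equals
# ||R x_piv - Q'b|| up to a constant, with x_piv a column permutation of x.
# Permutations preserve both the l2 norm and non-negativity, so minimal-norm
# and NNLS solves can run on the reduced square system.
qr_reduce <- function(A, b) {
  if (nrow(A) <= ncol(A)) {
    return(list(A = A, b = b, pivot = seq_len(ncol(A))))
  }
  qf <- qr(A, LAPACK = TRUE)
  H <- ncol(A)
  list(A = qr.R(qf)[seq_len(H), , drop = FALSE],
       b = qr.qty(qf, b)[seq_len(H)],
       pivot = qf$pivot)
}

unpivot <- function(x, pivot) {
  out <- numeric(length(x))
  out[pivot] <- x
  out
}

# minimal l2-norm least squares via SVD with a rank tolerance
min_norm_ls <- function(A, b, rank_tol = NULL) {
  if (ncol(A) == 0L) {
    return(list(x = numeric(0), rank = 0L, smax = 0, smin = 0, tol = 0))
  }
  sv <- svd(A)
  smax <- if (length(sv$d)) sv$d[1L] else 0
  tol <- rank_tol %||% (max(dim(A)) * .Machine$double.eps * smax)
  keep <- sv$d > tol
  r <- sum(keep)
  x <- if (r == 0L) numeric(ncol(A)) else {
    drop(sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep]))
  }
  list(x = x, rank = r, smax = smax, smin = min(sv$d), tol = tol)
}

#' Minimal-norm ordinary least squares for a node problem
#'
#' Returns a minimizer of `||Y_i - Phi_i A_i||_2`; when the minimizer is not
#' unique (rank-deficient or underdetermined design), the one of minimal
#' `l2` norm, computed through an orthogonal decomposition and an SVD with
#' rank tolerance `max(dim) * eps * sigma_max` (singular values below it are
#' treated as zero). Tall problems are first reduced by a QR factorization.
#'
#' @param problem a `node_problem` from [assemble_problems()].
#' @param rank_tol optional explicit rank tolerance.
#' @return A `coefficient_vector` with rank/conditioning diagnostics in
#'   `$meta`.
#' @export
solve_ols <- function(problem, rank_tol = NULL) {
  stopifnot(inherits(problem, "node_problem"))
  red <- qr_reduce(problem$Phi, problem$Y)
  fit <- min_norm_ls(red$A, red$b, rank_tol)
  x <- unpivot(fit$x, red$pivot)
  new_coefficient_vector(problem$node, x, problem$column_index$label,
                         meta = list(solver = "ols", rank = fit$rank,
                                     sigma_max = fit$smax, sigma_min = fit$smin,
                                     rank_tol = fit$tol))
}

# Lawson-Hanson active-set NNLS on the normal equations (the "fast NNLS"
# variant of Bro & de Jong): iterates on the Gram matrix G = Phi'Phi and
# c = Phi'Y, so each passive-set solve is small and the row count enters
# only through the one-time crossprod. Returns x >= 0 and iteration count.
nnls_activeset <- function(G, c, max_iter = NULL) {
  H <- length(c)
  max_iter <- max_iter %||% (30L * H)
  x <- numeric(H)
  passive <- logical(H)
  w <- c
  scale <- max(abs(c), 1e-300)
  iter <- 0L
  converged <- TRUE
  while (TRUE) {
    cand <- which(!passive & w > 1e-12 * scale)
    if (!length(cand)) break
    iter <- iter + 1L
    if (iter > max_iter) { converged <- FALSE; break }
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(H)
      Gp <- G[passive, passive, drop = FALSE]
      s[passive] <- tryCatch(solve(Gp, c[passive]),
                             error = function(e) {
                               qr.coef(qr(Gp), c[passive])
                             })
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > 0)) { x <- s; break }
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= 1e-14 * max(x, 1e-300)] <- FALSE
      x[!passive] <- 0
    }
    w <- c - drop(G %*% x)
  }
  list(x = x, iterations = iter, converged = converged)
}

#' Non-negative least squares for a node problem
#'
#' Minimizes `||Y_i - Phi_i A_i||_2` subject to `A_i >= 0` with the
#' Lawson-Hanson active-set algorithm, run on the normal equations
#' (`G = Phi'Phi`, `c = Phi'Y`) so that the cost of each active-set
#' iteration is independent of the number of time samples. The maximum
#' violation of the Karush-Kuhn-Tucker optimality conditions is reported in
#' `$meta`; if the iteration cap is exceeded the best iterate is returned
#' and flagged.
#'
#' @param problem a `node_problem`.
#' @param max_iter optional cap on active-set iterations.
#' @return A `coefficient_vector` with elementwise non-negative values.
#' @export
solve_nnls <- function(problem, max_iter = NULL) {
  stopifnot(inherits(problem, "node_problem"))
  if (ncol(problem$Phi) == 0L) {
    return(new_coefficient_vector(problem$node, numeric(0), character(0),
                                  meta = list(solver = "nnls", kkt = 0)))
  }
  G <- crossprod(problem$Phi)
  c_vec <- drop(crossprod(problem$Phi, problem$Y))
  sol <- nnls_activeset(G, c_vec, max_iter)
  x <- pmax(sol$x, 0)
  grad <- drop(G %*% x) - c_vec
  act <- x > 0
  kkt <- max(c(0, abs(grad[act]), pmax(-grad[!act], 0)))
  if (!sol$converged) {
    warning(sprintf("nnls: iteration cap exceeded (node %d); best iterate returned",
                    problem$node), call. = FALSE)
  }
  new_coefficient_vector(problem$node, x, problem$column_index$label,
                         meta = list(solver = "nnls", kkt = as.numeric(kkt),
                                     iterations = sol$iterations,
                                     converged = sol$converged))
}

#' Proximal operator of the Signal-Lasso penalty
#'
#' Exact scalar minimizer of `(xhat - x)^2 / 2 + alpha |x| + beta |x - 1|`,
#' the building block of the Signal Lasso: a soft-threshold with dead zones
#' around both 0 and 1, given by a five-piece closed form.
#'
#' @param xhat numeric vector of unpenalized values.
#' @param alpha non-negative penalty toward 0.
#' @param beta non-negative penalty toward 1.
#' @return Numeric vector of minimizers, same length as `xhat`.
#' @examples
#' prox_signal(c(-1, 0.1, 0.6, 1.05, 3), alpha = 0.5, beta = 0.3)
#' @export
prox_signal <- function(xhat, alpha, beta) {
  stop_if_not_scalar_number(alpha, "alpha")
  stop_if_not_scalar_number(beta, "beta")
  if (alpha < 0 || beta < 0) stop("penalties must be non-negative", call. = FALSE)
  out <- numeric(length(xhat))
  lo <- -alpha - beta
  mid_hi <- alpha - beta
  one_lo <- 1 + alpha - beta
  one_hi <- 1 + alpha + beta
  out[xhat < lo] <- xhat[xhat < lo] + alpha + beta
  # [lo, mid_hi] -> 0 (already zero)
  band <- xhat > mid_hi & xhat < one_lo
  out[band] <- xhat[band] - alpha + beta
  out[xhat >= one_lo & xhat <= one_hi] <- 1
  hi <- xhat > one_hi
  out[hi] <- xhat[hi] - alpha - beta
  out
}

signal_lasso_objective <- function(Phi, Y, x, alpha, beta) {
  r <- Y - Phi %*% x
  0.5 * sum(r^2) + alpha * sum(abs(x)) + beta * sum(abs(x - 1))
}

#' Signal Lasso for a node problem
#'
#' Minimizes `||Y_i - Phi_i A_i||_2^2 / 2 + alpha ||A_i||_1 +
#' beta ||A_i - 1||_1` by proximal-gradient descent with fixed step `1 / L`
#' (`L` the largest squared singular value of `Phi_i`, the Lipschitz constant
#' of the smooth part) and the elementwise [prox_signal()] operator. The
#' double penalty shrinks coefficients toward both 0 and 1, matching
#' unweighted (binary) structures. The objective is non-increasing across
#' iterations; convergence is declared when the iterate change drops below
#' `tol` in the infinity norm.
#'
#' No penalty values are canonical for this problem; the default
#' `1e-3 * max|Phi' Y|` is a data-scaled choice that users should treat as a
#' starting point for a grid.
#'
#' @param problem a `node_problem`.
#' @param alpha,beta non-negative penalties (`NULL` for the scaled default).
#' @param max_iter iteration cap; exceeding it flags `converged = FALSE` and
#'   returns the best iterate.
#' @param tol convergence tolerance on the iterate change.
#' @param init starting point: the minimal-norm least-squares solution
#'   (`"ols"`, default -- the objective is convex, so the limit is the same,
#'   but a warm start saves most iterations when the penalties are small) or
#'   the origin (`"zero"`).
#' @return A `coefficient_vector` with iterations, final objective and
#'   convergence flag in `$meta`.
#' @export
solve_signal_lasso <- function(problem, alpha = NULL, beta = NULL,
                               max_iter = 10000L, tol = 1e-10,
                               init = c("ols", "zero")) {
  init <- match.arg(init)
  stopifnot(inherits(problem, "node_problem"))
  Phi <- problem$Phi
  Y <- problem$Y
  H <- ncol(Phi)
  if (H == 0L) {
    return(new_coefficient_vector(problem$node, numeric(0), character(0),
                                  meta = list(solver = "signal_lasso",
                                              iterations = 0L, converged = TRUE,
                                              objective = 0.5 * sum(Y^2))))
  }
  cty <- crossprod(Phi, Y)
  default_pen <- 1e-3 * max(abs(cty))
  alpha <- alpha %||% default_pen
  beta <- beta %||% default_pen
  if (alpha < 0 || beta < 0) stop("penalties must be non-negative", call. = FALSE)
  G <- crossprod(Phi)
  L <- max(svd(Phi, nu = 0, nv = 0)$d)^2
  if (L == 0) L <- 1
  x <- if (init == "ols") unname(solve_ols(problem)$values) else numeric(H)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    grad <- G %*% x - cty
    x_new <- prox_signal(x - grad / L, alpha / L, beta / L)
    delta <- max(abs(x_new - x))
    x <- drop(x_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  obj <- signal_lasso_objective(Phi, Y, x, alpha, beta)
  if (!converged) {
    warning(sprintf("signal lasso: no convergence within %d iterations (node %d)",
                    max_iter, problem$node), call. = FALSE)
  }
  new_coefficient_vector(problem$node, x, problem$column_index$label,
                         meta = list(solver = "signal_lasso",
                                     iterations = iter, converged = converged,
                                     objective = as.numeric(obj),
                                     alpha = alpha, beta = beta,
                                     step = 1 / L))
}
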