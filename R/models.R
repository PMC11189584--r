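#' Specify the node dynamics and coupling functions
#'
#' A `model_spec` bundles everything the simulator and the reconstruction
#' need to know about the dynamical model: the per-node state dimension `n`,
#' the local dynamics `f_i`, and one coupling function `g^(d)` per
#' interaction order. The model `dx_i/dt = f_i(x_i) + sum_d sum_tuples
#' a^(d)_[i; j1..jd] g^(d)(x_i, x_j1, ..., x_jd)` is linear in the tensor
#' entries `a^(d)`, which is what makes reconstruction a linear problem.
#'
#' `local` must be vectorized: it receives a matrix of states (one row per
#' evaluation point, `n` columns) together with the parallel vector of node
#' indices (so node-dependent parameters can be looked up), and returns a
#' matrix of the same shape. Each `coupling[[d]]` receives the focal-node
#' state matrix and a list of `d` neighbor state matrices and returns a
#' matrix with `n` columns that is zero outside `coupled_components`.
#' Known coupling-strength constants (such as global sigmas) are folded into
#' the coupling functions, so that unweighted structures have 0/1 tensors.
#'
#' @param name model name (used in metadata).
#' @param state_dim per-node state dimension `n`.
#' @param local function `(X, nodes) -> X-like matrix`, the local dynamics.
#' @param coupling list of coupling functions, `coupling[[d]]` of order `d`.
#' @param coupled_components integer indices of the state components any
#'   coupling function can touch; its length is `n_g`, the number of usable
#'   regression rows per retained time sample.
#' @param params named list of model parameters (kept for metadata).
#' @param compiled optional tag (`"lv"` or `"rossler"`) selecting a compiled
#'   right-hand side for integration; user-defined models leave it `NULL`
#'   and are integrated through the (equivalent) interpreted evaluator.
#' @return An object of class `model_spec`.
#' @seealso [lv_model()], [rossler_model()]
#' @export
model_spec <- function(name, state_dim, local, coupling, coupled_components,
                       params = list(), compiled = NULL) {
  stopifnot(is.function(local), is.list(coupling), length(coupling) >= 1L)
  for (g in coupling) stopifnot(is.function(g))
  coupled_components <- as.integer(coupled_components)
  if (any(coupled_components < 1L) || any(coupled_components > state_dim)) {
    stop("`coupled_components` out of range", call. = FALSE)
  }
  structure(list(name = name, state_dim = as.integer(state_dim),
                 local = local, coupling = coupling,
                 coupled_components = coupled_components,
                 max_order = length(coupling), params = params,
                 compiled = compiled),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: n = %d, orders 1..%d, coupled components {%s}\n",
              x$name, x$state_dim, x$max_order,
              paste(x$coupled_components, collapse = ",")))
  invisible(x)
}

#' Default parameter table of the 7-species ecosystem
#'
#' Growth rates, carrying capacities and initial abundances of the
#' microbial-ecosystem case study (growth rates drawn from U(0,1), carrying
#' capacities from U(1,100), integer initial abundances in (10,100); the
#' concrete draw below is the case study's reference parameter set).
#'
#' @return `data.frame` with columns `node`, `r`, `k`, `x0`.
#' @export
lv_parameters <- function() {
  data.frame(
    node = 1:7,
    r  = c(0.6099, 0.6177, 0.8594, 0.8055, 0.5767, 0.1829, 0.2399),
    k  = c(88.7647, 3.8387, 49.5002, 17.6248, 97.8894, 71.5568, 50.5467),
    x0 = c(30, 45, 32, 50, 55, 30, 40)
  )
}

#' Generalized Lotka-Volterra model with three-body terms
#'
#' Population dynamics with logistic local growth
#' `f_i(x_i) = r_i x_i (1 - x_i / k_i)` and product-form couplings
#' `g^(1)(x_i, x_j) = x_i x_j`, `g^(2)(x_i, x_j, x_k) = x_i x_j x_k`
#' (permutation-invariant in the neighbors, so unordered tuples).
#' Defaults are the 7-species reference parameter table, [lv_parameters()].
#'
#' @param r vector of growth rates.
#' @param k vector of positive carrying capacities.
#' @return A [model_spec()] with `state_dim = 1`, `n_g = 1`.
#' @examples
#' m <- lv_model()
#' m$local(matrix(0.5), nodes = 1)  # r1 * 0.5 * (1 - 0.5 / k1)
#' @export
lv_model <- function(r = lv_parameters()$r, k = lv_parameters()$k) {
  if (any(k <= 0)) stop("carrying capacities must be positive", call. = FALSE)
  if (length(r) != length(k)) stop("`r` and `k` lengths differ", call. = FALSE)
  force(r); force(k)
  model_spec(
    name = "lotka_volterra",
    state_dim = 1L,
    local = function(X, nodes) {
      x <- X[, 1L]
      matrix(r[nodes] * x * (1 - x / k[nodes]), ncol = 1L)
    },
    coupling = list(
      function(Xi, nb) Xi[, 1L, drop = FALSE] * nb[[1L]][, 1L, drop = FALSE],
      function(Xi, nb) Xi[, 1L, drop = FALSE] * nb[[1L]][, 1L, drop = FALSE] *
        nb[[2L]][, 1L, drop = FALSE]
    ),
    coupled_components = 1L,
    params = list(r = r, k = k),
    compiled = "lv"
  )
}

#' Coupled Rossler oscillators with cubic three-body coupling
#'
#' Each node is a three-variable Rossler oscillator
#' (`dx = -y - z + coupling`, `dy = x + a y`, `dz = b + z (x - c)`) coupled
#' only through its first component: diffusive pairwise coupling
#' `sigma1 (x_j - x_i)` and the symmetric cubic three-body term
#' `sigma2 (x_j^2 x_k + x_j x_k^2 - 2 x_i^3)`, which vanishes on the
#' synchronized manifold. The known strengths `sigma1`, `sigma2` are folded
#' into the coupling functions so that an unweighted structure has 0/1
#' tensors.
#'
#' @param a,b,c local Rossler parameters (defaults 0.2, 0.2, 9).
#' @param sigma1,sigma2 non-negative coupling strengths
#'   (defaults `1e-4`, `1e-5`).
#' @return A [model_spec()] with `state_dim = 3`, `n_g = 1`.
#' @export
rossler_model <- function(a = 0.2, b = 0.2, c = 9,
                          sigma1 = 1e-4, sigma2 = 1e-5) {
  if (sigma1 < 0 || sigma2 < 0) stop("sigmas must be non-negative", call. = FALSE)
  force(a); force(b); force(c); force(sigma1); force(sigma2)
  zero2 <- function(m) cbind(m, 0, 0, deparse.level = 0)
  model_spec(
    name = "rossler",
    state_dim = 3L,
    local = function(X, nodes) {
      cbind(-X[, 2L] - X[, 3L],
            X[, 1L] + a * X[, 2L],
            b + X[, 3L] * (X[, 1L] - c), deparse.level = 0)
    },
    coupling = list(
      function(Xi, nb) zero2(sigma1 * (nb[[1L]][, 1L, drop = FALSE] -
                                         Xi[, 1L, drop = FALSE])),
      function(Xi, nb) {
        xj <- nb[[1L]][, 1L]; xk <- nb[[2L]][, 1L]; xi <- Xi[, 1L]
        zero2(matrix(sigma2 * (xj^2 * xk + xj * xk^2 - 2 * xi^3), ncol = 1L))
      }
    ),
    coupled_components = 1L,
    params = list(a = a, b = b, c = c, sigma1 = sigma1, sigma2 = sigma2),
    compiled = "rossler"
  )
}

#' Random initial state for the Rossler case study
#'
#' Draws per-node initial conditions uniformly from the case study's ranges
#' `x in [-3, 3]`, `y in [-3, 3]`, `z in [-1, 7]`.
#'
#' @param n_nodes number of nodes.
#' @param seed optional RNG seed.
#' @return `n_nodes` x 3 matrix.
#' @export
rossler_initial_state <- function(n_nodes, seed = NULL) {
  with_seed(seed, cbind(stats::runif(n_nodes, -3, 3),
                        stats::runif(n_nodes, -3, 3),
                        stats::runif(n_nodes, -1, 7)))
}
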