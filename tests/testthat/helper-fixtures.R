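# Small structures and models shared across tests.

# a directed weighted structure on n nodes with every possible order-1 and
# (optionally) order-2 slot filled with random weights
random_structure <- function(n_nodes, max_order = 2L, density = 0.5,
                             weight_sd = 1) {
  entries <- NULL
  for (i in seq_len(n_nodes)) {
    ci <- column_index(n_nodes, max_order, i, "unordered")
    keep <- stats::runif(nrow(ci)) < density
    if (!any(keep)) next
    vals <- numeric(nrow(ci))
    vals[keep] <- stats::rnorm(sum(keep), sd = weight_sd)
    entries <- rbind(entries, unflatten(vals, i, n_nodes, max_order, "unordered"))
  }
  if (is.null(entries)) {
    entries <- data.frame(order = 1L, node = 1L, n1 = 2L,
                          n2 = NA_integer_, weight = 1)
  }
  hyper_structure(n_nodes, max_order, entries, convention = "unordered")
}

# small generalized LV community with random positive k and mild couplings:
# rich transients, well-conditioned design
toy_lv_system <- function(n_nodes = 4, seed = 42, weight_sd = 0.02) {
  set.seed(seed)
  r <- stats::runif(n_nodes, 0.5, 1.5)
  k <- stats::runif(n_nodes, 1, 5)
  model <- lv_model(r = r, k = k)
  hs <- random_structure(n_nodes, max_order = 2L, density = 0.4,
                         weight_sd = weight_sd)
  x0 <- stats::runif(n_nodes, 0.5, 2)
  list(model = model, structure = hs, x0 = matrix(x0, ncol = 1L))
}

# analytic trajectory built directly from a function of time (no ODE solve)
analytic_trajectory <- function(f, t_max, M, n_nodes = 1L, state_dim = 1L) {
  times <- seq(0, t_max, length.out = M + 1L)
  states <- array(NA_real_, c(M + 1L, n_nodes, state_dim))
  for (i in seq_len(n_nodes)) {
    for (cmp in seq_len(state_dim)) {
      states[, i, cmp] <- f(times, i, cmp)
    }
  }
  hordyn:::new_trajectory(times, states, meta = list(model = "analytic"))
}

make_problem <- function(Phi, Y, node = 1L) {
  Phi <- as.matrix(Phi)
  structure(list(node = node, Y = as.numeric(Y), Phi = Phi,
                 column_index = data.frame(
                   order = rep(1L, ncol(Phi)),
                   n1 = seq_len(ncol(Phi)) + 1L,
                   label = paste0("c", seq_len(ncol(Phi)))),
                 n_g = 1L, m_range = c(0L, nrow(Phi) - 1L)),
            class = "node_problem")
}
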