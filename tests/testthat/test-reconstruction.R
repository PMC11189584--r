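# hand-built constant trajectory + derivative estimate for assembly checks
constant_traj <- function(states_row, z_row, M = 4, n = 1) {
  n_nodes <- nrow(states_row)
  states <- array(NA_real_, c(M + 1, n_nodes, n))
  derivs <- array(NA_real_, c(M + 1, n_nodes, n))
  for (m in 1:(M + 1)) {
    states[m, , ] <- states_row
    derivs[m, , ] <- z_row
  }
  hordyn:::new_trajectory(seq(0, 1, length.out = M + 1), states, derivs,
                          meta = list(model = "constant"))
}

test_that("assembly reproduces the hand-built two-species system", {
  # r1 = 1, k1 = 1, states (2, 3), true a12 = 0.5:
  # z1 = 2(1-2) + 0.5*2*3 = 1, y1 = z1 - f1 = 3, design g1 = x1 x2 = 6
  m <- lv_model(r = c(1, 1), k = c(1, 1))
  z <- matrix(c(1, 3 * (1 - 3)), ncol = 1)  # node 2 uncoupled
  tr <- constant_traj(matrix(c(2, 3), ncol = 1), z)
  probs <- assemble_problems(tr, exact_derivatives(tr), m, max_order = 1)
  expect_equal(unname(probs[[1]]$Y), rep(3, 5))
  expect_equal(unname(probs[[1]]$Phi[, 1]), rep(6, 5))
  expect_equal(unname(solve_ols(probs[[1]])$values), 0.5)
  expect_equal(unname(solve_ols(probs[[2]])$values), 0)
})

test_that("row counts follow the coupled-component bookkeeping", {
  mr <- rossler_model()
  kc <- build_karate_complex(0.1, seed = 2)
  x0 <- rossler_initial_state(34, seed = 2)
  tr <- simulate_trajectory(mr, kc, x0, t_max = 3, M = 30)
  fd <- finite_difference(tr, 2)
  probs <- assemble_problems(tr, fd, mr, max_order = 2)
  # only the x-component is coupled: n_g = 1, one row per retained sample
  expect_equal(nrow(probs[[1]]$Phi), 30 - 1)
  expect_equal(probs[[1]]$n_g, 1L)
  expect_equal(ncol(probs[[1]]$Phi), count_unknowns(34, 2, "unordered"))
})

test_that("candidate restriction shrinks the design and still recovers", {
  sys <- toy_lv_system(n_nodes = 5, seed = 8)
  tr <- simulate_trajectory(sys$model, sys$structure, sys$x0, t_max = 6,
                            M = 80, with_derivatives = TRUE)
  probs <- assemble_problems(tr, exact_derivatives(tr), sys$model, 2,
                             candidates = sys$structure)
  for (i in 1:5) {
    truth_i <- flatten(sys$structure, i)
    support <- names(truth_i)[truth_i != 0]
    expect_setequal(probs[[i]]$column_index$label, support)
    if (length(support)) {
      cv <- solve_ols(probs[[i]])
      expect_equal(cv$values[support], truth_i[support], tolerance = 1e-6)
    }
  }
})

test_that("exact derivatives give exact recovery for determined systems", {
  sys <- toy_lv_system(n_nodes = 4, seed = 3)
  tr <- simulate_trajectory(sys$model, sys$structure, sys$x0, t_max = 6,
                            M = 60, with_derivatives = TRUE)
  fit <- reconstruct(tr, sys$model, solver = "ols")
  expect_lt(reconstruction_error(sys$structure, fit), 1e-8)
  expect_lt(fit$discrepancy$E, 1e-16)
})

test_that("all three solvers recover a non-negative truth on determined data", {
  set.seed(17)
  n <- 4
  model <- lv_model(r = runif(n, 0.5, 1.5), k = runif(n, 1, 4))
  entries <- rbind(
    data.frame(order = 1, node = c(1, 2, 3), n1 = c(2, 4, 1),
               n2 = NA, weight = c(0.05, 0.08, 0.03)),
    data.frame(order = 2, node = c(1, 4), n1 = c(2, 1), n2 = c(3, 2),
               weight = c(0.04, 0.06)))
  hs <- hyper_structure(n, 2, entries)
  x0 <- matrix(runif(n, 0.5, 2), ncol = 1)
  tr <- simulate_trajectory(model, hs, x0, t_max = 6, M = 50,
                            with_derivatives = TRUE)
  for (solver in c("ols", "nnls", "signal_lasso")) {
    fit <- reconstruct(tr, model, solver = solver,
                       alpha = 1e-10, beta = 1e-10, tol = 1e-13,
                       max_iter = 100000)
    expect_lt(reconstruction_error(hs, fit), 1e-6)
  }
})

test_that("thresholded estimates match the exhaustive binary oracle", {
  # 0/1 truth, H = 6 unknowns per node: brute force over all 2^6 supports
  set.seed(28)
  n <- 4
  model <- lv_model(r = runif(n, 0.8, 1.2), k = runif(n, 2, 4))
  entries <- rbind(
    data.frame(order = 1, node = c(1, 2), n1 = c(3, 1), n2 = NA,
               weight = c(0.1, 0.1)),
    data.frame(order = 2, node = 3, n1 = 1, n2 = 4, weight = 0.1))
  hs01 <- hyper_structure(n, 2, entries)
  # weights 0.1 folded out: reconstruct the 0/1 tensor of 0.1-weighted edges
  tr <- simulate_trajectory(model, hs01, matrix(runif(n, 0.5, 2), ncol = 1),
                            t_max = 6, M = 40, with_derivatives = TRUE)
  probs <- assemble_problems(tr, exact_derivatives(tr), model, 2)
  for (i in 1:n) {
    p <- probs[[i]]
    est <- as.numeric(solve_ols(p)$values / 0.1 >= 0.5)
    H <- ncol(p$Phi)
    best <- NULL; best_rss <- Inf
    for (mask in 0:(2^H - 1)) {
      b <- as.numeric(bitwAnd(mask, 2^(0:(H - 1))) > 0)
      rss <- sum((p$Y - p$Phi %*% (0.1 * b))^2)
      if (rss < best_rss) { best_rss <- rss; best <- b }
    }
    expect_equal(est, best)
    expect_equal(0.1 * best, unname(flatten(hs01, i)))
  }
})

test_that("reconstruct returns a fully-formed model object", {
  hs <- build_lv_hypergraph(seed = 1)
  m <- lv_model()
  tr <- simulate_trajectory(m, hs, lv_parameters()$x0, t_max = 20, M = 120,
                            with_derivatives = TRUE)
  fit <- reconstruct(tr, m, solver = "ols")
  expect_s3_class(fit, "hyperfit")
  expect_equal(dim(coef(fit)), c(21L, 7L))
  expect_equal(coef_entry(fit, 2, c(3, 7)), 0.0062, tolerance = 1e-4)
  expect_equal(coef_entry(fit, 4, c(1, 6)), 0.0016, tolerance = 1e-4)
  # residuals/fitted are consistent with the discrepancy
  expect_equal(colSums(residuals(fit)^2), fit$discrepancy$E_i)
  expect_equal(sum(fit$discrepancy$E_i), fit$discrepancy$E)
  # predict reproduces the true right-hand side at sampled states
  st <- matrix(tr$states[5, , ], ncol = 1)
  expect_equal(predict(fit, st), evaluate_rhs(m, hs, st), tolerance = 1e-5)
  # simulate from the fitted structure tracks the original trajectory
  tr2 <- simulate(fit, x0 = lv_parameters()$x0, t_max = 5, M = 10)
  tr_ref <- simulate_trajectory(m, hs, lv_parameters()$x0, t_max = 5, M = 10)
  expect_equal(tr2$states, tr_ref$states, tolerance = 1e-4)
  expect_output(print(fit), "ols reconstruction")
  expect_output(print(summary(fit)), "Discrepancy")
})

test_that("symmetrize averages focal-node rotations and tracks asymmetry", {
  # perfectly symmetric input: identical weights, zero asymmetry
  sym <- hyper_structure(3, 1, data.frame(order = 1, node = c(1, 2), n1 = c(2, 1),
                                          n2 = NA, weight = c(1, 1)))
  out <- symmetrize(sym)
  expect_equal(out$entries$weight, c(1, 1))
  expect_equal(attr(out, "asymmetry"), 0)
  # mean rule: 1.0 and 0.8 -> 0.9 with asymmetry 0.2
  asym <- hyper_structure(3, 1, data.frame(order = 1, node = c(1, 2), n1 = c(2, 1),
                                           n2 = NA, weight = c(1, 0.8)))
  out2 <- symmetrize(asym)
  expect_equal(unique(out2$entries$weight), 0.9)
  expect_equal(attr(out2, "asymmetry"), 0.2, tolerance = 1e-12)
  # a missing rotation counts as zero
  half <- hyper_structure(3, 1, data.frame(order = 1, node = 1, n1 = 2,
                                           n2 = NA, weight = 1))
  out3 <- symmetrize(half)
  expect_equal(unique(out3$entries$weight), 0.5)
  expect_equal(attr(out3, "asymmetry"), 1)
})

test_that("zero response yields the all-zero minimal-norm reconstruction", {
  sys <- toy_lv_system(n_nodes = 3, seed = 10)
  empty <- hyper_structure(3, 2)
  tr <- simulate_trajectory(sys$model, empty, sys$x0, t_max = 4, M = 30,
                            with_derivatives = TRUE)
  fit <- reconstruct(tr, sys$model, solver = "ols")
  expect_equal(max(abs(coef(fit))), 0, tolerance = 1e-10)
})

test_that("reconstruction serializes to TSV with a JSON sidecar", {
  sys <- toy_lv_system(n_nodes = 4, seed = 3)
  tr <- simulate_trajectory(sys$model, sys$structure, sys$x0, t_max = 6,
                            M = 60, with_derivatives = TRUE)
  fit <- reconstruct(tr, sys$model, solver = "ols")
  tf <- tempfile(fileext = ".tsv")
  write_reconstruction(fit, tf)
  back <- read_hyperedge_tsv(tf)
  for (i in 1:4) {
    expect_equal(flatten(back, i), flatten(sys$structure, i), tolerance = 1e-6)
  }
  side <- jsonlite::fromJSON(paste0(tf, ".json"))
  expect_equal(side$solver, "ols")
  expect_length(side$E_i, 4L)
})
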