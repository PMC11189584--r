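test_that("right-hand side matches hand evaluations of the coupled model", {
  # empty structure: pure local dynamics
  m <- lv_model(r = c(1, 1), k = c(1, 1))
  empty <- hyper_structure(2, 1)
  expect_equal(evaluate_rhs(m, empty, c(0.5, 0.5))[, 1], c(0.25, 0.25))
  # one pairwise link: dx1 = 2(1 - 2) + 0.5 * 2 * 3 = 1
  hs <- hyper_structure(2, 1, data.frame(order = 1, node = 1, n1 = 2,
                                         weight = 0.5))
  out <- evaluate_rhs(m, hs, c(2, 3))
  expect_equal(out[1, 1], 2 * (1 - 2) + 0.5 * 2 * 3)
  expect_equal(out[2, 1], 3 * (1 - 3))
  # LV three-body coupling is the plain product
  m7 <- lv_model()
  hs2 <- hyper_structure(7, 2, data.frame(order = 2, node = 2, n1 = 3, n2 = 7,
                                          weight = 1))
  base <- evaluate_rhs(m7, hyper_structure(7, 2), rep(1, 7))
  with2 <- evaluate_rhs(m7, hs2, rep(1, 7))
  expect_equal(with2[2, 1] - base[2, 1], 1)  # g2(1,1,1) = 1
  # Rossler cubic coupling vanishes on the synchronized manifold
  mr <- rossler_model(sigma2 = 1)
  hsr <- hyper_structure(3, 2, data.frame(order = 2, node = 1, n1 = 2, n2 = 3,
                                          weight = 1))
  st <- matrix(rep(c(1, 0.3, 0.2), each = 3), nrow = 3)
  expect_equal(evaluate_rhs(mr, hsr, st), evaluate_rhs(mr, hyper_structure(3, 2), st))
  expect_error(evaluate_rhs(m, empty, c(1, NA)), "finite")
  expect_error(evaluate_rhs(m, empty, c(1, 2, 3)), "length|shape")
})

test_that("the right-hand side is linear in the structure weights", {
  set.seed(12)
  m <- lv_model(r = runif(5, 0.5, 1.5), k = runif(5, 1, 4))
  for (rep in 1:20) {
    joint <- random_structure(5)
    n_e <- nrow(joint$entries)
    if (n_e < 2L) next
    split_at <- sample(seq_len(n_e - 1L), 1)
    s1 <- hyper_structure(5, 2, joint$entries[seq_len(split_at), ])
    s2 <- hyper_structure(5, 2, joint$entries[-seq_len(split_at), ])
    x <- matrix(runif(5, 0.2, 2), ncol = 1)
    f <- m$local(x, 1:5)
    expect_equal(evaluate_rhs(m, joint, x),
                 evaluate_rhs(m, s1, x) + evaluate_rhs(m, s2, x) - f,
                 tolerance = 1e-12)
  }
})

test_that("simulation reaches the logistic carrying capacity", {
  m <- lv_model(r = c(1, 1), k = c(1, 1))
  tr <- simulate_trajectory(m, hyper_structure(2, 1), c(0.5, 0.5),
                            t_max = 40, M = 10)
  expect_lt(max(abs(tr$states[11, , 1] - 1)), 1e-6)
  expect_equal(length(tr$times), 11L)
  expect_equal(tr$dt, 4)
})

test_that("uncoupled Rossler nodes reproduce the isolated oscillator", {
  mr <- rossler_model(sigma1 = 0, sigma2 = 0)
  kc3 <- hyper_structure(3, 2, data.frame(order = 1, node = c(1, 2), n1 = c(2, 1),
                                          n2 = NA, weight = 1))
  x0 <- rbind(c(1, 1, 1), c(2, 0, 4), c(1, 1, 1))
  tr <- simulate_trajectory(mr, kc3, x0, t_max = 20, M = 50)
  iso <- simulate_trajectory(mr, hyper_structure(2, 1),
                             x0[1:2, ], t_max = 20, M = 50)
  expect_equal(tr$states[, 1, ], iso$states[, 1, ], tolerance = 1e-9)
  # nodes 1 and 3 share the initial state, so their trajectories coincide
  expect_equal(tr$states[, 1, ], tr$states[, 3, ], tolerance = 1e-10)
})

test_that("compiled and interpreted right-hand sides integrate identically", {
  hs <- build_lv_hypergraph(seed = 2)
  m <- lv_model()
  m_interp <- m; m_interp$compiled <- NULL
  tr1 <- simulate_trajectory(m, hs, lv_parameters()$x0, t_max = 5, M = 20)
  tr2 <- simulate_trajectory(m_interp, hs, lv_parameters()$x0, t_max = 5, M = 20)
  expect_equal(tr1$states, tr2$states, tolerance = 1e-11)

  mr <- rossler_model()
  mr_i <- mr; mr_i$compiled <- NULL
  kc <- build_karate_complex(0.2, seed = 4)
  x0 <- rossler_initial_state(34, seed = 4)
  tr3 <- simulate_trajectory(mr, kc, x0, t_max = 2, M = 20)
  tr4 <- simulate_trajectory(mr_i, kc, x0, t_max = 2, M = 20)
  expect_equal(tr3$states, tr4$states, tolerance = 1e-11)
})

test_that("stored derivative samples equal the right-hand side at the states", {
  hs <- build_lv_hypergraph(seed = 1)
  m <- lv_model()
  tr <- simulate_trajectory(m, hs, lv_parameters()$x0, t_max = 10, M = 25,
                            with_derivatives = TRUE)
  for (mm in c(1, 13, 26)) {
    expect_equal(tr$derivatives[mm, , , drop = FALSE],
                 array(evaluate_rhs(m, hs, tr$states[mm, , , drop = TRUE]),
                       c(1, 7, 1)),
                 tolerance = 1e-13)
  }
})

test_that("halving integration tolerances barely changes the samples", {
  hs <- build_lv_hypergraph(seed = 1)
  m <- lv_model()
  x0 <- lv_parameters()$x0
  tr1 <- simulate_trajectory(m, hs, x0, t_max = 20, M = 40)
  tr2 <- simulate_trajectory(m, hs, x0, t_max = 20, M = 40,
                             rtol = 5e-13, atol = 5e-13)
  expect_lt(max(abs(tr1$states - tr2$states)) / max(abs(tr1$states)), 1e-8)
})

test_that("trajectory text files round-trip exactly", {
  hs <- build_lv_hypergraph(seed = 1)
  m <- lv_model()
  tr <- simulate_trajectory(m, hs, lv_parameters()$x0, t_max = 5, M = 12,
                            with_derivatives = TRUE)
  tf <- tempfile(fileext = ".tsv")
  write_trajectory(tr, tf)
  back <- read_trajectory(tf)
  expect_identical(back$states, tr$states)
  expect_identical(back$derivatives, tr$derivatives)
  expect_identical(back$times, tr$times)
  expect_equal(back$deriv_range, c(0L, 12L))
})

test_that("integration failure is reported with the failing time", {
  # mutual three-body facilitation: dx ~ x^3 growth, finite-time blow-up
  m <- lv_model(r = c(1, 1, 1), k = c(1, 1, 1))
  hs <- hyper_structure(3, 2, data.frame(order = 2, node = 1:3,
                                         n1 = c(2, 1, 1), n2 = c(3, 3, 2),
                                         weight = 10))
  expect_error(
    suppressWarnings(simulate_trajectory(m, hs, c(5, 5, 5), t_max = 20, M = 10)),
    "integration failed"
  )
})
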