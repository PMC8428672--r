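test_that("the Hamiltonian assembles running cost and dynamics correctly", {
  p <- oc_scenario_parameters()
  w <- control_weights()
  zero <- numeric(11)
  expect_equal(hamiltonian(zero, numeric(11), 0, 0, w, p), 0)
  y <- numeric(11); y[3] <- 50; y[11] <- 7
  expect_equal(hamiltonian(y, numeric(11), 1, 0, w, p),
               w$B1 * 50 + w$B2 * 7 + w$C1 / 2)
  # duplicate-implementation oracle: running cost plus costate-weighted
  # right-hand sides assembled from the independently coded sbe_rhs()
  set.seed(10)
  for (rep in 1:25) {
    y <- random_state11()
    L <- rnorm(11, 0, 5)
    u <- runif(2)
    state18 <- c(y, numeric(7))
    f <- sbe_rhs(state18, p, u1 = u[1], u2 = u[2], model = "control")[1:11]
    manual <- w$B1 * y[3] + w$B2 * y[11] +
      0.5 * (w$C1 * u[1]^2 + w$C2 * u[2]^2) + sum(L * unname(f))
    expect_equal(hamiltonian(y, L, u[1], u[2], w, p), manual,
                 tolerance = 1e-12)
  }
})

test_that("analytic costate rates match finite-difference Hamiltonian gradients", {
  p <- oc_scenario_parameters()
  w <- control_weights()
  # zero costates: only the running cost survives the gradient
  y <- random_state11()
  a0 <- adjoint_rhs(y, numeric(11), 0.3, 0.6, w, p)
  expect_equal(a0, -c(0, 0, w$B1, rep(0, 7), w$B2))
  set.seed(11)
  worst <- 0
  for (rep in 1:100) {
    y <- random_state11()
    L <- rnorm(11, 0, 10)
    u <- runif(2)
    a <- adjoint_rhs(y, L, u[1], u[2], w, p)
    for (j in 1:11) {
      h <- 1e-4 * max(abs(y[j]), 1)
      f <- function(v) {
        yy <- y; yy[j] <- v
        hamiltonian(yy, L, u[1], u[2], w, p)
      }
      fd <- -fd_deriv(f, y[j], h)
      worst <- max(worst, abs(a[j] - fd) / max(abs(fd), abs(a[j]), 1e-8))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("without envenomation the snake costate sees only the logistic term", {
  p <- oc_scenario_parameters(beta = 0)
  w <- control_weights()
  set.seed(12)
  y <- random_state11()
  L <- rnorm(11)
  a <- adjoint_rhs(y, L, 0.5, 0.5, w, p)
  expect_equal(a[10],
               -L[10] * (p$Lambda_S * (1 - 2 * y[10] / p$K_S) - p$mu_S))
})

test_that("closed-form control characterisation minimises the Hamiltonian", {
  p <- oc_scenario_parameters()
  w <- control_weights()
  y <- random_state11()
  expect_equal(optimal_controls_pointwise(y, numeric(11), w, p), c(0, 0))
  # a costate pattern pushing awareness beyond its cap clamps at exactly 1
  L <- numeric(11); L[1] <- 1e6; L[2] <- -1e6
  expect_identical(optimal_controls_pointwise(y, L, w, p)[1], 1)
  set.seed(13)
  worst <- 0
  for (rep in 1:100) {
    y <- random_state11()
    L <- rnorm(11, 0, 1e-3)
    u <- optimal_controls_pointwise(y, L, w, p)
    o1 <- optimize(function(v) hamiltonian(y, L, v, u[2], w, p),
                   c(0, 1), tol = 1e-10)$minimum
    o2 <- optimize(function(v) hamiltonian(y, L, u[1], v, w, p),
                   c(0, 1), tol = 1e-10)$minimum
    # optimize() localises boundary minima only to ~1e-4
    dev1 <- if (u[1] %in% c(0, 1)) max(abs(u[1] - o1) - 1e-4, 0)
            else abs(u[1] - o1)
    dev2 <- if (u[2] %in% c(0, 1)) max(abs(u[2] - o2) - 1e-4, 0)
            else abs(u[2] - o2)
    worst <- max(worst, dev1, dev2)
  }
  expect_lt(worst, 1e-5)
  expect_error(optimal_controls_pointwise(y, L, control_weights(C1 = 0), p))
})

test_that("the objective quadrature behaves on known integrands", {
  w <- control_weights()
  t10 <- seq(0, 10, by = 0.1)
  n <- length(t10)
  expect_equal(evaluate_objective(t10, numeric(n), numeric(n),
                                  numeric(n), numeric(n), w), 0)
  # constant integrand C1/2 over 10 time units
  expect_equal(evaluate_objective(t10, numeric(n), numeric(n),
                                  rep(1, n), numeric(n), w), 10 * w$C1 / 2)
  expect_error(evaluate_objective(t10, numeric(n - 1), numeric(n),
                                  numeric(n), numeric(n), w), "mismatch")
  # refinement oracle on a smooth random integrand
  set.seed(14)
  f <- function(t) 50 + 40 * sin(t / 2) + 5 * t
  tc <- seq(0, 12, length.out = 121)
  tf <- seq(0, 12, length.out = 961)
  Jc <- evaluate_objective(tc, f(tc), f(tc) / 2, pmin(abs(sin(tc)), 1),
                           pmin(tc / 12, 1), w)
  Jf <- evaluate_objective(tf, f(tf), f(tf) / 2, pmin(abs(sin(tf)), 1),
                           pmin(tf / 12, 1), w)
  expect_equal(Jc, Jf, tolerance = 1e-3)
})

test_that("a costless objective drives the sweep to zero controls", {
  sol <- forward_backward_sweep(sbe_initial_state(), oc_scenario_parameters(),
                                control_weights(B1 = 0, B2 = 0), months = 3,
                                n_steps = 90, max_iter = 30)
  expect_true(sol$converged)
  expect_equal(max(abs(sol$u1)), 0)
  expect_equal(max(abs(sol$u2)), 0)
  expect_equal(sol$objective, 0)
})

test_that("sweep iterates stay admissible and beat corner policies", {
  init <- sbe_initial_state()
  p <- oc_scenario_parameters()
  w <- control_weights()
  sol <- forward_backward_sweep(init, p, w, months = 6, n_steps = 360,
                                max_iter = 60)
  expect_true(sol$converged)
  expect_true(all(sol$u1 >= 0 & sol$u1 <= 1))
  expect_true(all(sol$u2 >= 0 & sol$u2 <= 1))
  expect_true(all(abs(sol$adjoints[nrow(sol$adjoints), ]) == 0))
  for (u in list(c(0, 0), c(1, 1), c(1, 0), c(0, 1))) {
    expect_lte(sol$objective,
               constant_policy_objective(init, p, w, months = 6,
                                         u1 = u[1], u2 = u[2],
                                         n_steps = 360) * (1 + 1e-6))
  }
})
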