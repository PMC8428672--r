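test_that("force of infection follows the frequency-dependent form", {
  expect_equal(force_of_infection(0.0742, 0, 1e6), 0)
  expect_equal(force_of_infection(0.0742, 1e6, 1e6), 0.0371)
  # baseline snake and human totals, hand arithmetic:
  # 0.0742 * 12250 / (21466000 + 12250)
  expect_equal(force_of_infection(0.0742, 1.2250e4, 2.1466e7),
               4.23165e-05, tolerance = 1e-4)
  expect_error(force_of_infection(0.0742, 0, 0), "degenerate")
  expect_error(force_of_infection(-1, 1, 1), "nonnegative")
})

test_that("right-hand side matches hand-evaluated special cases", {
  p <- sbe_parameters()
  zero <- setNames(numeric(18), names(sbe_initial_state()))
  d <- sbe_rhs(zero, p)
  expect_equal(d[["S_U"]], p$Lambda_H)
  expect_equal(unname(d[-1]), numeric(17))

  # logistic equilibrium of the snake subsystem
  eq <- zero
  eq[["N_S"]] <- p$K_S * (1 - p$mu_S / p$Lambda_S)
  expect_equal(sbe_rhs(eq, p)[["N_S"]], 0, tolerance = 1e-12)

  # dI/dt at the baseline state, term-by-term hand evaluation
  y <- sbe_initial_state()
  N_H <- sum(y[1:9])
  lam <- p$beta * y[["N_S"]] / (N_H + y[["N_S"]])
  dI_hand <- ((1 - p$theta) * y[["S_E"]] + y[["S_U"]]) * lam -
    (p$tau + p$delta_1 + p$mu_H) * y[["I"]]
  expect_equal(sbe_rhs(y, p)[["I"]], dI_hand, tolerance = 1e-12)

  bad <- y; bad[["I"]] <- -1e3
  expect_error(sbe_rhs(bad, p), "negative")
  expect_error(sbe_rhs(y, p, u1 = 1.2), "\\[0, 1\\]")
})

test_that("constant and control variants differ only in late death terms", {
  p <- sbe_parameters()
  y <- sbe_initial_state()
  d_const <- sbe_rhs(y, p, u1 = 1, u2 = 1, model = "constant")
  d_ctrl <- sbe_rhs(y, p, u1 = 1, u2 = 1, model = "control")
  late <- y[["T_L"]] + y[["V_L"]]
  expect_equal(d_const[["D"]] - d_ctrl[["D"]], late * p$delta_2)
  expect_equal(d_ctrl[["T_L"]] - d_const[["T_L"]], y[["T_L"]] * p$delta_2)
  expect_equal(d_ctrl[["V_L"]] - d_const[["V_L"]], y[["V_L"]] * p$delta_2)
  same <- setdiff(names(d_const), c("D", "T_L", "V_L"))
  expect_equal(d_const[same], d_ctrl[same])
})

test_that("snake subsystem reproduces the closed-form logistic solution", {
  p <- sbe_parameters()
  init <- sbe_initial_state(S_U = 0, S_E = 0, I = 0, T_E = 0, T_L = 0,
                            V_E = 0, V_L = 0, R_D = 0, R_W = 0,
                            N_S = 5e3, D = 0)
  p2 <- sbe_parameters(Lambda_H = 0)
  traj <- simulate_sbe(params = p2, init = init, months = 24, step = 0.5)
  r <- p$Lambda_S - p$mu_S
  K_eff <- p$K_S * (1 - p$mu_S / p$Lambda_S)
  expected <- K_eff / (1 + (K_eff / 5e3 - 1) * exp(-r * traj$time))
  expect_equal(traj$N_S, expected, tolerance = 1e-6)
})

test_that("without envenoming the human population settles at its carrying level", {
  p <- sbe_parameters(beta = 0, delta_1 = 0, delta_2 = 0)
  traj <- simulate_sbe(params = p, init = sbe_initial_state(), months = 2000,
                       step = 25)
  N_H <- rowSums(traj[, 2:10])
  target <- p$Lambda_H / p$mu_H
  gap <- abs(N_H - target)
  expect_true(all(diff(gap) <= 1e-6 * target))  # monotone approach
  expect_lt(gap[length(gap)] / target, 0.01)
  expect_equal(traj$D - traj$D[1], rep(0, nrow(traj)))
})

test_that("trajectories keep states nonnegative and trackers nondecreasing", {
  traj <- simulate_sbe(months = 21, step = 0.25)
  expect_true(min(as.matrix(traj[, -1])) >= 0)
  for (col in c("C_inc", "C_TE", "C_TL", "C_VE", "C_VL", "C_RD", "C_RW", "D"))
    expect_true(!is.unsorted(traj[[col]]), label = paste(col, "nondecreasing"))
  expect_true(all(traj$N_S <= max(traj$N_S[1], sbe_parameters()$K_S) + 1e-6))
})

test_that("human bookkeeping identity holds along trajectories", {
  p <- sbe_parameters()
  traj <- simulate_sbe(params = p, months = 12, step = 1)
  for (i in c(1, 5, 13)) {
    y <- unlist(traj[i, -1])
    d <- sbe_rhs(y, p)
    dN_H <- sum(d[1:9])
    expect_equal(dN_H,
                 p$Lambda_H - p$mu_H * sum(y[1:9]) - p$delta_1 * y[["I"]] -
                   p$delta_2 * (y[["T_L"]] + y[["V_L"]]),
                 tolerance = 1e-9)
  }
})

test_that("halving the fixed integration step leaves outcomes unchanged", {
  coarse <- simulate_sbe(months = 12, step = 0.05, method = "rk4")
  fine <- simulate_sbe(months = 12, step = 0.025, method = "rk4")
  oc <- cumulative_outcomes(coarse)
  of <- cumulative_outcomes(fine)
  expect_equal(oc$cases, of$cases, tolerance = 1e-3)
  expect_equal(oc$deaths, of$deaths, tolerance = 1e-3)
  expect_equal(oc$disabilities, of$disabilities, tolerance = 1e-3)
})

test_that("cumulative deaths agree with independent quadrature of the death flow", {
  p <- sbe_parameters()
  traj <- simulate_sbe(params = p, months = 12, step = 0.05)
  flow <- p$delta_1 * traj$I + p$delta_2 * (traj$T_L + traj$V_L)
  n <- nrow(traj)
  trapz <- sum(diff(traj$time) * (flow[-n] + flow[-1]) / 2)
  deaths <- cumulative_outcomes(traj)$deaths
  expect_equal(trapz, deaths, tolerance = 1e-3)
})

test_that("outcome differencing behaves at the edges", {
  expect_equal(unlist(cumulative_outcomes(simulate_sbe(months = 0))[1:3]),
               c(cases = 0, deaths = 0, disabilities = 0))
  sc <- scenario_spec(list(epsilon = 0.5, theta = 0.5))
  av <- averted_outcomes(sc, sc)
  expect_equal(unlist(av), c(cases = 0, deaths = 0, disabilities = 0))
  sc6 <- scenario_spec(list(epsilon = 0.5, theta = 0.5), months = 6)
  expect_error(averted_outcomes(sc, sc6), "horizon")
})
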