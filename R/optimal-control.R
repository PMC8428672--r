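# Optimal control of the SBE model: minimise
#   J(u1, u2) = int_0^T ( B1 I + B2 D + (C1 u1^2 + C2 u2^2)/2 ) dt
# over admissible controls 0 <= u_i <= 1, subject to the
# time-dependent-control dynamics.  Costates follow dL/dt = -dH/dx with
# free terminal state (zero terminal costates); the solver is the classical
# fourth-order Runge-Kutta forward-backward sweep with averaging relaxation.

# RHS of the 11 model compartments only (control variant), used by the sweep.
.rhs11 <- function(y, p, u1, u2) {
  y <- pmax(y, 0)
  S_U <- y[1]; S_E <- y[2]; I <- y[3]; T_E <- y[4]; T_L <- y[5]
  V_E <- y[6]; V_L <- y[7]; R_D <- y[8]; R_W <- y[9]; N_S <- y[10]
  N_H <- S_U + S_E + I + T_E + T_L + V_E + V_L + R_D + R_W
  lam <- if (N_H + N_S > 0) p$beta * N_S / (N_H + N_S) else 0
  d2 <- (1 - u2) * p$delta_2
  c(p$Lambda_H - (lam + p$epsilon * u1 + p$mu_H) * S_U,
    p$epsilon * u1 * S_U + p$phi_1 * R_D + p$phi_2 * R_W -
      ((1 - p$theta) * lam + p$mu_H) * S_E,
    lam * ((1 - p$theta) * S_E + S_U) - (p$tau * u2 + p$delta_1 + p$mu_H) * I,
    p$tau * u2 * p$k * I - (p$alpha_1 + p$gamma_1 + p$mu_H) * T_E,
    p$tau * u2 * (1 - p$k) * I -
      (p$alpha_2 + p$sigma_1 + d2 + p$mu_H) * T_L,
    p$alpha_1 * T_E - (p$gamma_2 + p$mu_H) * V_E,
    p$alpha_2 * T_L - (p$sigma_2 + d2 + p$mu_H) * V_L,
    p$sigma_1 * p$rho_1 * T_L + p$sigma_2 * p$rho_2 * V_L -
      (p$phi_1 + p$mu_H) * R_D,
    p$gamma_1 * T_E + p$gamma_2 * V_E + p$sigma_1 * (1 - p$rho_1) * T_L +
      p$sigma_2 * (1 - p$rho_2) * V_L - (p$phi_2 + p$mu_H) * R_W,
    p$Lambda_S * N_S * (1 - N_S / p$K_S) - p$mu_S * N_S,
    p$delta_1 * I + (T_L + V_L) * d2)
}

#' Hamiltonian of the optimal-control problem
#'
#' \code{H = B1 I + B2 D + (C1 u1^2 + C2 u2^2)/2 + sum_x costate_x f_x},
#' with \code{f} the time-dependent-control right-hand sides of the 11
#' model compartments.
#'
#' @param state numeric vector, first 11 entries in canonical state order.
#' @param adjoint numeric costate vector of length 11.
#' @param u1,u2 controls in [0, 1].
#' @param weights a \code{\link{control_weights}} object.
#' @param params an \code{\link{sbe_parameters}} object.
#' @return scalar H.
#' @export
hamiltonian <- function(state, adjoint, u1, u2, weights, params) {
  y <- state[1:11]
  running <- weights$B1 * y[3] + weights$B2 * y[11] +
    0.5 * (weights$C1 * u1^2 + weights$C2 * u2^2)
  running + sum(adjoint * .rhs11(y, params, u1, u2))
}

#' Costate (adjoint) right-hand side
#'
#' Analytic gradient contract: \code{dL_x/dt = -dH/dx} for each of the 11
#' model compartments, with the force of infection treated as the
#' state-dependent function \code{beta N_S / (N_H + N_S)} (so every human
#' compartment contributes through the denominator).
#'
#' @inheritParams hamiltonian
#' @return numeric vector of costate derivatives, length 11.
#' @export
adjoint_rhs <- function(state, adjoint, u1, u2, weights, params) {
  p <- params
  y <- pmax(state[1:11], 0)
  L <- adjoint
  S_U <- y[1]; S_E <- y[2]; I <- y[3]; T_E <- y[4]; T_L <- y[5]
  V_E <- y[6]; V_L <- y[7]; R_D <- y[8]; R_W <- y[9]; N_S <- y[10]
  N_H <- S_U + S_E + I + T_E + T_L + V_E + V_L + R_D + R_W
  P <- N_H + N_S
  lam <- if (P > 0) p$beta * N_S / P else 0
  d2 <- (1 - u2) * p$delta_2
  th <- 1 - p$theta
  # dH/dlam: coefficient of the force of infection across f_SU, f_SE, f_I
  G <- (L[3] - L[1]) * S_U + th * (L[3] - L[2]) * S_E
  dlam_h <- if (P > 0) -lam / P else 0      # d lam / d(human compartment)
  dlam_s <- if (P > 0) p$beta * N_H / P^2 else 0
  dH <- c(
    -L[1] * (lam + p$epsilon * u1 + p$mu_H) + L[2] * p$epsilon * u1 +
      L[3] * lam + G * dlam_h,
    -L[2] * (th * lam + p$mu_H) + L[3] * th * lam + G * dlam_h,
    weights$B1 - L[3] * (p$tau * u2 + p$delta_1 + p$mu_H) +
      L[4] * p$tau * u2 * p$k + L[5] * p$tau * u2 * (1 - p$k) +
      L[11] * p$delta_1 + G * dlam_h,
    -L[4] * (p$alpha_1 + p$gamma_1 + p$mu_H) + L[6] * p$alpha_1 +
      L[9] * p$gamma_1 + G * dlam_h,
    -L[5] * (p$alpha_2 + p$sigma_1 + d2 + p$mu_H) + L[7] * p$alpha_2 +
      L[8] * p$sigma_1 * p$rho_1 + L[9] * p$sigma_1 * (1 - p$rho_1) +
      L[11] * d2 + G * dlam_h,
    -L[6] * (p$gamma_2 + p$mu_H) + L[9] * p$gamma_2 + G * dlam_h,
    -L[7] * (p$sigma_2 + d2 + p$mu_H) + L[8] * p$sigma_2 * p$rho_2 +
      L[9] * p$sigma_2 * (1 - p$rho_2) + L[11] * d2 + G * dlam_h,
    -L[8] * (p$phi_1 + p$mu_H) + L[2] * p$phi_1 + G * dlam_h,
    -L[9] * (p$phi_2 + p$mu_H) + L[2] * p$phi_2 + G * dlam_h,
    L[10] * (p$Lambda_S * (1 - 2 * N_S / p$K_S) - p$mu_S) + G * dlam_s,
    weights$B2
  )
  -dH
}

#' Pointwise minimisers of the Hamiltonian over the admissible box
#'
#' H is quadratic and coercive in each control, so the stationary point is
#' solved in closed form and projected onto [0, 1]:
#' \code{u1* = clamp(eps S_U (L_SU - L_SE) / C1)} and
#' \code{u2* = clamp((tau I (L_I - k L_TE - (1-k) L_TL) - delta_2 T_L L_TL -
#' delta_2 V_L L_VL + delta_2 (T_L + V_L) L_D) / C2)}.
#'
#' @inheritParams hamiltonian
#' @return numeric c(u1, u2).
#' @export
optimal_controls_pointwise <- function(state, adjoint, weights, params) {
  p <- params
  if (weights$C1 <= 0 || weights$C2 <= 0)
    stop("control cost weights must be positive")
  y <- pmax(state[1:11], 0)
  L <- adjoint
  u1 <- p$epsilon * y[1] * (L[1] - L[2]) / weights$C1
  u2 <- (p$tau * y[3] * (L[3] - p$k * L[4] - (1 - p$k) * L[5]) -
           p$delta_2 * y[5] * L[5] - p$delta_2 * y[7] * L[7] +
           p$delta_2 * (y[5] + y[7]) * L[11]) / weights$C2
  c(min(max(u1, 0), 1), min(max(u2, 0), 1))
}

#' Objective functional on a sweep grid
#'
#' Trapezoid quadrature of \code{B1 I + B2 D + (C1 u1^2 + C2 u2^2)/2} over
#' the common time grid.
#'
#' @param times time grid (months).
#' @param I,D state series on the grid.
#' @param u1,u2 control series on the grid.
#' @param weights a \code{\link{control_weights}} object.
#' @return scalar J >= 0.
#' @export
evaluate_objective <- function(times, I, D, u1, u2, weights) {
  n <- length(times)
  if (length(I) != n || length(D) != n || length(u1) != n || length(u2) != n)
    stop("grid mismatch between times, states and controls")
  f <- weights$B1 * I + weights$B2 * D +
    0.5 * (weights$C1 * u1^2 + weights$C2 * u2^2)
  sum(diff(times) * (f[-n] + f[-1]) / 2)
}

# Fixed-step RK4 forward pass of the 11-compartment control system, with
# controls linear between nodes (midpoint values averaged).
.sweep_forward <- function(init11, p, u1, u2, h, n) {
  Y <- matrix(NA_real_, n + 1, 11)
  Y[1, ] <- init11
  for (i in seq_len(n)) {
    y <- Y[i, ]
    u1m <- (u1[i] + u1[i + 1]) / 2; u2m <- (u2[i] + u2[i + 1]) / 2
    k1 <- .rhs11(y, p, u1[i], u2[i])
    k2 <- .rhs11(y + h / 2 * k1, p, u1m, u2m)
    k3 <- .rhs11(y + h / 2 * k2, p, u1m, u2m)
    k4 <- .rhs11(y + h * k3, p, u1[i + 1], u2[i + 1])
    Y[i + 1, ] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  Y
}

# RK4 backward pass of the costates from zero terminal conditions.
.sweep_backward <- function(Y, p, w, u1, u2, h, n) {
  A <- matrix(0, n + 1, 11)
  for (i in (n + 1):2) {
    L <- A[i, ]
    ym <- (Y[i, ] + Y[i - 1, ]) / 2
    u1m <- (u1[i] + u1[i - 1]) / 2; u2m <- (u2[i] + u2[i - 1]) / 2
    k1 <- adjoint_rhs(Y[i, ], L, u1[i], u2[i], w, p)
    k2 <- adjoint_rhs(ym, L - h / 2 * k1, u1m, u2m, w, p)
    k3 <- adjoint_rhs(ym, L - h / 2 * k2, u1m, u2m, w, p)
    k4 <- adjoint_rhs(Y[i - 1, ], L - h * k3, u1[i - 1], u2[i - 1], w, p)
    A[i - 1, ] <- L - h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  A
}

.rel_change <- function(new, old) {
  sum(abs(new - old)) / (sum(abs(new)) + .Machine$double.eps)
}

#' Forward-backward sweep solver for the two-control problem
#'
#' Starting from \code{u == 0}, iterates: RK4 forward integration of the
#' states, RK4 backward integration of the costates from zero terminal
#' conditions, pointwise control characterisation, and averaging relaxation
#' \code{u <- (u_prev + u_new)/2}, until the relative change of states,
#' costates and controls all fall below \code{tol}.
#'
#' @param init initial state (\code{\link{sbe_initial_state}}).
#' @param params an \code{\link{sbe_parameters}} object.
#' @param weights a \code{\link{control_weights}} object.
#' @param months horizon T in months.
#' @param strategy \code{"A"} (awareness only: u2 forced to 0), \code{"B"}
#'   (treatment only: u1 forced to 0) or \code{"C"} (both controls free).
#' @param n_steps sweep grid intervals (default 1460, a quarter-day step
#'   over 12 months).
#' @param tol relative convergence tolerance.
#' @param max_iter maximum sweep iterations; reaching it flags
#'   non-convergence instead of raising.
#' @return classed list \code{sbe_oc_solution}: \code{times}, \code{states}
#'   (matrix, 11 columns), \code{adjoints}, \code{u1}, \code{u2},
#'   \code{objective}, \code{iterations}, \code{converged}.
#' @export
forward_backward_sweep <- function(init, params, weights, months = 12,
                                   strategy = c("C", "A", "B"),
                                   n_steps = 1460, tol = 1e-4,
                                   max_iter = 200) {
  strategy <- match.arg(strategy)
  p <- params; w <- weights
  h <- months / n_steps
  times <- seq(0, months, length.out = n_steps + 1)
  init11 <- unname(init[1:11])
  u1 <- numeric(n_steps + 1); u2 <- numeric(n_steps + 1)
  Y <- .sweep_forward(init11, p, u1, u2, h, n_steps)
  A <- matrix(0, n_steps + 1, 11)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    Y_new <- .sweep_forward(init11, p, u1, u2, h, n_steps)
    A_new <- .sweep_backward(Y_new, p, w, u1, u2, h, n_steps)
    u_char <- t(vapply(seq_len(n_steps + 1), function(i)
      optimal_controls_pointwise(Y_new[i, ], A_new[i, ], w, p), numeric(2)))
    u1_new <- (u1 + u_char[, 1]) / 2
    u2_new <- (u2 + u_char[, 2]) / 2
    if (strategy == "A") u2_new[] <- 0
    if (strategy == "B") u1_new[] <- 0
    delta <- max(.rel_change(Y_new, Y), .rel_change(A_new, A),
                 .rel_change(u1_new, u1), .rel_change(u2_new, u2))
    Y <- Y_new; A <- A_new; u1 <- u1_new; u2 <- u2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  J <- evaluate_objective(times, Y[, 3], Y[, 11], u1, u2, w)
  structure(list(times = times, states = Y, adjoints = A,
                 u1 = u1, u2 = u2, objective = J,
                 iterations = iter, converged = converged,
                 strategy = strategy, params = p, weights = w,
                 init = init, months = months),
            class = "sbe_oc_solution")
}

#' Objective of a constant-control policy
#'
#' Integrates the control system under fixed \code{(u1, u2)} on the same
#' grid and evaluates the objective; used to benchmark the converged sweep
#' against corner and random constant policies.
#'
#' @inheritParams forward_backward_sweep
#' @param u1,u2 constant control values in [0, 1].
#' @return scalar J.
#' @export
constant_policy_objective <- function(init, params, weights, months = 12,
                                      u1 = 0, u2 = 0, n_steps = 1460) {
  h <- months / n_steps
  times <- seq(0, months, length.out = n_steps + 1)
  ug1 <- rep(u1, n_steps + 1); ug2 <- rep(u2, n_steps + 1)
  Y <- .sweep_forward(unname(init[1:11]), params, ug1, ug2, h, n_steps)
  evaluate_objective(times, Y[, 3], Y[, 11], ug1, ug2, weights)
}
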