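#' Force of infection (per-susceptible envenoming hazard)
#'
#' The daily/monthly hazard of envenoming per susceptible is
#' \code{beta * N_S / (N_H + N_S)}: bites are proportional to the chance
#' that an encounter involves a snake.
#'
#' @param beta effective envenomation rate (per time unit).
#' @param N_S snake count.
#' @param N_H human count.
#' @return hazard in \code{[0, beta]}, same time unit as \code{beta}.
#' @examples
#' force_of_infection(0.0742, 0, 1e6)        # no snakes, no hazard
#' force_of_infection(0.0742, 1e6, 1e6)      # half of beta
#' @export
force_of_infection <- function(beta, N_S, N_H) {
  if (beta < 0) stop("beta must be nonnegative")
  if (N_H + N_S <= 0) stop("degenerate population: N_H + N_S must be positive")
  beta * N_S / (N_H + N_S)
}

#' Right-hand side of the SBE model (R implementation)
#'
#' Evaluates the time derivative of the 18-component state (11 model
#' compartments plus 7 cumulative-flow trackers).  Two variants share the
#' implementation: the constant-control system (\code{model = "constant"},
#' where the late death rate \code{delta_2} acts unconditionally and the
#' controls default to 1) and the time-dependent-control system
#' (\code{model = "control"}, where late deaths carry a \code{(1 - u2)}
#' factor).  Used by the forward-backward sweep and as a readable reference
#' for the compiled right-hand side that \code{\link{simulate_sbe}} calls.
#'
#' @param state named or unnamed numeric vector of length 18 in canonical
#'   order (see \code{\link{sbe_initial_state}}).
#' @param params an \code{\link{sbe_parameters}} object.
#' @param u1,u2 control values in [0, 1].
#' @param model \code{"constant"} or \code{"control"}.
#' @return numeric vector of derivatives, length 18, named.
#' @export
sbe_rhs <- function(state, params, u1 = 1, u2 = 1,
                    model = c("constant", "control")) {
  model <- match.arg(model)
  if (length(state) != 18) stop("state must have 18 components")
  if (any(state[1:11] < 0)) {
    floor_tol <- -1e-9 * max(sum(state[1:9]), 1)
    if (any(state[1:11] < floor_tol))
      stop("negative state entries beyond tolerance")
    state <- pmax(state, 0)
  }
  if (u1 < 0 || u1 > 1 || u2 < 0 || u2 > 1) stop("controls must lie in [0, 1]")
  p <- params
  S_U <- state[[1]]; S_E <- state[[2]]; I <- state[[3]]
  T_E <- state[[4]]; T_L <- state[[5]]; V_E <- state[[6]]; V_L <- state[[7]]
  R_D <- state[[8]]; R_W <- state[[9]]; N_S <- state[[10]]

  N_H <- S_U + S_E + I + T_E + T_L + V_E + V_L + R_D + R_W
  lam <- if (N_H + N_S > 0) p$beta * N_S / (N_H + N_S) else 0
  d2 <- if (model == "control") (1 - u2) * p$delta_2 else p$delta_2

  inc   <- lam * ((1 - p$theta) * S_E + S_U)
  to_TE <- p$tau * u2 * p$k * I
  to_TL <- p$tau * u2 * (1 - p$k) * I
  to_VE <- p$alpha_1 * T_E
  to_VL <- p$alpha_2 * T_L
  to_RD <- p$sigma_1 * p$rho_1 * T_L + p$sigma_2 * p$rho_2 * V_L
  to_RW <- p$gamma_1 * T_E + p$gamma_2 * V_E +
    p$sigma_1 * (1 - p$rho_1) * T_L + p$sigma_2 * (1 - p$rho_2) * V_L

  d <- c(
    p$Lambda_H - (lam + p$epsilon * u1 + p$mu_H) * S_U,
    p$epsilon * u1 * S_U + p$phi_1 * R_D + p$phi_2 * R_W -
      ((1 - p$theta) * lam + p$mu_H) * S_E,
    inc - (p$tau * u2 + p$delta_1 + p$mu_H) * I,
    to_TE - (p$alpha_1 + p$gamma_1 + p$mu_H) * T_E,
    to_TL - (p$alpha_2 + p$sigma_1 + d2 + p$mu_H) * T_L,
    to_VE - (p$gamma_2 + p$mu_H) * V_E,
    to_VL - (p$sigma_2 + d2 + p$mu_H) * V_L,
    to_RD - (p$phi_1 + p$mu_H) * R_D,
    to_RW - (p$phi_2 + p$mu_H) * R_W,
    p$Lambda_S * N_S * (1 - N_S / p$K_S) - p$mu_S * N_S,
    p$delta_1 * I + (T_L + V_L) * d2,
    inc, to_TE, to_TL, to_VE, to_VL, to_RD, to_RW
  )
  names(d) <- .all_state_names
  d
}

#' Scenario specification for a model run
#'
#' Bundles parameter overrides, initial conditions, horizon and frozen
#' control values.  The constant-control system is run with
#' \code{u1 = u2 = 1}.
#'
#' @param overrides named list of parameter overrides (e.g.
#'   \code{list(epsilon = 0.5, theta = 0.5)}).
#' @param init initial state from \code{\link{sbe_initial_state}}.
#' @param months horizon in months (> 0 unless evaluating the initial
#'   instant only).
#' @param u1,u2 frozen controls in [0, 1].
#' @param model \code{"constant"} or \code{"control"}.
#' @param params base parameters to override.
#' @return classed list \code{sbe_scenario}.
#' @export
scenario_spec <- function(overrides = list(), init = sbe_initial_state(),
                          months = 12, u1 = 1, u2 = 1,
                          model = c("constant", "control"),
                          params = sbe_parameters()) {
  model <- match.arg(model)
  if (months < 0) stop("horizon must be nonnegative")
  if (length(overrides)) {
    bad <- setdiff(names(overrides), .param_names)
    if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
    params <- validate_parameters(modifyList(unclass(params), overrides))
    class(params) <- "sbe_parameters"
  }
  structure(list(params = params, init = init, months = months,
                 u1 = u1, u2 = u2, model = model),
            class = "sbe_scenario")
}

.parms_vector <- function(params, u1, u2, model) {
  c(unlist(params[.param_names], use.names = FALSE), u1, u2,
    as.numeric(model == "control"))
}

#' Simulate the SBE model
#'
#' Integrates the 18-component system with the compiled right-hand side.
#' Scenario runs use the adaptive \code{lsoda} solver (relative tolerance
#' 1e-8); a fixed-step classical Runge-Kutta is available for cross-checks.
#'
#' @param spec an \code{\link{scenario_spec}}; or leave \code{NULL} and pass
#'   the pieces directly.
#' @param params,init,months,u1,u2,model used when \code{spec} is NULL.
#' @param step output grid spacing in months.
#' @param method \code{"lsoda"} (adaptive, default) or \code{"rk4"}.
#' @return an \code{sbe_trajectory}: data.frame with \code{time} and the 18
#'   state columns, the scenario attached as attribute \code{"scenario"}.
#' @examples
#' traj <- simulate_sbe(months = 2)
#' tail(traj, 1)$C_inc
#' @export
simulate_sbe <- function(spec = NULL, params = sbe_parameters(),
                         init = sbe_initial_state(), months = 12,
                         u1 = 1, u2 = 1, model = c("constant", "control"),
                         step = 0.05, method = c("lsoda", "rk4")) {
  method <- match.arg(method)
  if (is.null(spec)) {
    model <- match.arg(model)
    spec <- scenario_spec(list(), init, months, u1, u2, model, params)
  }
  if (any(spec$init < 0)) stop("initial conditions must be nonnegative")
  times <- unique(c(seq(0, spec$months, by = step), spec$months))
  if (length(times) < 2) times <- c(0, max(spec$months, step * 1e-6))
  parms <- .parms_vector(spec$params, spec$u1, spec$u2, spec$model)
  out <- deSolve::ode(y = unname(spec$init), times = times,
                      func = "sbe_derivs", parms = parms,
                      dllname = "sbecontrol", initfunc = "sbe_initmod",
                      method = if (method == "lsoda") "lsoda" else "rk4",
                      rtol = 1e-8, atol = 1e-6)
  if (attr(out, "istate")[1] < 0) stop("ODE solver failed to converge")
  out <- as.data.frame(out)
  names(out) <- c("time", .all_state_names)
  floor_tol <- -1e-8 * max(sum(spec$init[1:9]), 1)
  if (min(as.matrix(out[, 2:12])) < floor_tol)
    stop("state invariant violated: negative excursion beyond tolerance")
  out[, 2:19] <- pmax(as.matrix(out[, 2:19]), 0)
  if (spec$months == 0) out <- out[1, , drop = FALSE]
  structure(out, scenario = spec, class = c("sbe_trajectory", "data.frame"))
}

#' Cumulative epidemiological outcomes of a trajectory
#'
#' @param traj an \code{sbe_trajectory}.
#' @return list with \code{cases} (new envenomings), \code{deaths},
#'   \code{disabilities} (recoveries with disability) accrued over the run,
#'   and \code{curves}, the per-series cumulative columns.
#' @export
cumulative_outcomes <- function(traj) {
  first <- traj[1, ]
  last <- traj[nrow(traj), ]
  list(cases = last$C_inc - first$C_inc,
       deaths = last$D - first$D,
       disabilities = last$C_RD - first$C_RD,
       curves = traj[, c("time", "C_inc", "C_TE", "C_TL", "C_VE", "C_VL",
                         "C_RD", "C_RW", "D")])
}

#' Outcomes averted by an intervention scenario
#'
#' Element-wise difference (baseline minus intervention) of
#' \code{\link{cumulative_outcomes}}.  The baseline is the matching
#' zero-control scenario: \code{epsilon = theta = 0} for awareness
#' interventions, \code{k = 0} for early-treatment interventions.
#'
#' @param intervention,baseline \code{\link{scenario_spec}} objects sharing
#'   initial conditions and horizon.
#' @return list with \code{cases}, \code{deaths}, \code{disabilities}
#'   averted.
#' @export
averted_outcomes <- function(intervention, baseline) {
  if (!isTRUE(all.equal(intervention$months, baseline$months)))
    stop("scenarios must share the same horizon")
  if (!isTRUE(all.equal(intervention$init, baseline$init)))
    stop("scenarios must share initial conditions")
  a <- cumulative_outcomes(simulate_sbe(intervention))
  b <- cumulative_outcomes(simulate_sbe(baseline))
  list(cases = b$cases - a$cases,
       deaths = b$deaths - a$deaths,
       disabilities = b$disabilities - a$disabilities)
}

#' Awareness-campaign scenario pair
#'
#' Builds the intervention scenario with campaign coverage and efficacy both
#' at \code{level} and the corresponding 0\%-awareness baseline.
#'
#' @param level awareness coverage and efficacy (0 to 1).
#' @param months horizon in months.
#' @param params base parameters.
#' @param init initial state.
#' @return list with elements \code{intervention} and \code{baseline}.
#' @export
awareness_scenario <- function(level, months = 12, params = sbe_parameters(),
                               init = sbe_initial_state()) {
  list(intervention = scenario_spec(list(epsilon = level, theta = level),
                                    init, months, params = params),
       baseline = scenario_spec(list(epsilon = 0, theta = 0),
                                init, months, params = params))
}

#' Early-treatment scenario pair
#'
#' Intervention with proportion \code{level} of treated patients treated
#' early, against the 0\%-early-treatment baseline (\code{k = 0}).
#'
#' @inheritParams awareness_scenario
#' @param level proportion treated early (0 to 1).
#' @return list with elements \code{intervention} and \code{baseline}.
#' @export
early_treatment_scenario <- function(level, months = 12,
                                     params = sbe_parameters(),
                                     init = sbe_initial_state()) {
  list(intervention = scenario_spec(list(k = level), init, months,
                                    params = params),
       baseline = scenario_spec(list(k = 0), init, months, params = params))
}
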