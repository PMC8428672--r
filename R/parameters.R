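#' sbecontrol: snakebite envenoming transmission and control modelling
#'
#' Compartmental human-snake dynamics of snakebite envenoming (SBE) with
#' awareness and antivenom-treatment interventions, calibration to monthly
#' cumulative surveillance series, Pontryagin optimal control via the
#' forward-backward sweep, and cost-effectiveness analysis (ICER, DALY,
#' GDP-per-capita thresholds).
#'
#' @useDynLib sbecontrol, .registration = TRUE
#' @importFrom stats optim runif rnorm rpois var quantile setNames approx
#' @importFrom utils read.csv write.csv modifyList
#' @keywords internal
"_PACKAGE"

# Days per calendar month under an annualised convention.
DAYS_PER_MONTH <- 365 / 12

#' Convert a per-day rate to a per-month rate
#'
#' The model is integrated with the month as time unit; demographic rates
#' derived from life expectancies (per day) are converted with a 365/12-day
#' month.
#'
#' @param rate_per_day numeric rate in day^-1.
#' @return rate in month^-1.
#' @export
per_day_to_per_month <- function(rate_per_day) rate_per_day * DAYS_PER_MONTH

.param_names <- c(
  "Lambda_H", "Lambda_S", "mu_H", "mu_S", "beta", "epsilon", "theta",
  "tau", "k", "delta_1", "delta_2", "alpha_1", "alpha_2",
  "gamma_1", "gamma_2", "sigma_1", "sigma_2", "rho_1", "rho_2",
  "phi_1", "phi_2", "K_S"
)

.proportion_names <- c("theta", "k", "rho_1", "rho_2")

#' Model parameters for the SBE transmission model
#'
#' Constructs the full rate/proportion parameter set of the human-snake
#' model.  All rates are per month (the model's time unit); proportions are
#' dimensionless in [0, 1].  Defaults are the fitted estimates for northeast
#' Nigeria: transmission, treatment and recovery rates taken at face value
#' per month, and the demographic rates (\code{Lambda_H}, \code{mu_H},
#' \code{mu_S}) derived from life-expectancy arithmetic in days and converted
#' with \code{\link{per_day_to_per_month}}.
#'
#' @param Lambda_H recruitment of unaware susceptibles (persons/month).
#' @param Lambda_S intrinsic snake population growth rate (1/month).
#' @param mu_H,mu_S natural mortality rates of humans and snakes (1/month).
#' @param beta effective envenomation rate (1/month).
#' @param epsilon awareness-campaign coverage rate (1/month).
#' @param theta awareness efficacy, fraction of the envenoming hazard removed
#'   for aware susceptibles.
#' @param tau antivenom treatment rate of envenomed individuals (1/month).
#' @param k proportion of treated individuals treated early (within 24 h).
#' @param delta_1,delta_2 SBE-induced death rates in the envenomed and the
#'   late-treatment/late-reaction compartments (1/month).
#' @param alpha_1,alpha_2 early-adverse-reaction (EAR) rates during early and
#'   late treatment (1/month).
#' @param gamma_1,gamma_2 recovery-without-disability rates from early
#'   treatment and early-treatment EAR (1/month).
#' @param sigma_1,sigma_2 recovery rates from late treatment and late-treatment
#'   EAR (1/month); a fraction \code{rho_1}/\code{rho_2} of these recover with
#'   disability.
#' @param rho_1,rho_2 proportions recovering with disability.
#' @param phi_1,phi_2 return rates from the recovered classes to the aware
#'   susceptible class (1/month).
#' @param K_S snake carrying capacity (snakes).
#' @param ... overrides collected into the parameter list; unknown names are
#'   an error.
#' @return an object of class \code{sbe_parameters} (named list).
#' @examples
#' p <- sbe_parameters()
#' p$beta
#' sbe_parameters(epsilon = 0.5, theta = 0.5)$theta
#' @export
sbe_parameters <- function(Lambda_H = per_day_to_per_month(1324),
                           Lambda_S = 0.1925,
                           mu_H = per_day_to_per_month(5.0426e-05),
                           mu_S = per_day_to_per_month(2.283e-04),
                           beta = 0.0742,
                           epsilon = 0.0051,
                           theta = 1.7729e-04,
                           tau = 0.9997,
                           k = 0.8073,
                           delta_1 = 0.0025,
                           delta_2 = 4.2564e-04,
                           alpha_1 = 0.1215,
                           alpha_2 = 0.1708,
                           gamma_1 = 0.9310,
                           gamma_2 = 0.9310,
                           sigma_1 = 0.9924,
                           sigma_2 = 0.9924,
                           rho_1 = 0.1500,
                           rho_2 = 0.9985,
                           phi_1 = 0.5233,
                           phi_2 = 0.9416,
                           K_S = 6.6604e04,
                           ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown parameter(s): ", paste(names(extra), collapse = ", "))
  p <- mget(.param_names)
  structure(validate_parameters(p), class = "sbe_parameters")
}

#' Validate an SBE parameter set
#'
#' Checks completeness, nonnegativity of all rates and the [0, 1] range of
#' the proportions \code{theta}, \code{k}, \code{rho_1}, \code{rho_2}.
#'
#' @param p named list of parameters.
#' @return the validated list, invisibly classed.
#' @export
validate_parameters <- function(p) {
  missing <- setdiff(.param_names, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(p), .param_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- p[.param_names]
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("non-finite parameter value")
  if (any(vals < 0))
    stop("negative parameter(s): ",
         paste(names(vals)[vals < 0], collapse = ", "))
  bad <- .proportion_names[unlist(p[.proportion_names]) > 1]
  if (length(bad))
    stop("proportion(s) above 1: ", paste(bad, collapse = ", "))
  if (p$K_S <= 0) stop("K_S must be positive")
  p
}

#' Derived rate aggregates of the constant-control model
#'
#' Total outflow rates K1-K9 of each human compartment and the complement
#' proportions Pi1-Pi4.  In the constant-control model the late compartments'
#' outflows K5 and K7 include the late death rate \code{delta_2}.
#'
#' @param p an \code{\link{sbe_parameters}} object.
#' @return named numeric vector K1..K9, Pi_1..Pi_4.
#' @export
derived_rates <- function(p) {
  with(p, c(
    K1 = epsilon + mu_H,
    K2 = mu_H,
    K3 = tau + delta_1 + mu_H,
    K4 = alpha_1 + gamma_1 + mu_H,
    K5 = alpha_2 + sigma_1 + delta_2 + mu_H,
    K6 = gamma_2 + mu_H,
    K7 = sigma_2 + delta_2 + mu_H,
    K8 = phi_1 + mu_H,
    K9 = phi_2 + mu_H,
    Pi_1 = 1 - theta,
    Pi_2 = 1 - k,
    Pi_3 = 1 - rho_1,
    Pi_4 = 1 - rho_2
  ))
}

#' Demographic rates from life expectancy and population size
#'
#' Natural mortality is the reciprocal of life expectancy; recruitment
#' balances mortality at the stated population size.  Both are returned per
#' day, the unit in which the demographic inputs are quoted.
#'
#' @param life_expectancy_years life expectancy in years (> 0).
#' @param population population size (> 0).
#' @return list with \code{mu} (1/day) and \code{Lambda} (persons/day).
#' @examples
#' demographic_params(54.332, 26263866)  # Lambda ~ 1324/day
#' @export
demographic_params <- function(life_expectancy_years, population) {
  if (life_expectancy_years <= 0) stop("life expectancy must be positive")
  if (population <= 0) stop("population must be positive")
  mu <- 1 / (life_expectancy_years * 365)
  list(mu = mu, Lambda = population * mu)
}

.state_names <- c("S_U", "S_E", "I", "T_E", "T_L", "V_E", "V_L",
                  "R_D", "R_W", "N_S", "D")
.tracker_names <- c("C_inc", "C_TE", "C_TL", "C_VE", "C_VL", "C_RD", "C_RW")
.all_state_names <- c(.state_names, .tracker_names)

#' Initial state of the SBE model
#'
#' Builds the full 18-component state: the 11 model compartments plus the
#' seven cumulative-flow trackers used to read off the monthly surveillance
#' series.  Trackers start at the reported initial cumulative counts, i.e.
#' at the matching compartment's initial value, so model-implied report
#' curves line up with registry tables at month 0.
#'
#' Defaults are the fitted/reported initial conditions for the northeast
#' Nigeria registry (January 2019).
#'
#' @param S_U,S_E unaware / aware susceptibles.
#' @param I envenomed individuals.
#' @param T_E,T_L individuals under early / late antivenom treatment.
#' @param V_E,V_L individuals with early adverse reactions during early /
#'   late treatment.
#' @param R_D,R_W recovered with / without disability.
#' @param N_S snakes.
#' @param D cumulative SBE deaths.
#' @return named numeric vector of length 18.
#' @export
sbe_initial_state <- function(S_U = 2.1459e07, S_E = 6.5132e03, I = 99,
                              T_E = 76, T_L = 7, V_E = 8, V_L = 0,
                              R_D = 4, R_W = 93, N_S = 1.2250e04, D = 2) {
  y <- c(S_U = S_U, S_E = S_E, I = I, T_E = T_E, T_L = T_L,
         V_E = V_E, V_L = V_L, R_D = R_D, R_W = R_W, N_S = N_S, D = D,
         C_inc = I, C_TE = T_E, C_TL = T_L, C_VE = V_E, C_VL = V_L,
         C_RD = R_D, C_RW = R_W)
  if (any(!is.finite(y)) || any(y < 0))
    stop("initial state must be finite and nonnegative")
  y
}

#' Objective and control-cost weights of the optimal-control problem
#'
#' @param B1,B2 state weights on the envenomed prevalence I(t) and on the
#'   cumulative deaths D(t) in the running cost.
#' @param C1,C2 quadratic cost weights for the awareness control u1 and the
#'   treatment control u2 (US$-scaled); must be positive so the Hamiltonian
#'   is coercive in the controls.
#' @return classed list \code{sbe_weights}.
#' @export
control_weights <- function(B1 = 1, B2 = 1, C1 = 0.28, C2 = 237) {
  if (min(B1, B2) < 0) stop("state weights must be nonnegative")
  if (min(C1, C2) <= 0) stop("control cost weights must be positive")
  structure(list(B1 = B1, B2 = B2, C1 = C1, C2 = C2), class = "sbe_weights")
}
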