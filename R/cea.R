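#' Configuration of the cost-effectiveness analysis
#'
#' @param discount_rate annual discount rate (default 5\%), converted to a
#'   per-month rate inside the discounted-cost integral.
#' @param daly_per_death discounted DALYs per premature SBE death
#'   (default 23.41).
#' @param gdp_per_capita per-capita GDP in US$ used for the
#'   cost-effectiveness thresholds (default 2,229.9, Nigeria 2019).
#' @param c1 unit cost of educating one susceptible (US$/person).
#' @param c2 unit cost of one antivenom treatment (US$/treatment).
#' @param cost_model \code{"as-printed"} integrates the published cost
#'   integrand exactly, including the bare adverse-reaction terms
#'   \code{alpha_1 V_E + alpha_2 V_L} (unit management cost of 1 US$ per
#'   person-month) and the \code{tau (k T_E + (1-k) T_L)} treatment
#'   grouping; \code{"inflow"} instead costs the treatment inflow
#'   \code{C2 u2 tau I}.
#' @return classed list \code{sbe_cea_config}.
#' @export
cea_config <- function(discount_rate = 0.05, daly_per_death = 23.41,
                       gdp_per_capita = 2229.9, c1 = 0.28, c2 = 237,
                       cost_model = c("as-printed", "inflow")) {
  cost_model <- match.arg(cost_model)
  if (discount_rate < 0) stop("discount rate must be nonnegative")
  if (daly_per_death <= 0) stop("DALY factor must be positive")
  if (gdp_per_capita <= 0) stop("GDP per capita must be positive")
  structure(list(discount_rate = discount_rate,
                 daly_per_death = daly_per_death,
                 gdp_per_capita = gdp_per_capita,
                 c1 = c1, c2 = c2, cost_model = cost_model),
            class = "sbe_cea_config")
}

#' Discounted implementation cost of a control schedule
#'
#' Trapezoid quadrature of the discounted cost integrand
#' \code{(C1 u1 eps S_U + C2 u2 (k T_E + (1-k) T_L) tau + alpha_1 V_E +
#' alpha_2 V_L) exp(-r t)} over the solution grid, with the annual discount
#' rate converted to per month.
#'
#' @param sol an \code{sbe_oc_solution} from
#'   \code{\link{forward_backward_sweep}}, or any list with \code{times},
#'   \code{states} (matrix with canonical first 11 columns), \code{u1},
#'   \code{u2}.
#' @param config a \code{\link{cea_config}}.
#' @param params an \code{\link{sbe_parameters}} object.
#' @return discounted cost in US$ (>= 0).
#' @export
discounted_control_cost <- function(sol, config, params) {
  p <- params
  times <- sol$times
  n <- length(times)
  if (nrow(sol$states) != n || length(sol$u1) != n || length(sol$u2) != n)
    stop("grid mismatch between states and controls")
  S_U <- sol$states[, 1]; I <- sol$states[, 3]
  T_E <- sol$states[, 4]; T_L <- sol$states[, 5]
  V_E <- sol$states[, 6]; V_L <- sol$states[, 7]
  r_month <- config$discount_rate / 12
  treat <- if (config$cost_model == "inflow") {
    config$c2 * sol$u2 * p$tau * I
  } else {
    config$c2 * sol$u2 * (p$k * T_E + (1 - p$k) * T_L) * p$tau
  }
  f <- (config$c1 * sol$u1 * p$epsilon * S_U + treat +
          p$alpha_1 * V_E + p$alpha_2 * V_L) * exp(-r_month * times)
  sum(diff(times) * (f[-n] + f[-1]) / 2)
}

#' Itemised awareness-campaign budget (broadcast media)
#'
#' The packaged line items for radio/TV jingle production and airing across
#' the six-state study region.
#'
#' @return data.frame with \code{activity}, \code{resource}, \code{amount}
#'   (US$).
#' @export
awareness_cost_items <- function() {
  path <- system.file("extdata", "awareness_costs.csv",
                      package = "sbecontrol", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Bulk-SMS campaign parameters
#'
#' @return list with \code{unit_cost} (US$/SMS), \code{population_reached},
#'   \code{messages_per_month}, \code{months}.
#' @export
sms_campaign <- function() {
  list(unit_cost = 0.0051, population_reached = 14069290.38,
       messages_per_month = 8, months = 12)
}

#' Total and per-capita awareness budget
#'
#' Sums the broadcast line items and the SMS campaign
#' (\code{unit_cost x population_reached x messages_per_month x months}),
#' then divides by the covered population.  Monetary outputs are rounded to
#' cents.
#'
#' @param items broadcast cost line items (data.frame with \code{amount}).
#' @param sms SMS campaign parameters (\code{\link{sms_campaign}}) or NULL.
#' @param population population of the covered area (> 0).
#' @return list with \code{broadcast}, \code{sms}, \code{total},
#'   \code{per_capita} (all US$).
#' @export
awareness_budget <- function(items = awareness_cost_items(),
                             sms = sms_campaign(),
                             population = 26263866) {
  if (population <= 0) stop("population must be positive")
  if (!is.null(items) && any(items$amount < 0))
    stop("cost amounts must be nonnegative")
  broadcast <- if (is.null(items) || !nrow(items)) 0 else sum(items$amount)
  sms_total <- if (is.null(sms)) 0 else
    sms$unit_cost * sms$population_reached * sms$messages_per_month *
      sms$months
  total <- round(broadcast + sms_total, 2)
  list(broadcast = round(broadcast, 2), sms = round(sms_total, 2),
       total = total, per_capita = round(total / population, 2))
}

#' Convert deaths averted to DALYs averted
#'
#' One premature SBE death is equivalent to \code{daly_per_death}
#' discounted disability-adjusted life years (default 23.41).
#'
#' @param deaths deaths averted (>= 0).
#' @param config a \code{\link{cea_config}}.
#' @return DALYs averted.
#' @examples
#' deaths_to_daly(117)  # ~2,739 DALYs
#' @export
deaths_to_daly <- function(deaths, config = cea_config()) {
  if (any(deaths < 0)) stop("deaths must be nonnegative")
  deaths * config$daly_per_death
}

#' Sequential ICER table and dominance walk
#'
#' Computes the incremental cost-effectiveness ratio table for competing
#' strategies in their given order: the first strategy's ICER is its
#' absolute cost-effectiveness ratio, each later one is incremental against
#' its predecessor in the current list.  Any strategy whose incremental ICER
#' exceeds its predecessor's reference ICER is dominated; it is removed and
#' the table recomputed until stable.  The recommended strategy is the
#' retained one with the lowest final ICER among those under the
#' cost-effectiveness threshold (3x GDP per capita).
#'
#' @param outcomes data.frame with columns \code{strategy}, \code{effect}
#'   (deaths or DALYs averted) and \code{cost} (US$).
#' @param config a \code{\link{cea_config}}.
#' @return list with \code{steps} (list of ICER tables, one per
#'   elimination round), \code{final} (last table), \code{dominated}
#'   (character), \code{recommended} (character), and \code{classification}
#'   of the recommended ICER.
#' @export
icer_analysis <- function(outcomes, config = cea_config()) {
  if (nrow(outcomes) < 2) stop("need at least two strategies")
  if (anyDuplicated(outcomes$strategy)) stop("duplicate strategy names")
  tied <- duplicated(outcomes$effect) | duplicated(outcomes$effect,
                                                   fromLast = TRUE)
  if (any(tied)) {
    # tie on effect: keep the cheaper strategy
    keep <- !logical(nrow(outcomes))
    for (e in unique(outcomes$effect[tied])) {
      idx <- which(outcomes$effect == e)
      keep[setdiff(idx, idx[which.min(outcomes$cost[idx])])] <- FALSE
    }
    message("tied effects: dropping ",
            paste(outcomes$strategy[!keep], collapse = ", "),
            " (higher cost at equal effect)")
    outcomes <- outcomes[keep, , drop = FALSE]
  }
  icer_table <- function(df) {
    icer <- numeric(nrow(df))
    icer[1] <- df$cost[1] / df$effect[1]
    if (nrow(df) > 1)
      for (i in 2:nrow(df))
        icer[i] <- (df$cost[i] - df$cost[i - 1]) /
          (df$effect[i] - df$effect[i - 1])
    df$icer <- icer
    df
  }
  current <- outcomes
  steps <- list()
  dominated <- character(0)
  repeat {
    tab <- icer_table(current)
    steps[[length(steps) + 1]] <- tab
    if (nrow(tab) == 1) break
    drop <- NULL
    for (i in 2:nrow(tab)) {
      de <- tab$effect[i] - tab$effect[i - 1]
      dc <- tab$cost[i] - tab$cost[i - 1]
      if (de > 0 && dc <= 0) { drop <- i - 1; break }   # strongly dominated
      if (de <= 0 && dc >= 0) { drop <- i; break }      # strongly dominated
      if (tab$icer[i] > tab$icer[i - 1]) { drop <- i; break }
    }
    if (is.null(drop)) break
    dominated <- c(dominated, tab$strategy[drop])
    current <- current[current$strategy != tab$strategy[drop], ,
                       drop = FALSE]
  }
  final <- steps[[length(steps)]]
  affordable <- final$icer < 3 * config$gdp_per_capita
  cand <- if (any(affordable)) final[affordable, ] else final
  recommended <- cand$strategy[which.min(cand$icer)]
  list(steps = steps, final = final, dominated = dominated,
       recommended = recommended,
       classification = gdp_classify(final$icer[final$strategy ==
                                                  recommended], config))
}

#' Cost-effectiveness frontier (extended dominance)
#'
#' The standard frontier: strategies sorted by effect, strongly dominated
#' ones (costlier and no more effective) removed, then extended dominance
#' applied until incremental ICERs increase along the frontier (every
#' retained point lies on the lower convex hull of (effect, cost) anchored
#' at the do-nothing origin).
#'
#' @param outcomes data.frame with \code{strategy}, \code{effect},
#'   \code{cost}.
#' @return the frontier subset with incremental ICERs, ordered by effect.
#' @export
ce_frontier <- function(outcomes) {
  df <- outcomes[order(outcomes$effect, outcomes$cost), , drop = FALSE]
  # strong dominance: higher (or equal) cost with no more effect
  keep <- rep(TRUE, nrow(df))
  best <- Inf
  for (i in rev(seq_len(nrow(df)))) {
    if (df$cost[i] >= best) keep[i] <- FALSE else best <- df$cost[i]
  }
  df <- df[keep, , drop = FALSE]
  # extended dominance: enforce increasing incremental ICERs from (0, 0)
  repeat {
    eff <- c(0, df$effect); cost <- c(0, df$cost)
    icer <- diff(cost) / diff(eff)
    drop <- which(diff(icer) < 0)
    if (!length(drop)) break
    df <- df[-drop[1], , drop = FALSE]
  }
  eff <- c(0, df$effect); cost <- c(0, df$cost)
  df$icer <- diff(cost) / diff(eff)
  rownames(df) <- NULL
  df
}

#' Classify an ICER against GDP-per-capita thresholds
#'
#' Highly cost-effective below 1x GDP per capita, cost-effective from 1x up
#' to (but excluding) 3x, not cost-effective at or above 3x.
#'
#' @param icer incremental cost-effectiveness ratio (US$ per unit effect).
#' @param config a \code{\link{cea_config}}.
#' @return one of \code{"highly cost-effective"}, \code{"cost-effective"},
#'   \code{"not cost-effective"}.
#' @export
gdp_classify <- function(icer, config = cea_config()) {
  if (icer < 0) stop("icer must be nonnegative")
  gdp <- config$gdp_per_capita
  if (icer < gdp) "highly cost-effective"
  else if (icer < 3 * gdp) "cost-effective"
  else "not cost-effective"
}

#' Budget required to avert an observed death toll
#'
#' Scales a cost-per-death-averted ratio by an observed death count,
#' rounded to whole dollars: the budget that would have averted the deaths
#' actually recorded.
#'
#' @param icer US$ per death averted (>= 0).
#' @param observed_deaths observed deaths (>= 0).
#' @return US$ (whole dollars).
#' @examples
#' scale_cost_to_observed(620.07, 117)  # 72,548
#' @export
scale_cost_to_observed <- function(icer, observed_deaths) {
  if (icer < 0 || observed_deaths < 0) stop("inputs must be nonnegative")
  # commercial rounding (half away from zero), as in the published figures
  floor(icer * observed_deaths + 0.5)
}

#' Outcomes and discounted costs of the optimal-control strategies
#'
#' Solves the forward-backward sweep for each requested strategy, differences
#' cumulative deaths against the uncontrolled (u = 0) run over the same
#' horizon, and attaches the discounted implementation cost.
#'
#' @param strategies character subset of \code{c("A", "B", "C")}.
#' @param params an \code{\link{sbe_parameters}} object (the published
#'   optimal-control scenario uses \code{sigma_1 = sigma_2 = 0.45},
#'   \code{epsilon = theta = 0.65}, \code{k = 0.55}).
#' @param init initial state.
#' @param weights a \code{\link{control_weights}}.
#' @param config a \code{\link{cea_config}}.
#' @param months horizon in months.
#' @param n_steps sweep grid intervals.
#' @param ... passed to \code{\link{forward_backward_sweep}}.
#' @return list with \code{outcomes} (data.frame strategy/effect/cost, where
#'   effect is deaths averted) and \code{solutions} (the sweep solutions).
#' @export
strategy_outcomes <- function(strategies = c("A", "B", "C"),
                              params = oc_scenario_parameters(),
                              init = sbe_initial_state(),
                              weights = control_weights(),
                              config = cea_config(), months = 12,
                              n_steps = 1460, ...) {
  base_Y <- .sweep_forward(unname(init[1:11]), params,
                           rep(0, n_steps + 1), rep(0, n_steps + 1),
                           months / n_steps, n_steps)
  base_deaths <- base_Y[n_steps + 1, 11] - base_Y[1, 11]
  sols <- lapply(strategies, function(s)
    forward_backward_sweep(init, params, weights, months, strategy = s,
                           n_steps = n_steps, ...))
  names(sols) <- strategies
  effect <- vapply(sols, function(sol)
    base_deaths - (sol$states[n_steps + 1, 11] - sol$states[1, 11]),
    numeric(1))
  cost <- vapply(sols, discounted_control_cost, numeric(1),
                 config = config, params = params)
  list(outcomes = data.frame(strategy = strategies, effect = effect,
                             cost = cost, row.names = NULL),
       solutions = sols)
}

#' Parameters of the published optimal-control scenario
#'
#' Baseline estimates with the scenario overrides
#' \code{sigma_1 = sigma_2 = 0.45}, \code{epsilon = theta = 0.65},
#' \code{k = 0.55}.
#'
#' @param ... further overrides.
#' @return an \code{\link{sbe_parameters}} object.
#' @export
oc_scenario_parameters <- function(...) {
  sbe_parameters(sigma_1 = 0.45, sigma_2 = 0.45, epsilon = 0.65,
                 theta = 0.65, k = 0.55, ...)
}
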