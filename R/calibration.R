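.report_series <- c("envenomings", "early_treatment", "late_treatment",
                    "ear_early", "ear_late", "recovered_disability",
                    "recovered_no_disability", "deaths")
.series_trackers <- c("C_inc", "C_TE", "C_TL", "C_VE", "C_VL",
                      "C_RD", "C_RW", "D")

#' Validate a monthly cumulative report table
#'
#' A report table holds the eight cumulative surveillance series (new
#' envenomings, early/late treatment starts, adverse reactions during
#' early/late treatment, recoveries with/without disability, deaths) at
#' month boundaries 0..M.  Each series must be nonnegative and nondecreasing.
#'
#' @param x data.frame with columns \code{month} and the eight series.
#' @return \code{x}, invisibly, or an error.
#' @export
validate_report_table <- function(x) {
  need <- c("month", .report_series)
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("report table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(x) < 3) stop("report table needs at least months 0..2")
  if (is.unsorted(x$month, strictly = TRUE)) stop("months must be increasing")
  for (s in .report_series) {
    v <- x[[s]]
    if (any(v < 0)) stop("negative counts in series ", s)
    if (is.unsorted(v)) stop("series ", s, " must be nondecreasing")
  }
  invisible(x)
}

#' Model-implied monthly cumulative report curves
#'
#' Integrates the constant-control model and reads the cumulative-flow
#' trackers at month boundaries.  Because trackers are initialised at the
#' reported initial cumulative counts (\code{\link{sbe_initial_state}}),
#' the month-0 row equals the registry's starting values.
#'
#' @param params an \code{\link{sbe_parameters}} object.
#' @param init initial state.
#' @param months number of months (table covers months 0..months).
#' @return report table data.frame (months + the 8 series).
#' @export
model_report_curves <- function(params, init = sbe_initial_state(),
                                months = 21) {
  if (months == 0) {
    out <- data.frame(month = 0, t(init[.series_trackers]))
    names(out) <- c("month", .report_series)
    return(out)
  }
  traj <- simulate_sbe(params = params, init = init, months = months,
                       step = 1)
  rows <- match(0:months, traj$time)
  out <- data.frame(month = 0:months,
                    traj[rows, .series_trackers, drop = FALSE])
  names(out) <- c("month", .report_series)
  rownames(out) <- NULL
  out
}

#' Weighted sum of squared residuals between two report tables
#'
#' @param model,data report tables on identical month grids.
#' @param weights per-series weights, named or in series order; default 1.
#' @return scalar objective, zero iff the tables agree (positive weights).
#' @export
sum_squared_residuals <- function(model, data,
                                  weights = rep(1, length(.report_series))) {
  if (!isTRUE(all.equal(model$month, data$month)))
    stop("month grids differ between model and data")
  if (is.null(names(weights))) names(weights) <- .report_series
  total <- 0
  for (s in .report_series)
    total <- total + weights[[s]] * sum((model[[s]] - data[[s]])^2)
  total
}

# Per-series residual sums, used by the profiled Gaussian MCMC kernel.
.series_ssr <- function(model, data) {
  vapply(.report_series,
         function(s) sum((model[[s]] - data[[s]])^2), numeric(1))
}

#' Specification of a calibration problem
#'
#' Declares which parameters and initial conditions are free, with bounds,
#' and what the fixed quantities are.  Free names are model parameter names
#' plus the estimable initial conditions \code{"S_U0"}, \code{"S_E0"},
#' \code{"N_S0"}.  Default bounds: [0, 1] for proportions and efficacies,
#' [0, 10] per month for rates, and order-of-magnitude windows around the
#' packaged baseline for population-scale quantities.
#'
#' @param free character vector of free quantity names, or a named list of
#'   \code{c(lower, upper)} bounds.
#' @param params fixed parameter values (also the source of defaults for
#'   free parameters' start points).
#' @param init fixed initial conditions.
#' @param weights per-series fitting weights.
#' @return classed list \code{sbe_fit_spec}.
#' @export
fit_spec <- function(free, params = sbe_parameters(),
                     init = sbe_initial_state(),
                     weights = rep(1, length(.report_series))) {
  default_bounds <- function(nm) {
    switch(nm,
      theta = , k = , rho_1 = , rho_2 = c(0, 1),
      Lambda_H = c(0, 1e6),
      S_U0 = c(1e6, 1e8), S_E0 = c(0, 1e5), N_S0 = c(1e3, 1e5),
      K_S = c(1e4, 1e6),
      c(0, 10))
  }
  if (!is.list(free)) free <- setNames(lapply(free, default_bounds), free)
  valid <- c(.param_names, "S_U0", "S_E0", "N_S0")
  bad <- setdiff(names(free), valid)
  if (length(bad)) stop("unknown free quantity: ", paste(bad, collapse = ", "))
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] > b[2])
      stop("invalid bounds for ", nm)
  }
  structure(list(free = free, params = params, init = init,
                 weights = weights), class = "sbe_fit_spec")
}

# Apply a free-quantity vector to (params, init).
.apply_free <- function(x, spec) {
  params <- unclass(spec$params)
  init <- spec$init
  for (nm in names(x)) {
    if (nm %in% .param_names) {
      params[[nm]] <- x[[nm]]
    } else {
      # S_U0/S_E0/N_S0: estimable initial conditions, no tracker counterpart
      init[[sub("0$", "", nm)]] <- x[[nm]]
    }
  }
  class(params) <- "sbe_parameters"
  list(params = params, init = init)
}

.fit_objective <- function(x, spec, data) {
  names(x) <- names(spec$free)
  pi <- .apply_free(x, spec)
  m <- try(model_report_curves(pi$params, pi$init, max(data$month)),
           silent = TRUE)
  if (inherits(m, "try-error")) return(1e12)
  sum_squared_residuals(m, data, spec$weights)
}

#' Bounded least-squares calibration with multi-start
#'
#' Minimises the weighted sum of squared residuals between model-implied and
#' observed cumulative report curves over the free quantities, using
#' L-BFGS-B from multiple starting points (the current values plus uniform
#' draws within bounds).
#'
#' @param data report table (see \code{\link{validate_report_table}}).
#' @param spec an \code{\link{fit_spec}}.
#' @param starts number of starting points (>= 1).
#' @param seed RNG seed for the random starts.
#' @return list with \code{estimate} (named vector), \code{objective},
#'   \code{params}/\code{init} at the optimum, and \code{convergence}.
#' @export
least_squares_fit <- function(data, spec, starts = 5, seed = 1) {
  validate_report_table(data)
  free <- spec$free
  if (!length(free)) {
    obj <- .fit_objective(numeric(0), spec, data)
    return(list(estimate = numeric(0), objective = obj,
                params = spec$params, init = spec$init, convergence = 0L))
  }
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  current <- vapply(names(free), function(nm) {
    if (nm %in% .param_names) spec$params[[nm]]
    else spec$init[[sub("0$", "", nm)]]
  }, numeric(1))
  set.seed(seed)
  start_points <- list(pmin(pmax(current, lower), upper))
  if (starts > 1)
    for (i in seq_len(starts - 1))
      start_points[[i + 1]] <- lower + runif(length(free)) * (upper - lower)
  best <- NULL
  n_fail <- 0
  for (x0 in start_points) {
    fit <- try(optim(x0, .fit_objective, spec = spec, data = data,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500,
                                    parscale = pmax(abs(x0), 1e-3))),
               silent = TRUE)
    if (inherits(fit, "try-error")) { n_fail <- n_fail + 1; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")
  est <- setNames(best$par, names(free))
  pi <- .apply_free(est, spec)
  list(estimate = est, objective = best$value,
       params = pi$params, init = pi$init, convergence = best$convergence)
}

#' Adaptive random-walk Metropolis sampling of the calibration posterior
#'
#' Targets a Gaussian observation model on the cumulative counts with
#' per-series variances profiled out (equivalent to a log posterior
#' \code{-sum_s (n/2) log SSR_s} on a flat box prior given by the bounds).
#' The diagonal proposal is tuned to a 20-40\% acceptance fraction during
#' burn-in.
#'
#' @param data report table.
#' @param spec an \code{\link{fit_spec}}.
#' @param start named start vector within bounds (e.g. a least-squares
#'   estimate); chains beyond the first are overdispersed around it.
#' @param n_iter post-burn-in iterations per chain.
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param burn_in adaptation/burn-in iterations discarded per chain.
#' @param seed RNG seed.
#' @param likelihood \code{"profiled"} (default) or \code{"flat"} (constant
#'   likelihood; chains then explore the bound box uniformly).
#' @return classed list \code{sbe_chains}: \code{chains} (list of matrices
#'   iterations x parameters), \code{acceptance}, \code{bounds}, \code{seed},
#'   \code{burn_in}.
#' @export
mcmc_sample <- function(data, spec, start, n_iter = 5000, n_chains = 4,
                        burn_in = n_iter, seed = 1,
                        likelihood = c("profiled", "flat")) {
  likelihood <- match.arg(likelihood)
  validate_report_table(data)
  free <- spec$free
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  start <- start[names(free)]
  if (any(start < lower | start > upper)) stop("start outside bounds")
  # month 0 is the registry anchor shared by model and data (zero residual
  # by construction), not an observation: it carries no likelihood weight
  n_obs <- nrow(data) - 1
  log_post <- function(x) {
    if (any(x < lower | x > upper)) return(-Inf)
    if (likelihood == "flat") return(0)
    names(x) <- names(free)
    pi <- .apply_free(x, spec)
    m <- try(model_report_curves(pi$params, pi$init, max(data$month)),
             silent = TRUE)
    if (inherits(m, "try-error")) return(-Inf)
    ssr <- .series_ssr(m, data)
    -sum(n_obs / 2 * log(pmax(ssr, 1e-12)))
  }
  set.seed(seed)
  d <- length(free)
  chains <- vector("list", n_chains)
  acc <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    x <- if (ch == 1) start else {
      # overdispersed but scale-aware starts for the extra chains
      jitter <- pmax(0.05 * abs(start), 1e-3 * (upper - lower))
      repeat {
        cand <- start + jitter * rnorm(d)
        if (all(cand >= lower & cand <= upper)) break
      }
      cand
    }
    lp <- log_post(x)
    # proposal: scaled empirical-covariance random walk (adapted during
    # burn-in only), seeded at the parameter scale rather than the often
    # loose bound width; a scalar multiplier chases 20-40% acceptance
    scale0 <- pmax(0.02 * abs(start), 1e-4 * (upper - lower))
    prop_chol <- diag(scale0, d)
    lambda <- 1
    trace <- matrix(NA_real_, burn_in + n_iter, d)
    keep <- matrix(NA_real_, n_iter, d,
                   dimnames = list(NULL, names(free)))
    n_acc <- 0; n_acc_win <- 0
    total <- burn_in + n_iter
    for (it in seq_len(total)) {
      prop <- x + lambda * drop(prop_chol %*% rnorm(d))
      lp_prop <- log_post(prop)
      if (log(runif(1)) < lp_prop - lp) {
        x <- prop; lp <- lp_prop
        n_acc_win <- n_acc_win + 1
        if (it > burn_in) n_acc <- n_acc + 1
      }
      trace[it, ] <- x
      if (it <= burn_in && it %% 50 == 0) {
        rate <- n_acc_win / 50
        if (rate < 0.05) lambda <- lambda * 0.3
        else if (rate < 0.2) lambda <- lambda * 0.7
        else if (rate > 0.4) lambda <- lambda * 1.6
        n_acc_win <- 0
        if (it >= 200) {
          win <- trace[max(1, it - 400):it, , drop = FALSE]
          cov_emp <- 2.38^2 / d * var(win) + diag((1e-3 * scale0)^2, d)
          ch_try <- try(chol(cov_emp), silent = TRUE)
          if (!inherits(ch_try, "try-error")) {
            prop_chol <- t(ch_try)
            lambda <- max(lambda, 0.2)
          }
        }
      }
      if (it > burn_in) keep[it - burn_in, ] <- x
    }
    if (n_iter > 0 && n_acc == 0 && likelihood != "flat")
      warning("chain ", ch, ": zero acceptance after adaptation")
    chains[[ch]] <- keep
    acc[ch] <- n_acc / n_iter
  }
  structure(list(chains = chains, acceptance = acc,
                 bounds = cbind(lower = lower, upper = upper),
                 seed = seed, burn_in = burn_in),
            class = "sbe_chains")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For each parameter, with W the mean within-chain variance and B/n the
#' between-chain variance of the chain means,
#' \code{R_c = sqrt((n - 1)/n + B/(n W))}.  Values close to 1 indicate that
#' the chains have mixed over the same distribution.
#'
#' @param chains an \code{sbe_chains} object or a plain list of equally
#'   sized sample matrices (iterations x parameters).
#' @param band convergence band for the verdict (default [0.9, 1.1]).
#' @return list with \code{psrf} (named vector), \code{converged} (logical),
#'   \code{band}.
#' @export
gelman_rubin <- function(chains, band = c(0.9, 1.1)) {
  if (inherits(chains, "sbe_chains")) chains <- chains$chains
  m <- length(chains)
  if (m < 2) stop("need at least two chains")
  n <- nrow(chains[[1]])
  if (n < 2) stop("need at least two post-burn-in samples")
  if (!all(vapply(chains, nrow, integer(1)) == n))
    stop("chains must have equal length")
  d <- ncol(chains[[1]])
  psrf <- numeric(d)
  for (j in seq_len(d)) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(draws, 2, var))
    B_over_n <- var(colMeans(draws))
    if (W == 0) {
      if (B_over_n > 0) stop("degenerate chains: zero within-chain variance")
      psrf[j] <- 1
    } else {
      psrf[j] <- sqrt((n - 1) / n + B_over_n / W)
    }
  }
  names(psrf) <- colnames(chains[[1]])
  list(psrf = psrf, converged = all(psrf >= band[1] & psrf <= band[2]),
       band = band)
}
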