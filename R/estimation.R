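#' Normalized sum-of-squared-residuals cost
#'
#' The model-agreement cost: `sum(((y - yhat) / sem)^2)` over all supplied
#' points. Non-finite predictions make the cost `Inf` (optimizer-safe),
#' with attribute `sim_failed = TRUE`.
#'
#' @param y observed means.
#' @param yhat model predictions at the same points.
#' @param sem standard errors of the mean (all > 0).
#' @return non-negative scalar.
#' @export
cost_nssr <- function(y, yhat, sem) {
  stopifnot(length(y) == length(yhat), length(y) == length(sem),
            all(sem > 0))
  if (any(!is.finite(yhat))) {
    out <- Inf
    attr(out, "sim_failed") <- TRUE
    return(out)
  }
  sum(((y - yhat) / sem)^2)
}

#' Cost of a model against a multi-condition dataset
#'
#' Simulates each condition once at the union of that condition's data
#' times and accumulates [cost_nssr()] across all observables and
#' conditions. A failed integration yields `Inf`.
#'
#' @param model an [ode_model()].
#' @param conditions named list of [condition()] objects; names must cover
#'   `data$condition`.
#' @param data data.frame with columns `condition`, `observable`, `time`,
#'   `mean`, `sem`.
#' @param ... passed to [simulate_model()].
#' @return non-negative scalar (possibly `Inf`).
#' @export
model_cost <- function(model, conditions, data, ...) {
  total <- 0
  for (cn in unique(data$condition)) {
    d <- data[data$condition == cn, ]
    sim <- tryCatch(
      simulate_model(model, conditions[[cn]], sort(unique(d$time)), ...),
      error = function(e) NULL)
    if (is.null(sim)) {
      out <- Inf; attr(out, "sim_failed") <- TRUE
      return(out)
    }
    idx <- match(d$time, sim$time)
    yhat <- vapply(seq_len(nrow(d)),
                   function(i) sim[[d$observable[i]]][idx[i]], numeric(1))
    v <- cost_nssr(d$mean, yhat, d$sem)
    if (!is.finite(v)) return(v)
    total <- total + v
  }
  total
}

#' Chi-squared acceptance threshold
#'
#' Upper-tail critical value of the chi-squared distribution: the
#' rejection threshold for the normalized-SSR cost at significance
#' `alpha` with `df` degrees of freedom.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1).
#' @return critical value.
#' @export
chi2_threshold <- function(df, alpha = 0.05) {
  if (!is.numeric(df) || df < 1) stop("df must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  stats::qchisq(1 - alpha, df)
}

#' Chi-squared acceptance test
#'
#' A model/parameter combination is accepted iff its cost is below the
#' critical value; anything at or above the threshold is rejected.
#'
#' @param v non-negative cost.
#' @inheritParams chi2_threshold
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
chi2_test <- function(v, df, alpha = 0.05) {
  stopifnot(v >= 0 || !is.finite(v))
  is.finite(v) && v < chi2_threshold(df, alpha)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Global stochastic optimizer: differential evolution with local polish
#'
#' A population-based global search over a box, followed by an L-BFGS-B
#' polish of the incumbent, under a hard budget of objective evaluations.
#' Deterministic given `seed`. Non-finite objective values are treated as
#' `Inf`. The returned best point never leaves the bounds and the
#' best-so-far trace is monotone non-increasing.
#'
#' @param fn objective, vector -> scalar.
#' @param lower,upper finite bounds.
#' @param budget maximum objective evaluations (> 0), shared across
#'   restarts and polish.
#' @param restarts independent population restarts.
#' @param seed RNG seed.
#' @param init optional matrix of points (rows) injected into the first
#'   population, e.g. a known good start.
#' @return `fit_result`: list with `par`, `value`, `trace` (data.frame
#'   `eval`, `best`), `evals`, `seed`.
#' @export
fit_global <- function(fn, lower, upper, budget = 2000, restarts = 3,
                       seed = 1L, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower), budget > 0)
  evals <- 0L
  best_par <- NULL
  best_val <- Inf
  tr_eval <- integer(budget); tr_best <- numeric(budget)
  eval1 <- function(x) {
    if (evals >= budget) stop("..budget..", call. = FALSE)
    v <- tryCatch(fn(x), error = function(e) Inf)
    # failed evaluations get a huge finite value so gradient-based polish
    # stays well-defined; anything at this cap reports back as Inf
    if (!is.finite(v) || is.na(v)) v <- 1e15
    v <- min(v, 1e15)
    evals <<- evals + 1L
    if (v < best_val) { best_val <<- v; best_par <<- x }
    tr_eval[evals] <<- evals; tr_best[evals] <<- best_val
    v
  }
  with_seed(seed, {
    polish_reserve <- min(budget %/% 5L, 30L * (d + 1L))
    per_restart <- max(1L, (budget - polish_reserve) %/% restarts)
    for (r in seq_len(restarts)) {
      if (evals >= budget) break
      np <- max(8L, 4L * d)
      np <- min(np, max(1L, per_restart))
      pop <- matrix(stats::runif(np * d, lower, upper), np, d, byrow = TRUE)
      if (r == 1L && !is.null(init)) {
        ini <- matrix(init, ncol = d)
        take <- min(nrow(ini), np)
        pop[seq_len(take), ] <- pmin(pmax(ini[seq_len(take), , drop = FALSE],
                                          rep(lower, each = take)),
                                     rep(upper, each = take))
      }
      fv <- rep(Inf, np)
      ok <- tryCatch({
        for (i in seq_len(np)) fv[i] <- eval1(pop[i, ])
        used <- np
        FF <- 0.7; CR <- 0.9
        while (np >= 4L && used < per_restart &&
               evals < budget - polish_reserve) {
          for (i in seq_len(np)) {
            if (used >= per_restart || evals >= budget - polish_reserve) break
            rs <- sample(setdiff(seq_len(np), i), 3L)
            trial <- pop[rs[1], ] + FF * (pop[rs[2], ] - pop[rs[3], ])
            cr <- stats::runif(d) < CR
            cr[sample.int(d, 1L)] <- TRUE
            trial <- ifelse(cr, trial, pop[i, ])
            trial <- pmin(pmax(trial, lower), upper)
            v <- eval1(trial)
            used <- used + 1L
            if (v <= fv[i]) { pop[i, ] <- trial; fv[i] <- v }
          }
        }
        TRUE
      }, error = function(e) {
        if (conditionMessage(e) == "..budget..") FALSE else stop(e)
      })
      if (!ok) break
    }
    # local polish of the incumbent
    if (!is.null(best_par) && is.finite(best_val) &&
        evals < budget - (d + 2L)) {
      tryCatch(
        stats::optim(best_par, eval1, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 25L)),
        error = function(e)
          if (conditionMessage(e) != "..budget..") stop(e))
    }
  })
  if (is.null(best_par)) best_par <- (lower + upper) / 2
  if (best_val >= 1e15) best_val <- Inf
  structure(list(par = pmin(pmax(best_par, lower), upper), value = best_val,
                 trace = data.frame(eval = tr_eval[seq_len(evals)],
                                    best = tr_best[seq_len(evals)]),
                 evals = evals, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: v* =", format(x$value), "after", x$evals,
      "evaluations (seed", x$seed, ")\n")
  invisible(x)
}

free_parameters <- function(model) {
  pa <- model$parameters
  which(pa$upper > pa$lower)
}

param_transform <- function(model, idx) {
  # kinetic (strictly positive lower bound) parameters live in log10
  # space; scale/offset parameters with lower <= 0 stay linear
  pa <- model$parameters[idx, ]
  logs <- pa$lower > 0
  lo <- pa$lower; hi <- pa$upper
  lo[logs] <- log10(lo[logs]); hi[logs] <- log10(hi[logs])
  list(idx = idx, logs = logs, lower = lo, upper = hi,
       to_theta = function(values) {
         values[logs] <- log10(values[logs]); values
       },
       from_theta = function(theta) {
         theta[logs] <- 10^theta[logs]; theta
       })
}

set_params <- function(model, idx, values) {
  model$parameters$value[idx] <- values
  model
}

#' Fit a model's free parameters to data
#'
#' Global stochastic search (see [fit_global()]) over the model's free
#' parameters (those with `lower < upper`), in log10 space for strictly
#' positive kinetic parameters and linear space otherwise, minimizing
#' [model_cost()].
#'
#' @param model an [ode_model()].
#' @param conditions named list of [condition()]s keyed by the condition
#'   labels in `data`.
#' @param data data.frame as in [model_cost()].
#' @param budget,restarts,seed see [fit_global()].
#' @param ... passed to [simulate_model()].
#' @return a `fit_result`; `$model` holds the refitted model.
#' @export
fit_model <- function(model, conditions, data, budget = 2000, restarts = 3,
                      seed = 1L, ...) {
  idx <- free_parameters(model)
  tr <- param_transform(model, idx)
  obj <- function(theta)
    model_cost(set_params(model, idx, tr$from_theta(theta)),
               conditions, data, ...)
  fr <- fit_global(obj, tr$lower, tr$upper, budget = budget,
                   restarts = restarts, seed = seed,
                   init = matrix(tr$to_theta(model$parameters$value[idx]),
                                 nrow = 1))
  fr$par_values <- stats::setNames(tr$from_theta(fr$par),
                                   model$parameters$name[idx])
  fr$model <- set_params(model, idx, fr$par_values)
  fr
}

#' Prediction uncertainty under the chi-squared constraint
#'
#' For every requested time point, minimizes and maximizes the prediction
#' while requiring the data agreement to stay below `threshold`. The
#' constraint is relaxed into the objective as a penalty:
#' `|p| + |p(theta*)| * (1 + |v(theta) - threshold|)` added whenever
#' `v(theta) > threshold` (maximization runs on the sign-flipped
#' prediction). The best-fit point is injected into every search
#' population, so the feasible set is never empty and the returned
#' envelopes always contain the best-fit trajectory.
#'
#' @param model an [ode_model()] (used for bounds/parameterization).
#' @param conditions named list of [condition()]s.
#' @param data data.frame as in [model_cost()].
#' @param pred list with `observable`, `condition`, `times`: the
#'   prediction to bound.
#' @param threshold chi-squared rejection threshold for the cost.
#' @param fit a `fit_result` from [fit_model()] with `value <= threshold`.
#' @param budget evaluations per (time point, direction) search.
#' @param seed RNG seed.
#' @param ... passed to [simulate_model()].
#' @return a `prediction_band`: list with `times`, `lower`, `upper`,
#'   `best`, `threshold`.
#' @export
uncertainty_bounds <- function(model, conditions, data, pred, threshold,
                               fit, budget = 400, seed = 1L, ...) {
  if (!is.finite(fit$value) || fit$value > threshold)
    stop("model rejected at this threshold (v* = ", format(fit$value),
         " > ", format(threshold), ")", call. = FALSE)
  idx <- free_parameters(model)
  tr <- param_transform(model, idx)
  theta_star <- tr$to_theta(fit$par_values)
  predict_at <- function(theta) {
    m <- set_params(model, idx, tr$from_theta(theta))
    sim <- tryCatch(
      simulate_model(m, conditions[[pred$condition]], pred$times, ...),
      error = function(e) NULL)
    if (is.null(sim)) return(rep(NA_real_, length(pred$times)))
    sim[[pred$observable]]
  }
  cost_at <- function(theta)
    model_cost(set_params(model, idx, tr$from_theta(theta)),
               conditions, data, ...)
  best <- predict_at(theta_star)
  lower <- upper <- best
  k <- 0L
  for (j in seq_along(pred$times)) {
    for (sgn in c(1, -1)) {
      k <- k + 1L
      p_star <- abs(best[j])
      obj <- function(theta) {
        p <- predict_at(theta)[j]
        if (!is.finite(p)) return(Inf)
        v <- cost_at(theta)
        pen <- if (!is.finite(v) || v > threshold)
          abs(p) + p_star * (1 + abs(v - threshold)) else 0
        sgn * p + pen
      }
      fr <- fit_global(obj, tr$lower, tr$upper, budget = budget,
                       restarts = 2, seed = (seed + 7L * k) %% 2147483647L,
                       init = matrix(theta_star, nrow = 1))
      # keep the optimum only if it is actually feasible
      v_opt <- cost_at(fr$par)
      if (is.finite(v_opt) && v_opt <= threshold + 1e-9) {
        p_opt <- predict_at(fr$par)[j]
        if (is.finite(p_opt)) {
          if (sgn > 0) lower[j] <- min(lower[j], p_opt)
          else upper[j] <- max(upper[j], p_opt)
        }
      }
    }
  }
  structure(list(times = pred$times, lower = lower, upper = upper,
                 best = best, threshold = threshold),
            class = "prediction_band")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat("prediction_band over", length(x$times), "time points, threshold",
      format(x$threshold), "\n")
  invisible(x)
}
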