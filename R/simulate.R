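input_value_fun <- function(inputs) {
  # value(t) per input: dose inside any on/off window, else 0
  function(name, t) {
    inp <- inputs[[name]]
    if (is.null(inp) || inp$dose == 0) return(0)
    w <- inp$windows
    on <- any(t >= w[, 1] & t < w[, 2])
    if (on) inp$dose else 0
  }
}

resolve_clamps <- function(model, clamps) {
  # clamp keys may be state names or protein identifiers; a protein key
  # resolves to the state carrying that protein's activity observable
  if (!length(clamps)) return(numeric())
  out <- numeric()
  for (k in names(clamps)) {
    if (k %in% model$states$name) {
      out[[k]] <- clamps[[k]]
    } else if (k %in% names(model$activity)) {
      obs <- model$activity[[k]]
      stn <- model$observables$state[model$observables$name == obs]
      out[[stn]] <- clamps[[k]]
    } else {
      stop("clamp targets unknown state/protein: ", k, call. = FALSE)
    }
  }
  out
}

#' Simulate an ODE model under a condition
#'
#' Integrates the model with `deSolve::lsoda` (stiff-capable, adaptive).
#' The condition's initial and effect scalings are applied first; clamps
#' multiply the clamped state's value wherever it appears in *other*
#' states' rate expressions; the input schedule override replaces input
#' dose/windows. With `equilibrate = TRUE` (default) the model is first
#' run for `equil_time` minutes with all inputs off and the endpoint is
#' taken as the initial state, so stimulation starts from steady state
#' at t = 0.
#'
#' @param model an [ode_model()].
#' @param cond a [condition()] or `NULL`.
#' @param times sorted, non-negative simulation times in minutes.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param equilibrate pre-equilibrate with inputs off before t = 0?
#' @param equil_time pre-equilibration horizon in minutes.
#' @return data.frame with `time`, one column per state and per observable.
#' @export
simulate_model <- function(model, cond = NULL, times,
                           rtol = 1e-6, atol = 1e-9,
                           equilibrate = TRUE, equil_time = 1000) {
  stopifnot(!is.unsorted(times), all(times >= 0))
  if (!is.null(cond)) {
    model <- apply_condition(model, cond)
    if (length(cond$input_schedule)) {
      for (n in names(cond$input_schedule)) {
        if (!n %in% names(model$inputs))
          stop("condition schedules unknown input: ", n, call. = FALSE)
        model$inputs[[n]] <- cond$input_schedule[[n]]
      }
    }
    clamps <- resolve_clamps(model, cond$clamps)
  } else clamps <- numeric()

  st_names <- model$states$name
  y0 <- stats::setNames(model$states$init, st_names)
  pars <- stats::setNames(model$parameters$value, model$parameters$name)
  rate_exprs <- lapply(model$rates[st_names], str2lang)
  in_names <- names(model$inputs)
  ifun <- input_value_fun(model$inputs)

  deriv <- function(t, y, p, inputs_on) {
    e <- as.list(c(y, pars))
    for (n in in_names) e[[n]] <- if (inputs_on) ifun(n, t) else 0
    if (length(clamps)) {
      ec <- e
      for (cs in names(clamps)) ec[[cs]] <- ec[[cs]] * clamps[[cs]]
      dy <- vapply(st_names, function(s) {
        env <- if (s %in% names(clamps)) {
          tmp <- ec; tmp[[s]] <- e[[s]]; tmp  # own rate sees itself unclamped
        } else ec
        eval(rate_exprs[[s]], env)
      }, numeric(1))
    } else {
      dy <- vapply(st_names, function(s) eval(rate_exprs[[s]], e), numeric(1))
    }
    list(dy)
  }

  if (equilibrate && equil_time > 0) {
    eq <- deSolve::lsoda(y0, c(0, equil_time), deriv, parms = NULL,
                         inputs_on = FALSE, rtol = rtol, atol = atol)
    y0 <- stats::setNames(as.numeric(eq[nrow(eq), st_names]), st_names)
  }

  sim_times <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::lsoda(y0, sim_times, deriv, parms = NULL,
                        inputs_on = TRUE, rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  bad <- !is.finite(as.matrix(out[, st_names, drop = FALSE]))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop("integration failure: state ", st_names[ij[2]],
         " non-finite at t = ", out$time[ij[1]], call. = FALSE)
  }
  if (nrow(out) < length(sim_times))
    stop("integration failure: solver stopped at t = ",
         out$time[nrow(out)], call. = FALSE)
  out <- out[match(times, out$time), , drop = FALSE]

  ob <- model$observables
  for (i in seq_len(nrow(ob))) {
    sc <- ob$scale[i]
    scv <- suppressWarnings(as.numeric(sc))
    if (is.na(scv)) scv <- pars[[sc]]
    off <- ob$offset[i]
    offv <- if (is.na(off)) 0 else {
      ov <- suppressWarnings(as.numeric(off))
      if (is.na(ov)) pars[[off]] else ov
    }
    out[[ob$name[i]]] <- scv * out[[ob$state[i]]] + offv
  }
  rownames(out) <- NULL
  out
}

#' Activity trajectories of the model's proteins
#'
#' Simulates the model and returns the designated activity observable of
#' each protein, the canonical upstream signal used when attaching
#' phosphosites.
#'
#' @inheritParams simulate_model
#' @return data.frame: `time` plus one column per protein identifier.
#' @export
protein_activities <- function(model, cond = NULL, times, ...) {
  sim <- simulate_model(model, cond, times, ...)
  out <- data.frame(time = sim$time)
  for (p in names(model$activity)) out[[p]] <- sim[[model$activity[[p]]]]
  out
}
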