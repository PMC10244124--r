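#' Construct an ODE signaling model
#'
#' An `ode_model` bundles states (with initial values and an optional protein
#' identifier used for network adjacency), bounded kinetic parameters, one
#' rate expression per state, time-dependent step inputs, linear observables
#' (`scale * state + offset`), and a protein -> activity-observable map that
#' designates the canonical signal each protein feeds downstream.
#'
#' @param states data.frame with columns `name`, `init`, `protein`
#'   (`NA`/`"-"` for species without a protein identity, e.g. metabolites).
#' @param parameters data.frame with columns `name`, `value`, `lower`, `upper`.
#' @param rates named character vector, one arithmetic expression per state
#'   over state, parameter and input names.
#' @param inputs named list; each element `list(dose =, windows =)` where
#'   `windows` is a 2-column matrix of on/off times in minutes.
#' @param observables data.frame with columns `name`, `scale` (parameter name
#'   or literal number), `state`, `offset` (parameter name, number, or `NA`).
#' @param activity named character vector mapping protein identifier to the
#'   observable that carries that protein's activity signal.
#' @return an object of class `ode_model`.
#' @export
ode_model <- function(states, parameters, rates, inputs = list(),
                      observables, activity = character()) {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  parameters <- as.data.frame(parameters, stringsAsFactors = FALSE)
  observables <- as.data.frame(observables, stringsAsFactors = FALSE)
  if (!all(c("name", "init", "protein") %in% names(states)))
    stop("states needs columns name, init, protein", call. = FALSE)
  if (!all(c("name", "value", "lower", "upper") %in% names(parameters)))
    stop("parameters needs columns name, value, lower, upper", call. = FALSE)
  m <- structure(list(states = states, parameters = parameters,
                      rates = rates, inputs = inputs,
                      observables = observables, activity = activity),
                 class = "ode_model")
  validate_ode_model(m)
  m
}

validate_ode_model <- function(m) {
  st <- m$states; pa <- m$parameters; ob <- m$observables
  if (anyDuplicated(st$name)) stop("duplicate state names", call. = FALSE)
  if (anyDuplicated(pa$name)) stop("duplicate parameter names", call. = FALSE)
  if (length(m$inputs) && anyDuplicated(names(m$inputs)))
    stop("duplicate input names", call. = FALSE)
  if (any(!is.finite(st$init))) stop("non-finite initial value", call. = FALSE)
  bad <- pa$value < pa$lower | pa$value > pa$upper
  if (any(bad))
    stop("parameter outside its bounds: ",
         paste(pa$name[bad], collapse = ", "), call. = FALSE)
  known <- c(st$name, pa$name, names(m$inputs))
  if (!setequal(names(m$rates), st$name))
    stop("rates must cover exactly the states", call. = FALSE)
  for (s in names(m$rates)) {
    syms <- all.vars(str2lang(m$rates[[s]]))
    miss <- setdiff(syms, known)
    if (length(miss))
      stop("undefined symbol(s) in rate of ", s, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(ob))) {
    if (!ob$state[i] %in% st$name)
      stop("observable ", ob$name[i], " maps unknown state ", ob$state[i],
           call. = FALSE)
    for (tok in c(ob$scale[i], ob$offset[i])) {
      if (is.na(tok)) next
      if (is.na(suppressWarnings(as.numeric(tok))) && !tok %in% pa$name)
        stop("observable ", ob$name[i], " references unknown parameter ",
             tok, call. = FALSE)
    }
  }
  for (p in names(m$activity)) {
    if (!m$activity[[p]] %in% ob$name)
      stop("activity map for ", p, " names unknown observable", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.ode_model <- function(x, ...) {
  cat("ode_model:", nrow(x$states), "states,", nrow(x$parameters),
      "parameters,", length(x$inputs), "inputs,",
      nrow(x$observables), "observables\n")
  invisible(x)
}

#' Experimental condition
#'
#' A condition rescales a model before/while simulating it: multiplicative
#' factors on initial values, effect factors in \[0, 1\] on parameters
#' (0 = full blockage, 1 = no effect), an input schedule override, and
#' multiplicative clamps applied to a state's value wherever it appears in
#' *other* states' rate expressions (the inhibitor semantics).
#'
#' @param initial_scalings named numeric, state -> factor (>= 0).
#' @param effect_scalings named numeric, parameter -> factor in \[0, 1\].
#' @param input_schedule named list, input -> `list(dose =, windows =)`.
#' @param clamps named numeric, state or protein -> factor in \[0, 1\].
#' @return an object of class `sim_condition`.
#' @export
condition <- function(initial_scalings = numeric(), effect_scalings = numeric(),
                      input_schedule = list(), clamps = numeric()) {
  stopifnot(all(is.finite(initial_scalings)), all(initial_scalings >= 0),
            all(is.finite(effect_scalings)),
            all(effect_scalings >= 0 & effect_scalings <= 1),
            all(is.finite(clamps)), all(clamps >= 0 & clamps <= 1))
  structure(list(initial_scalings = initial_scalings,
                 effect_scalings = effect_scalings,
                 input_schedule = input_schedule, clamps = clamps),
            class = "sim_condition")
}

#' Apply a condition to a model
#'
#' Returns a new model with scaled initial values and effect-scaled
#' parameters; the original is untouched. Clamps and input schedules are
#' dynamic and consumed by [simulate_model()] instead.
#'
#' @param model an [ode_model()].
#' @param cond a [condition()].
#' @return a new `ode_model`.
#' @export
apply_condition <- function(model, cond) {
  for (s in names(cond$initial_scalings)) {
    i <- match(s, model$states$name)
    if (is.na(i)) stop("condition scales unknown state: ", s, call. = FALSE)
    model$states$init[i] <- model$states$init[i] * cond$initial_scalings[[s]]
  }
  for (p in names(cond$effect_scalings)) {
    i <- match(p, model$parameters$name)
    if (is.na(i)) stop("condition scales unknown parameter: ", p, call. = FALSE)
    model$parameters$value[i] <-
      model$parameters$value[i] * cond$effect_scalings[[p]]
  }
  model
}

fmt_num <- function(x) {
  # deterministic, round-trip-exact number formatting for the text format
  vapply(x, function(v) sprintf("%.15g", v), "")
}

#' Write a model to its canonical text form
#'
#' UTF-8 text with sections `[states] [parameters] [rates] [inputs]
#' [observables] [activity]`, one definition per line, `#` comments.
#' Writing then reading reproduces the model exactly at the text level.
#'
#' @param model an [ode_model()].
#' @param path file path.
#' @export
write_model <- function(model, path) {
  st <- model$states; pa <- model$parameters; ob <- model$observables
  lines <- c("[states]",
             sprintf("%s %s %s", st$name, fmt_num(st$init),
                     ifelse(is.na(st$protein), "-", st$protein)),
             "[parameters]",
             sprintf("%s %s %s %s", pa$name, fmt_num(pa$value),
                     fmt_num(pa$lower), fmt_num(pa$upper)),
             "[rates]",
             sprintf("%s = %s", names(model$rates),
                     unname(model$rates[names(model$rates)])),
             "[inputs]",
             vapply(names(model$inputs), function(n) {
               inp <- model$inputs[[n]]
               w <- apply(inp$windows, 1, function(r)
                 paste0(fmt_num(r[1]), ":", fmt_num(r[2])))
               sprintf("%s %s %s", n, fmt_num(inp$dose),
                       paste(w, collapse = ","))
             }, ""),
             "[observables]",
             sprintf("%s = %s * %s%s", ob$name, ob$scale, ob$state,
                     ifelse(is.na(ob$offset), "", paste0(" + ", ob$offset))),
             "[activity]",
             if (length(model$activity))
               sprintf("%s %s", names(model$activity),
                       unname(model$activity)) else character())
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a model from its canonical text form
#'
#' @param path file path.
#' @return an [ode_model()].
#' @export
read_model <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  keep <- which(trimws(lines) != "")
  if (!length(keep)) stop("parse error at line 1: empty model file",
                          call. = FALSE)
  perr <- function(i, msg) stop("parse error at line ", i, ": ", msg,
                                call. = FALSE)
  section <- NA_character_
  st <- list(); pa <- list(); rates <- character(); inputs <- list()
  ob <- list(); activity <- character()
  for (i in keep) {
    ln <- trimws(lines[i])
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% c("states", "parameters", "rates", "inputs",
                          "observables", "activity"))
        perr(i, paste0("unknown section [", section, "]"))
      next
    }
    if (is.na(section)) perr(i, "content before any section header")
    if (section == "states") {
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tok) != 3) perr(i, "state line needs: name init protein")
      v <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(v)) perr(i, "bad initial value")
      st[[length(st) + 1L]] <- data.frame(
        name = tok[1], init = v,
        protein = if (tok[3] == "-") NA_character_ else tok[3])
    } else if (section == "parameters") {
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tok) != 4) perr(i, "parameter line needs: name value lb ub")
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(v)) perr(i, "bad numeric field")
      pa[[length(pa) + 1L]] <- data.frame(name = tok[1], value = v[1],
                                          lower = v[2], upper = v[3])
    } else if (section == "rates") {
      kv <- regmatches(ln, regexec("^([^=[:space:]]+)\\s*=\\s*(.+)$", ln))[[1]]
      if (length(kv) != 3) perr(i, "rate line needs: state = expression")
      ok <- tryCatch({str2lang(kv[3]); TRUE}, error = function(e) FALSE)
      if (!ok) perr(i, "unparseable rate expression")
      rates[[kv[2]]] <- kv[3]
    } else if (section == "inputs") {
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tok) != 3) perr(i, "input line needs: name dose windows")
      dose <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(dose)) perr(i, "bad dose")
      wins <- strsplit(strsplit(tok[3], ",")[[1]], ":")
      wm <- t(vapply(wins, function(w) {
        v <- suppressWarnings(as.numeric(w))
        if (length(v) != 2 || anyNA(v)) perr(i, "bad window, expected on:off")
        v
      }, numeric(2)))
      inputs[[tok[1]]] <- list(dose = dose, windows = wm)
    } else if (section == "observables") {
      rx <- "^([^=[:space:]]+)\\s*=\\s*([^*[:space:]]+)\\s*\\*\\s*([^+[:space:]]+)(\\s*\\+\\s*(\\S+))?\\s*$"
      kv <- regmatches(ln, regexec(rx, ln))[[1]]
      if (!length(kv)) perr(i, "observable line needs: name = scale * state [+ offset]")
      ob[[length(ob) + 1L]] <- data.frame(
        name = kv[2], scale = kv[3], state = kv[4],
        offset = if (kv[6] == "") NA_character_ else kv[6])
    } else { # activity
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tok) != 2) perr(i, "activity line needs: protein observable")
      activity[[tok[1]]] <- tok[2]
    }
  }
  if (!length(st)) perr(keep[length(keep)], "model has no [states] entries")
  bind_or <- function(lst, proto) if (length(lst)) do.call(rbind, lst)
                                  else proto
  pa_df <- bind_or(pa, data.frame(name = character(), value = numeric(),
                                  lower = numeric(), upper = numeric()))
  ob_df <- bind_or(ob, data.frame(name = character(), scale = character(),
                                  state = character(),
                                  offset = character()))
  m <- tryCatch(
    ode_model(do.call(rbind, st), pa_df, rates, inputs, ob_df, activity),
    error = function(e) stop("parse error: ", conditionMessage(e),
                             call. = FALSE))
  m
}

#' Demo core model of adipocyte signaling
#'
#' A 10-state illustrative core: an insulin input activates the insulin
#' receptor (IR/IRp), which activates PKB; an adrenergic input activates
#' adenylate cyclase (ACp), producing cAMP; PKB activates PDE3B which
#' degrades cAMP (the crosstalk arm); cAMP drives HSL phosphorylation
#' (lipolysis observable) and an exocytosis observable; PKB drives GLUT4
#' translocation (glucose-uptake observable). Initial values of IR and
#' GLUT4 are the hooks for the type-2-diabetes condition. Every protein
#' state carries a protein identifier so the expansion engine can attach
#' phosphosites to it.
#'
#' @return an [ode_model()].
#' @export
build_demo_core <- function() {
  states <- data.frame(
    name = c("IR", "IRp", "PKB", "PKBp", "ACp", "cAMP", "PDE3Bp",
             "HSLp", "GLUT4", "GLUT4m"),
    init = c(1, 0, 1, 0, 0, 0.1, 0, 0, 1, 0),
    protein = c("INSR", "INSR", "AKT1", "AKT1", "ADCY3", NA, "PDE3B",
                "LIPE", "SLC2A4", "SLC2A4"))
  parameters <- data.frame(
    name = c("k_ir", "kd_ir", "k_pkb", "kd_pkb", "k_ac", "kd_ac",
             "k_camp", "kd_camp", "k_pde", "k_pde3b", "kd_pde3b",
             "k_hsl", "kd_hsl", "k_g4", "kd_g4",
             "s_glu", "s_lip", "s_exo"),
    value = c(0.3, 0.1, 1, 0.3, 1, 0.3, 0.5, 0.3, 3, 0.5, 0.2,
              1, 0.3, 0.15, 0.05, 50, 1, 1),
    lower = c(rep(1e-4, 15), 0, 0, 0),
    upper = c(rep(1e4, 15), 100, 100, 100))
  rates <- c(
    IR     = "-k_ir*insulin*IR + kd_ir*IRp",
    IRp    = "k_ir*insulin*IR - kd_ir*IRp",
    PKB    = "-k_pkb*IRp*PKB + kd_pkb*PKBp",
    PKBp   = "k_pkb*IRp*PKB - kd_pkb*PKBp",
    ACp    = "k_ac*adrenaline*(1-ACp) - kd_ac*ACp",
    cAMP   = "k_camp*ACp + 0.03 - kd_camp*cAMP - k_pde*PDE3Bp*cAMP",
    PDE3Bp = "k_pde3b*PKBp*(1-PDE3Bp) - kd_pde3b*PDE3Bp",
    HSLp   = "k_hsl*cAMP*(1-HSLp) - kd_hsl*HSLp",
    GLUT4  = "-k_g4*PKBp*GLUT4 + kd_g4*GLUT4m",
    GLUT4m = "k_g4*PKBp*GLUT4 - kd_g4*GLUT4m")
  inputs <- list(
    insulin = list(dose = 1, windows = matrix(c(0, 60), 1)),
    adrenaline = list(dose = 0, windows = matrix(c(0, 60), 1)))
  observables <- data.frame(
    name = c("IR_active", "PKB_activity", "AC_activity", "cAMP_level",
             "PDE3B_activity", "HSL_phospho", "glucose_uptake",
             "lipolysis", "exocytosis"),
    scale = c("1", "1", "1", "1", "1", "1", "s_glu", "s_lip", "s_exo"),
    state = c("IRp", "PKBp", "ACp", "cAMP", "PDE3Bp", "HSLp", "GLUT4m",
              "HSLp", "cAMP"),
    offset = NA_character_)
  activity <- c(INSR = "IR_active", AKT1 = "PKB_activity",
                ADCY3 = "AC_activity", PDE3B = "PDE3B_activity",
                LIPE = "HSL_phospho", SLC2A4 = "glucose_uptake")
  ode_model(states, parameters, rates, inputs, observables, activity)
}

#' Type-2-diabetes condition for the demo core
#'
#' Initial-value reductions on the receptor (to 55% of normal) and on the
#' GLUT4 pool (to 50%), the two T2D hooks the demo core carries. Kinetic
#' parameters are left unchanged, as in the normal condition.
#'
#' @return a [condition()].
#' @export
t2d_demo_condition <- function() {
  condition(initial_scalings = c(IR = 0.55, GLUT4 = 0.5))
}
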