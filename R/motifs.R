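#' Kinetic motif families for site attachment
#'
#' Each motif is a minimal mass-action ODE on the phosphorylated fraction
#' `P` of a site (fractions of the three pools sum to 1), driven by one or
#' two frozen upstream trajectories `u(t)`:
#' \describe{
#'   \item{phos}{`dP/dt = ku*u*(1-P) - kret*P` (phosphorylation)}
#'   \item{dephos}{`dP/dt = kb*(1-P) - ku*u*P` (dephosphorylation; basal
#'     drive `kb` fitted)}
#'   \item{satphos}{phosphorylation with saturated drive
#'     `ku*u/(Km + u)`}
#'   \item{phos2}{two phosphorylating inputs `(k1*u1 + k2*u2)*(1-P)`}
#'   \item{dephos2}{two dephosphorylating inputs}
#'   \item{phosdephos}{one phosphorylating, one dephosphorylating input}
#'   \item{extra}{phosphorylation into a secondary state before returning:
#'     `U -> P -> S -> U` with transition `ktr` and return `kret`}
#' }
#' All motifs are linear in the pool fractions given `u(t)`, so they are
#' integrated with exact exponential steps (see `src/motif_step.cpp`).
#'
#' @return data.frame: family name, number of inputs, number of kinetic
#'   parameters, type (`"phos"`/`"dephos"`/`"mixed"`), stage.
#' @export
motif_families <- function() {
  data.frame(
    family = c("phos", "dephos", "satphos",
               "phos2", "dephos2", "phosdephos", "extra"),
    n_inputs = c(1L, 1L, 1L, 2L, 2L, 2L, 1L),
    n_kin = c(2L, 2L, 3L, 3L, 3L, 3L, 3L),
    type = c("phos", "dephos", "phos", "phos", "dephos", "mixed", "phos"),
    stage = c("single", "single", "single", "double", "double", "double",
              "extra"))
}

#' Refined integration grid over a data time grid
#'
#' Subdivides every data interval into at least `min_sub` substeps of at
#' most `dt_max` minutes, for the exponential-step motif integrators.
#'
#' @param times sorted data times (first element is the stimulus onset).
#' @param dt_max maximal substep (minutes).
#' @param min_sub minimal substeps per data interval.
#' @return list: `t0`, `ends` (substep endpoints after `t0`), `dt`,
#'   `mids` (substep midpoints), `out_idx` (index into `ends` for each
#'   data time after the first).
#' @export
motif_grid <- function(times, dt_max = 0.5, min_sub = 4L) {
  stopifnot(length(times) >= 2, !is.unsorted(times, strictly = TRUE))
  t0 <- times[1]
  ends <- numeric(0); out_idx <- integer(0)
  prev <- t0
  for (tt in times[-1]) {
    ns <- max(min_sub, ceiling((tt - prev) / dt_max))
    seg <- prev + (tt - prev) * seq_len(ns) / ns
    seg[ns] <- tt
    ends <- c(ends, seg)
    out_idx <- c(out_idx, length(ends))
    prev <- tt
  }
  dt <- diff(c(t0, ends))
  list(t0 = t0, ends = ends, dt = dt, mids = c(t0, ends)[-(length(ends) + 1)] + dt / 2,
       out_idx = out_idx)
}

# scalar-motif coefficients: dP/dt = a(t) - b(t) * P
motif_coef <- function(family, kin, u) {
  switch(family,
    phos = {
      drv <- kin[1] * u[[1]]
      list(a = drv, b = drv + kin[2])
    },
    dephos = list(a = rep(kin[1], length(u[[1]])),
                  b = kin[1] + kin[2] * u[[1]]),
    satphos = {
      drv <- kin[1] * u[[1]] / (kin[2] + u[[1]])
      list(a = drv, b = drv + kin[3])
    },
    phos2 = {
      drv <- kin[1] * u[[1]] + kin[2] * u[[2]]
      list(a = drv, b = drv + kin[3])
    },
    dephos2 = list(a = rep(kin[1], length(u[[1]])),
                   b = kin[1] + kin[2] * u[[1]] + kin[3] * u[[2]]),
    phosdephos = {
      drv <- kin[1] * u[[1]]
      list(a = drv, b = drv + kin[2] * u[[2]] + kin[3])
    },
    stop("unknown scalar motif family: ", family, call. = FALSE))
}

#' Pre-stimulus steady state of a motif
#'
#' @param family motif family name.
#' @param kin kinetic parameter vector.
#' @param u0 input value(s) at stimulus onset.
#' @return named vector `P` (and `S` for the extra-state chain).
#' @export
motif_steady <- function(family, kin, u0) {
  u0 <- unname(u0)
  if (family == "extra") {
    a0 <- kin[1] * u0[1]; ktr <- kin[2]; kret <- kin[3]
    den <- a0 * kret + a0 * ktr + ktr * kret
    P0 <- if (den > 0) a0 * kret / den else 0
    return(c(P = P0, S = if (kret > 0) ktr * P0 / kret else 0))
  }
  cf <- motif_coef(family, kin, lapply(u0, function(x) x))
  c(P = if (cf$b[1] > 0) unname(cf$a[1] / cf$b[1]) else 0)
}

#' Integrate a motif along the refined grid
#'
#' @param family motif family.
#' @param kin kinetic parameters (natural scale, > 0).
#' @param u_mid list of input-value vectors at `grid$mids`.
#' @param u0 input value(s) at `grid$t0`.
#' @param grid a [motif_grid()].
#' @return list: `path` (P at `grid$ends`), `P0`, `at_data` (P at the
#'   data times, including the first).
#' @export
motif_path <- function(family, kin, u_mid, u0, grid) {
  ss <- motif_steady(family, kin, u0)
  if (family == "extra") {
    a <- kin[1] * u_mid[[1]]
    res <- extra_state_path(ss[["P"]], ss[["S"]], a, kin[2], kin[3],
                            grid$dt)
    path <- res$P
  } else {
    cf <- motif_coef(family, kin, u_mid)
    path <- lin_path(ss[["P"]], cf$a, cf$b, grid$dt)
  }
  list(path = path, P0 = ss[["P"]],
       at_data = c(ss[["P"]], path[grid$out_idx]))
}

#' Weighted least-squares affine mapping of a trajectory onto data
#'
#' Fits `y ~ a * x + b` with weights `1/sem^2` in closed form and returns
#' the mapping and its normalized-SSR cost. Used both for observable
#' offsets and for the data-driven candidate scoring.
#'
#' @param x trajectory values at the data times.
#' @param y data means.
#' @param sem data SEMs.
#' @param a fixed slope; if `NULL` the slope is profiled too.
#' @return list `a`, `b`, `cost`.
#' @export
affine_wls <- function(x, y, sem, a = NULL) {
  w <- 1 / sem^2
  if (is.null(a)) {
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    den <- sw * sxx - sx^2
    if (abs(den) < 1e-300) { a <- 0; b <- sy / sw }
    else { a <- (sw * sxy - sx * sy) / den; b <- (sy - a * sx) / sw }
  } else {
    b <- sum(w * (y - a * x)) / sum(w)
  }
  list(a = a, b = b, cost = sum(w * (y - a * x - b)^2))
}
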