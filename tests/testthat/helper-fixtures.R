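# shared fixtures, built in code

decay_model <- function(k = 1, lower = 1e-2, upper = 1e2) {
  ode_model(
    states = data.frame(name = "x", init = 1, protein = NA),
    parameters = data.frame(name = "k", value = k, lower = lower,
                            upper = upper),
    rates = c(x = "-k*x"), inputs = list(),
    observables = data.frame(name = "xo", scale = "1", state = "x",
                             offset = NA))
}

# two-state chain A -> B with an input driving A; used for clamp semantics
chain_model <- function() {
  ode_model(
    states = data.frame(name = c("A", "B"), init = c(0, 0),
                        protein = c("PA", "PB")),
    parameters = data.frame(name = c("ka", "da", "kb", "db"),
                            value = c(1, 0.5, 1, 0.5),
                            lower = rep(1e-4, 4), upper = rep(1e4, 4)),
    rates = c(A = "ka*stim*(1-A) - da*A", B = "kb*A*(1-B) - db*B"),
    inputs = list(stim = list(dose = 1, windows = matrix(c(0, 60), 1))),
    observables = data.frame(name = c("Ao", "Bo"), scale = c("1", "1"),
                             state = c("A", "B"), offset = NA),
    activity = c(PA = "Ao", PB = "Bo"))
}

default_times <- function() c(0, 0.25, 0.5, 1, 2, 5, 10, 20, 60)

# a smooth rising upstream signal on the default grid, as mid/t0 values
rising_input <- function(grid, rate = 0.5) {
  list(mid = 1 - exp(-rate * grid$mids), t0 = 0)
}

# noisy replicate table for a single site with the given mean trajectory
site_raw <- function(site, protein, mu, times = default_times(),
                     replicates = 3, sd = 0.02, seed = 1,
                     condition = "control", responder = TRUE) {
  withr::with_seed(seed, do.call(rbind, lapply(seq_len(replicates),
    function(r) data.frame(site = site, protein = protein,
                           condition = condition, time_min = times,
                           replicate = r,
                           value = mu + rnorm(length(mu), 0, sd),
                           responder = responder))))
}
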