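test_that("simulation matches closed forms and identity cases", {
  dec <- decay_model(k = 1)
  s <- simulate_model(dec, NULL, c(0, 1), equilibrate = FALSE)
  expect_equal(s$x[2], exp(-1), tolerance = 1e-5)

  frozen <- ode_model(
    states = data.frame(name = c("a", "b"), init = c(2, 3),
                        protein = NA),
    parameters = data.frame(name = "k", value = 1, lower = 1e-4,
                            upper = 1e4),
    rates = c(a = "0", b = "0"), inputs = list(),
    observables = data.frame(name = "ao", scale = "1", state = "a",
                             offset = NA))
  s <- simulate_model(frozen, NULL, c(0, 5, 50), equilibrate = FALSE)
  expect_equal(s$a, rep(2, 3))
  expect_equal(s$b, rep(3, 3))
})

test_that("halving the solver tolerances barely moves the observables", {
  m <- build_demo_core()
  tt <- c(0, 1, 5, 20, 60)
  s1 <- simulate_model(m, NULL, tt, rtol = 1e-6, atol = 1e-9)
  s2 <- simulate_model(m, NULL, tt, rtol = 5e-7, atol = 5e-10)
  for (ob in m$observables$name) {
    rel <- abs(s1[[ob]] - s2[[ob]]) / pmax(abs(s1[[ob]]), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("conditions rescale initial values and parameters correctly", {
  m <- build_demo_core()
  t2d <- t2d_demo_condition()
  m2 <- apply_condition(m, t2d)
  expect_equal(m2$states$init[m2$states$name == "IR"], 0.55)
  expect_equal(m2$states$init[m2$states$name == "GLUT4"], 0.5)
  # original untouched
  expect_equal(m$states$init[m$states$name == "IR"], 1)

  expect_identical(apply_condition(m, condition()), m)

  # effect scaling of 1 leaves simulations unchanged
  c1 <- condition(effect_scalings = c(k_pkb = 1))
  s0 <- simulate_model(m, NULL, c(0, 5, 20))
  s1 <- simulate_model(m, c1, c(0, 5, 20))
  expect_equal(s1$PKBp, s0$PKBp, tolerance = 1e-10)

  expect_error(apply_condition(m, condition(initial_scalings = c(XX = 1))),
               "unknown state")
  expect_error(condition(effect_scalings = c(k = 1.5)))
})

test_that("an all-ones condition reproduces baseline trajectories", {
  m <- build_demo_core()
  allone <- condition(
    initial_scalings = setNames(rep(1, nrow(m$states)), m$states$name),
    effect_scalings = c(k_ir = 1), clamps = c(AKT1 = 1))
  tt <- c(0, 1, 5, 20, 60)
  s0 <- simulate_model(m, NULL, tt)
  s1 <- simulate_model(m, allone, tt)
  for (st in m$states$name)
    expect_equal(s1[[st]], s0[[st]], tolerance = 1e-6)
})

test_that("clamping a state to zero silences its downstream influence", {
  m <- chain_model()
  tt <- c(0, 2, 10, 30)
  s <- simulate_model(m, condition(clamps = c(A = 0)), tt,
                      equilibrate = FALSE)
  # A still responds to the stimulus, but B never sees it
  expect_gt(s$A[4], 0.5)
  expect_equal(s$B, rep(0, 4), tolerance = 1e-8)
})

test_that("model files round-trip bit-exactly and bad files fail to parse", {
  m <- build_demo_core()
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_model(m, f1)
  write_model(read_model(f1), f2)
  expect_identical(readLines(f1), readLines(f2))

  shipped <- system.file("extdata", "demo_core.txt", package = "odexpand")
  f3 <- withr::local_tempfile(fileext = ".txt")
  write_model(read_model(shipped), f3)
  expect_identical(readLines(shipped), readLines(f3))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[states]", "x 1 -", "[parameters]", "[rates]",
               "x = -k*x + oops", "[inputs]", "[observables]"), bad)
  expect_error(read_model(bad), "undefined symbol")

  writeLines(character(), bad)
  expect_error(read_model(bad), "parse error")
})

test_that("the demo core responds to its two inputs as designed", {
  m <- build_demo_core()
  tt <- c(0, 5, 10, 20)
  s <- simulate_model(m, NULL, tt)
  expect_gt(s$PKB_activity[4], s$PKB_activity[1] + 0.1)

  adr <- condition(input_schedule = list(
    insulin = list(dose = 0, windows = matrix(c(0, 60), 1)),
    adrenaline = list(dose = 1, windows = matrix(c(0, 60), 1))))
  sa <- simulate_model(m, adr, tt)
  expect_gt(sa$cAMP_level[4], sa$cAMP_level[1])

  off <- condition(input_schedule = list(
    insulin = list(dose = 0, windows = matrix(c(0, 60), 1))))
  s0 <- simulate_model(m, off, c(0, 10, 30, 60))
  for (ob in m$observables$name)
    expect_lt(diff(range(s0[[ob]])), 1e-5)
})

test_that("model invariants are enforced at construction", {
  expect_error(ode_model(
    states = data.frame(name = c("x", "x"), init = c(1, 1), protein = NA),
    parameters = data.frame(name = "k", value = 1, lower = 0, upper = 2),
    rates = c(x = "-k*x"), inputs = list(),
    observables = data.frame(name = "o", scale = "1", state = "x",
                             offset = NA)), "duplicate state")
  expect_error(ode_model(
    states = data.frame(name = "x", init = 1, protein = NA),
    parameters = data.frame(name = "k", value = 5, lower = 0, upper = 2),
    rates = c(x = "-k*x"), inputs = list(),
    observables = data.frame(name = "o", scale = "1", state = "x",
                             offset = NA)), "outside its bounds")
})
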