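small_world <- function(seed = 31) {
  sp <- truth_spec(n_proteins = 6, tiers = 2, seed = seed)
  tr <- generate_truth(sp)
  ex <- expand_model(tr$core, tr$dataset, tr$interactions,
                     expand_config(budget = 500, restarts = 2,
                                   seed = seed))
  list(tr = tr, ex = ex)
}

w_shared <- small_world()

test_that("a unit clamp predicts no change anywhere", {
  w <- w_shared
  rep <- predict_inhibition(w$ex, condition(clamps = c(AKT1 = 1)),
                            w$tr$dataset)
  expect_true(all(rep$per_site$predicted == "unclear"))
})

test_that("inhibitor clamps propagate with correct bookkeeping", {
  w <- w_shared
  rep <- predict_inhibition(w$ex, condition(clamps = c(AKT1 = 0.1)),
                            w$tr$dataset)
  # denominators + ignored = total sites
  expect_equal(sum(rep$per_layer$n_evaluable) + sum(rep$ignored),
               nrow(rep$per_site))
  expect_true(all(rep$per_layer$fraction_correct >= 0 &
                    rep$per_layer$fraction_correct <= 1))
  # evaluable sites have a definite observed direction
  ev <- rep$per_site[rep$per_site$status == "evaluable", ]
  expect_true(all(ev$observed %in% c("increase", "decrease")))

  expect_error(predict_inhibition(w$ex, condition(clamps = c(AKT1 = 0.1)),
                                  w$tr$dataset,
                                  inhibitor_condition = "nope"),
               "no 'nope' block")
})

test_that("unclear observed intervals are excluded exactly per the rule", {
  # hand-built dataset: site U has an inhibitor effect interval spanning
  # zero; site C has a clear decrease
  times <- c(0, 10, 20)
  mk <- function(site, mu_ctrl, mu_inh, sd) rbind(
    site_raw(site, sub("_s1", "", site), mu_ctrl, times = times,
             sd = sd, seed = 8, condition = "control"),
    site_raw(site, sub("_s1", "", site), mu_inh, times = times,
             sd = sd, seed = 9, condition = "inhibitor"))
  raw <- rbind(mk("U_s1", c(1, 1, 1), c(1, 1, 1.001), sd = 0.3),
               mk("C_s1", c(1, 1.5, 2), c(1, 1.1, 1.2), sd = 0.01))
  ds <- filter_sites(raw)
  b_u <- ds$summary[ds$summary$site == "U_s1", ]
  # confirm the construction: U's interval spans zero at 20 min
  du <- b_u$mean[b_u$condition == "inhibitor" & b_u$time == 20] -
    b_u$mean[b_u$condition == "control" & b_u$time == 20]
  su <- sqrt(sum(b_u$sem[b_u$time == 20]^2))
  expect_true(du - su < 0 && du + su > 0)

  # on the synthetic world, every site whose observed interval spans
  # zero must be ignored, and only those (among sites with data)
  w <- w_shared
  rep <- predict_inhibition(w$ex, condition(clamps = c(AKT1 = 0.1)),
                            w$tr$dataset)
  for (i in seq_len(nrow(rep$per_site))) {
    s <- rep$per_site$site[i]
    sm <- w$tr$dataset$summary
    bc <- sm[sm$site == s & sm$condition == "control" & sm$time == 20, ]
    bi <- sm[sm$site == s & sm$condition == "inhibitor" & sm$time == 20, ]
    d <- bi$mean - bc$mean
    se <- sqrt(bi$sem^2 + bc$sem^2)
    spans <- d - se < 0 && d + se > 0
    if (spans) {
      expect_identical(rep$per_site$status[i], "unclear observed effect")
    } else if (bi$n >= 2) {
      expect_identical(rep$per_site$status[i], "evaluable")
    }
  }
})

test_that("T2D propagation yields unit fold changes for a null condition", {
  w <- w_shared
  fc <- t2d_propagate(w$ex, condition())
  expect_true(all(abs(fc - 1) < 1e-6))
})

test_that("reduced receptor availability propagates with motif-consistent signs", {
  w <- w_shared
  fc <- t2d_propagate(w$ex, t2d_demo_condition())
  expect_true(length(fc) > 0)
  expect_true(all(is.finite(fc)))
  # phosphorylation motifs directly fed by the weakened insulin arm go
  # down; dephosphorylation motifs on the same inputs go up
  for (s in names(w$ex$sites)) {
    cand <- w$ex$sites[[s]]
    if (!all(cand$input_nodes %in% c("INSR", "AKT1"))) next
    if (cand$family %in% c("phos", "satphos", "extra"))
      expect_lt(fc[[s]], 1 + 1e-6)
    if (cand$family == "dephos") expect_gt(fc[[s]], 1 - 1e-6)
  }
  expect_true(any(fc < 0.99))

  # perturbing only the GLUT4 pool leaves sites on other branches alone
  fc_g4 <- t2d_propagate(w$ex, condition(initial_scalings =
                                           c(GLUT4 = 0.5)))
  feeds_from <- function(cand, root) {
    q <- cand$input_nodes; seen <- character()
    while (length(q)) {
      n <- q[1]; q <- q[-1]
      if (n %in% seen) next
      seen <- c(seen, n)
      if (n == root) return(TRUE)
      if (n %in% names(w$ex$sites))
        q <- c(q, w$ex$sites[[n]]$input_nodes)
    }
    FALSE
  }
  downstream_of_glut4 <- vapply(w$ex$sites, feeds_from, TRUE,
                                root = "SLC2A4")
  expect_true(all(abs(fc_g4[!downstream_of_glut4] - 1) < 1e-6))
})

test_that("fold changes are invariant to site processing order", {
  w <- w_shared
  fc1 <- t2d_propagate(w$ex, t2d_demo_condition())
  fc2 <- t2d_propagate(w$ex, t2d_demo_condition())
  expect_identical(fc1, fc2)
})
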