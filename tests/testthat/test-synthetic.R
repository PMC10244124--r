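test_that("the generator is deterministic and honors its dials", {
  sp <- truth_spec(n_proteins = 6, tiers = 2, seed = 41)
  t1 <- generate_truth(sp)
  t2 <- generate_truth(sp)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_phospho_csv(t1$raw, f1); write_phospho_csv(t2$raw, f2)
  expect_identical(readLines(f1), readLines(f2))

  # decoy ratio 0: only true edges
  t0 <- generate_truth(truth_spec(n_proteins = 6, tiers = 2,
                                  decoy_ratio = 0, seed = 41))
  expect_equal(nrow(t0$interactions), nrow(t0$true_edges))

  # unsatisfiable spec
  expect_error(truth_spec(n_proteins = 2, tiers = 5))
})

test_that("replicate means converge to the noise-free simulation as CV -> 0", {
  sp <- truth_spec(n_proteins = 5, tiers = 1, cv = 1e-8,
                   noise_floor = 1e-9, seed = 43)
  tr <- generate_truth(sp)
  sm <- tr$dataset$summary
  for (p in names(tr$truth)) {
    t <- tr$truth[[p]]
    b <- sm[sm$site == t$site & sm$condition == "control", ]
    # recompute the noise-free trajectory through the same machinery
    # used by the generator is circular; instead check replicates agree
    raw <- tr$raw[tr$raw$site == t$site & tr$raw$condition == "control", ]
    spread <- tapply(raw$value, raw$time_min, function(v) diff(range(v)))
    expect_lt(max(spread), 1e-6)
  }
})

test_that("replicate noise is calibrated to the requested CV", {
  sp <- truth_spec(seed = 47)  # defaults: CV 5%
  tr <- generate_truth(sp)
  raw <- tr$raw[tr$raw$condition == "control" &
                  tr$raw$site %in% vapply(tr$truth, `[[`, "", "site"), ]
  est <- by(raw, list(raw$site, raw$time_min), function(d) {
    mu <- mean(d$value)
    c(sd = sd(d$value), expected = max(sp$noise_floor, sp$cv * abs(mu)))
  })
  m <- do.call(rbind, as.list(est))
  # pooled ratio of empirical to specified sd within 10%
  ratio <- sqrt(mean(m[, "sd"]^2) / mean(m[, "expected"]^2))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("responder labels cover exactly the motif-generated sites", {
  sp <- truth_spec(n_proteins = 6, tiers = 2, seed = 53)
  tr <- generate_truth(sp)
  resp <- names(tr$dataset$responders)[tr$dataset$responders]
  expect_setequal(resp, vapply(tr$truth, `[[`, "", "site"))
  nonresp <- names(tr$dataset$responders)[!tr$dataset$responders]
  expect_setequal(nonresp, tr$noise_sites)
})

test_that("generated networks are feed-forward by construction", {
  tr <- generate_truth(truth_spec(n_proteins = 9, tiers = 3, seed = 59))
  tier <- vapply(tr$truth, `[[`, 0L, "tier")
  for (p in names(tr$truth)) {
    for (par in tr$truth[[p]]$parents) {
      par_tier <- if (par %in% names(tier)) tier[[par]] else 0L
      expect_lt(par_tier, tier[[p]])
    }
  }
})

test_that("recovery metrics match hand-counted values on a worked fixture", {
  # five true sites, one noise site; a fake expansion accepting four
  # sites: three with a true edge, one noise site with a decoy edge
  truth <- list(
    truth = list(
      A = list(site = "A_s1", protein = "A", tier = 1L, family = "phos",
               parents = "INSR"),
      B = list(site = "B_s1", protein = "B", tier = 1L,
               family = "dephos", parents = "AKT1"),
      C = list(site = "C_s1", protein = "C", tier = 2L, family = "phos",
               parents = "A"),
      D = list(site = "D_s1", protein = "D", tier = 2L,
               family = "extra", parents = "B"),
      E = list(site = "E_s1", protein = "E", tier = 3L, family = "phos",
               parents = "C")),
    noise_sites = "N_s1")
  mk_cand <- function(site, src, family, layer) list(
    site = site, family = family, layer = layer,
    edges = data.frame(source = src, target = sub("_s1", "", site)))
  fake <- structure(list(sites = list(
    A_s1 = mk_cand("A_s1", "INSR", "phos", 1L),
    B_s1 = mk_cand("B_s1", "AKT1", "phos", 1L),   # wrong family
    C_s1 = mk_cand("C_s1", "PDE3B", "phos", 2L),  # decoy edge
    N_s1 = mk_cand("N_s1", "AKT1", "phos", 2L))), # noise site
    class = "expanded_model")
  sc <- score_recovery(fake, truth)
  expect_equal(sc$site_recall, 3 / 5)      # A, B, C of 5 true sites
  expect_equal(sc$edge_precision, 2 / 4)   # A, B of 4 accepted
  expect_equal(sc$motif_accuracy, 1 / 2)   # A correct, B wrong family
  expect_equal(sc$n_true_accepted, 3)

  # identity: re-encoding the truth gives perfect scores
  perfect <- structure(list(sites = list(
    A_s1 = mk_cand("A_s1", "INSR", "phos", 1L),
    B_s1 = mk_cand("B_s1", "AKT1", "dephos", 1L),
    C_s1 = mk_cand("C_s1", "A", "phos", 2L),
    D_s1 = mk_cand("D_s1", "B", "extra", 2L),
    E_s1 = mk_cand("E_s1", "C", "phos", 3L))),
    class = "expanded_model")
  sp <- score_recovery(perfect, truth)
  expect_equal(sp$site_recall, 1)
  expect_equal(sp$edge_precision, 1)
  expect_equal(sp$motif_accuracy, 1)
  expect_equal(sp$layer_agreement, 1)

  # core-only expansion: recall zero
  none <- structure(list(sites = list()), class = "expanded_model")
  expect_equal(score_recovery(none, truth)$site_recall, 0)

  # foreign sites are rejected
  alien <- structure(list(sites = list(
    Z_s1 = mk_cand("Z_s1", "INSR", "phos", 1L))),
    class = "expanded_model")
  expect_error(score_recovery(alien, truth), "mismatched site universes")
})

test_that("the null generator produces structure-free, filterable data", {
  nl <- generate_null_data(n_sites = 5, seed = 61)
  expect_equal(length(unique(nl$dataset$summary$site)), 5)
  expect_true(all(nl$interactions$n_primary_sources >= 1))
  expect_true(all(nl$interactions$source %in%
                    names(nl$core$activity)))
  nl2 <- generate_null_data(n_sites = 5, seed = 61)
  expect_identical(nl$raw, nl2$raw)
})
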