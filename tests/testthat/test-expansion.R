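fast_cfg <- function(seed = 1, ...) {
  expand_config(budget = 500, restarts = 2, seed = seed, ...)
}

# frozen upstream nodes on the default grid: one fast riser, one slow,
# one flat decoy
toy_nodes <- function(grid) {
  mk <- function(f) {
    vals <- f(c(grid$t0, grid$ends))
    list(mid = f(grid$mids), t0 = vals[1], path = vals)
  }
  list(
    A = c(mk(function(t) 1 - exp(-0.8 * t)), protein = "A"),
    B = c(mk(function(t) 1 - exp(-0.08 * t)), protein = "B"),
    D = c(mk(function(t) rep(0.4, length(t))), protein = "D"))
}

edge_row <- function(source, target, sign = "",
                     n = 10L) {
  interaction_list(data.frame(source = source, target = target,
                              sign = sign, n_primary_sources = n))[1, ]
}

test_that("adjacency respects model membership, confidence and exclusions", {
  il <- interaction_list(data.frame(
    source = c("A", "C"), target = c("B", "D"), sign = "",
    n_primary_sources = c(3L, 9L)))
  sp <- c(Bs = "B", Ds = "D")
  adj <- find_adjacent("A", il, 3, c("Bs", "Ds"), sp)
  expect_identical(names(adj), "Bs")
  expect_length(find_adjacent("A", il, 9, c("Bs", "Ds"), sp), 0)
  # already-added sites are simply not offered
  expect_length(find_adjacent("A", il, 3, "Ds", sp), 0)
})

test_that("a single-input motif is recovered from its own simulation", {
  times <- default_times()
  grid <- motif_grid(times)
  nodes <- toy_nodes(grid)
  kin <- c(1.5, 0.4); a_true <- 2; b_true <- 0.5
  mp <- motif_path("phos", kin, list(nodes$A$mid), nodes$A$t0, grid)
  y <- a_true * mp$at_data + b_true
  sem <- rep(0.02, length(y))
  cfg <- fast_cfg()
  cand <- test_single("Bs", edge_row("A", "B", "+"), nodes, y, sem,
                      seq_along(y), grid, cfg, seed = 11)
  expect_true(cand$accepted)
  expect_lt(cand$v, 1)
  expect_identical(cand$family, "phos")

  # an uncorrelated slow decoy input fits the same data worse
  cand_d <- test_single("Bs", edge_row("B", "B2", "+"), nodes, y, sem,
                        seq_along(y), grid, cfg, seed = 11)
  expect_gt(cand_d$v, cand$v)
})

test_that("constant data is explained with a vanishing input weight", {
  times <- default_times()
  grid <- motif_grid(times)
  nodes <- toy_nodes(grid)
  y <- rep(0.5, length(times)); sem <- rep(0.01, length(y))
  cfg <- fast_cfg()
  cand <- test_single("Cs", edge_row("A", "C"), nodes, y, sem,
                      seq_along(y), grid, cfg, seed = 5)
  expect_true(cand$accepted)
  # brute-force grid over (ku, kret) with the scale profiled at its
  # optimum per point; our optimizer must not be beaten by the grid
  ks <- 10^seq(-4, 4, length.out = 25)
  grid_best <- min(vapply(ks, function(ku) {
    min(vapply(ks, function(kr) {
      mp <- motif_path("phos", c(ku, kr), list(nodes$A$mid), nodes$A$t0,
                       grid)
      affine_wls(mp$at_data, y, sem)$cost
    }, 1))
  }, 1))
  expect_lte(cand$v, grid_best + 1e-6)
})

test_that("dual-input motifs recover a phos+dephos ground truth", {
  times <- default_times()
  grid <- motif_grid(times)
  nodes <- toy_nodes(grid)
  kin <- c(2, 1.5, 0.1)
  mp <- motif_path("phosdephos", kin, list(nodes$A$mid, nodes$B$mid),
                   c(nodes$A$t0, nodes$B$t0), grid)
  y <- 1.5 * mp$at_data + 0.3
  sem <- rep(0.02, length(y))
  cfg <- fast_cfg()
  e1 <- edge_row("A", "C", "+"); e2 <- edge_row("B", "C", "-")
  cand <- test_double("Cs", e1, e2, nodes, y, sem, seq_along(y), grid,
                      cfg, seed = 9)
  expect_true(cand$accepted)
  expect_identical(cand$family, "phosdephos")
  expect_setequal(cand$input_nodes, c("A", "B"))

  cand2 <- test_double("Cs", e1, e2, nodes, y, sem, seq_along(y), grid,
                       cfg, seed = 9)
  expect_identical(cand$v, cand2$v)  # determinism
})

test_that("overshoot data needs the secondary-state chain", {
  times <- default_times()
  grid <- motif_grid(times)
  nodes <- toy_nodes(grid)
  kin <- c(3, 0.6, 0.02)  # strong drive, slow return: rise then fall
  mp <- motif_path("extra", kin, list(nodes$A$mid), nodes$A$t0, grid)
  y <- 2 * mp$at_data + 0.4
  sem <- rep(0.015, length(y))
  cfg <- fast_cfg()
  e <- edge_row("A", "E", "+")
  single <- test_single("Es", e, nodes, y, sem, seq_along(y), grid, cfg,
                        seed = 21)
  extra <- test_extra_state("Es", e, nodes, y, sem, seq_along(y), grid,
                            cfg, seed = 22)
  expect_false(single$accepted)
  expect_true(extra$accepted)
  expect_identical(extra$family, "extra")
})

test_that("data-driven scoring finds exact affine matches and ranks like brute force", {
  sp <- truth_spec(n_proteins = 4, tiers = 1, seed = 2)
  tr <- generate_truth(sp)
  grid <- motif_grid(default_times())
  core_act <- protein_activities(tr$core, NULL,
                                 sort(unique(c(grid$t0, grid$ends,
                                               grid$mids))))
  nodes <- list()
  tp <- c(grid$t0, grid$ends)
  for (p in names(tr$core$activity)) {
    v <- core_act[[p]]
    nodes[[p]] <- list(protein = p,
                       mid = v[match(grid$mids, core_act$time)],
                       t0 = v[match(grid$t0, core_act$time)],
                       path = v[match(tp, core_act$time)])
  }
  # a site whose means are exactly 2 * PKB activity + 1
  akt <- nodes$AKT1$path[match(default_times(), tp)]
  raw <- site_raw("X_s1", "PX", 2 * akt + 1, sd = 1e-9)
  ds <- filter_sites(raw, sem_floor_frac = 0.01)
  dd <- data_driven_candidates(nodes, "X_s1", ds, c(X_s1 = "PX"), grid,
                               top_k = 2)
  expect_identical(dd$source_node[dd$dd_rank == 1], "AKT1")

  # top_k beyond the node count emits every node
  dd_all <- data_driven_candidates(nodes, "X_s1", ds, c(X_s1 = "PX"),
                                   grid, top_k = 99)
  expect_equal(nrow(dd_all), length(nodes))

  # ranking agrees with independent enumeration via weighted lm
  b <- ds$summary[ds$summary$site == "X_s1", ]
  ref_cost <- vapply(names(nodes), function(n) {
    x <- nodes[[n]]$path[match(b$time, tp)]
    fit <- lm(b$mean ~ x, weights = 1 / b$sem^2)
    sum(residuals(fit)^2 / b$sem^2)
  }, 1)
  expect_identical(dd_all$source_node[order(dd_all$dd_rank)],
                   names(sort(ref_cost)))
})

test_that("maximal-model size follows the counting rule", {
  raw <- rbind(site_raw("a_s1", "A", rep(1, 9)),
               site_raw("b_s1", "B", rep(1, 9)),
               site_raw("c_s1", "C", rep(1, 9)))
  ds <- filter_sites(raw)
  il <- interaction_list(data.frame(
    source = c("A", "A", "B", "C"), target = c("B", "C", "C", "A"),
    n_primary_sources = 1L))
  expect_equal(estimate_maximal_size(il, ds),
               c(n_states = 6L, n_parameters = 7L))

  none <- interaction_list(data.frame(source = "X", target = "Y",
                                      n_primary_sources = 1L))
  expect_equal(estimate_maximal_size(none, ds),
               c(n_states = 0L, n_parameters = 0L))

  # an edge touching a protein without data is dropped with its sites
  il2 <- interaction_list(data.frame(
    source = c("A", "A"), target = c("B", "Z"),
    n_primary_sources = 1L))
  expect_equal(estimate_maximal_size(il2, ds),
               c(n_states = 2L, n_parameters = 2L))
})

test_that("expansion on a small truth is deterministic and invariant-clean", {
  sp <- truth_spec(n_proteins = 6, tiers = 2, seed = 19)
  tr <- generate_truth(sp)
  cfg <- fast_cfg(seed = 19)
  ex1 <- expand_model(tr$core, tr$dataset, tr$interactions, cfg)
  ex2 <- expand_model(tr$core, tr$dataset, tr$interactions, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_expanded(ex1, d1); write_expanded(ex2, d2)
  expect_identical(readLines(file.path(d1, "layers.json")),
                   readLines(file.path(d2, "layers.json")))

  expect_true(verify_feed_forward(ex1))
  expect_true(verify_acceptance(ex1, tr$dataset))

  # retest economy: no (site, stage, edge set) fitted twice
  key <- paste(ex1$ledger$site, ex1$ledger$stage, ex1$ledger$edges)
  expect_false(anyDuplicated(key) > 0)

  # confidence monotonicity within each phase
  for (ph in unique(vapply(ex1$layers, `[[`, "", "phase"))) {
    lv <- vapply(Filter(function(l) l$phase == ph, ex1$layers),
                 function(l) as.numeric(l$level), 1)
    if (length(lv) > 1) expect_true(all(diff(lv) <= 0))
  }

  # empty interactions and no data-driven phase: core only
  empty_il <- interaction_list(data.frame(source = character(),
                                          target = character()))
  ex0 <- expand_model(tr$core, tr$dataset, empty_il,
                      fast_cfg(seed = 19,
                               phases = c("responders", "all-data")))
  expect_length(ex0$sites, 0)
  expect_length(ex0$layers, 0)
})

test_that("serialized expansions reload into equivalent models", {
  sp <- truth_spec(n_proteins = 5, tiers = 1, seed = 23)
  tr <- generate_truth(sp)
  ex <- expand_model(tr$core, tr$dataset, tr$interactions,
                     fast_cfg(seed = 23))
  d <- withr::local_tempdir()
  write_expanded(ex, d)
  ex2 <- read_expanded(d)
  expect_setequal(names(ex2$sites), names(ex$sites))
  s1 <- simulate_expanded(ex, NULL, c(0, 5, 20))
  s2 <- simulate_expanded(ex2, NULL, c(0, 5, 20))
  expect_equal(s2$site_obs, s1$site_obs, tolerance = 1e-6)
})
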