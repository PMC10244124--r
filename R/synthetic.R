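#' Specification of a synthetic ground truth
#'
#' Describes the benchmark world the generator builds: a feed-forward
#' network of phosphoproteins rooted at the demo core's
#' insulin-responsive branch, simulated through the package's own kinetic
#' motifs, observed on a sparse time grid with replicate Gaussian noise,
#' and accompanied by a confidence-graded edge list in which true edges
#' draw high primary-source counts and decoys low ones (with overlap, so
#' the confidence descent matters).
#'
#' @param n_proteins number of true phosphoproteins (one site each).
#' @param tiers intended depth (layers) of the true network.
#' @param family_mix sampling probabilities over motif families.
#' @param decoy_ratio decoy edges per true edge.
#' @param true_conf,decoy_conf inclusive integer ranges of
#'   `n_primary_sources` for true/decoy edges.
#' @param times sampling grid in minutes (stimulus at t = 0).
#' @param replicates replicates per (site, time).
#' @param cv replicate noise coefficient of variation (sd = cv * |signal|).
#' @param noise_floor absolute noise floor.
#' @param responder_fraction fraction of all sites that are responders
#'   (true sites); the remainder are nonresponder sites whose means are
#'   time-point-wise random (no motif structure).
#' @param inhib_node,inhib_factor core node clamped for the inhibitor
#'   block and its clamp factor.
#' @param seed master seed.
#' @return a `truth_spec` list.
#' @export
truth_spec <- function(n_proteins = 30L, tiers = 3L,
                       family_mix = c(phos = 0.45, dephos = 0.2,
                                      satphos = 0.1, phos2 = 0.1,
                                      extra = 0.15),
                       decoy_ratio = 1, true_conf = c(5L, 20L),
                       decoy_conf = c(1L, 8L),
                       times = c(0, 0.25, 0.5, 1, 2, 5, 10, 20, 60),
                       replicates = 3L, cv = 0.05, noise_floor = 0.01,
                       responder_fraction = 0.6,
                       inhib_node = "AKT1", inhib_factor = 0.1,
                       seed = 1L) {
  stopifnot(abs(sum(family_mix) - 1) < 1e-8, cv > 0, tiers >= 1,
            n_proteins >= tiers, replicates >= 2,
            responder_fraction > 0, responder_fraction <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 tiers = as.integer(tiers), family_mix = family_mix,
                 decoy_ratio = decoy_ratio, true_conf = true_conf,
                 decoy_conf = decoy_conf, times = times,
                 replicates = as.integer(replicates), cv = cv,
                 noise_floor = noise_floor,
                 responder_fraction = responder_fraction,
                 inhib_node = inhib_node, inhib_factor = inhib_factor,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

sample_kin <- function(family) {
  ku <- 10^stats::runif(1, -0.5, 0.7)
  kret <- 10^stats::runif(1, -1, 0.3)
  switch(family,
    phos = c(ku, kret),
    dephos = c(kret, ku),
    satphos = c(ku, 10^stats::runif(1, -1, 0.5), kret),
    phos2 = c(ku, 10^stats::runif(1, -0.5, 0.7), kret),
    dephos2 = c(kret, ku, 10^stats::runif(1, -0.5, 0.7)),
    phosdephos = c(ku, 10^stats::runif(1, -0.5, 0.7), kret),
    extra = c(ku, 10^stats::runif(1, -1, 0.3), kret))
}

#' Generate a synthetic ground truth
#'
#' Builds the network described by `spec`, simulates every true site
#' through its motif driven by the demo core under an insulin step,
#' draws replicate data with additive Gaussian noise, emits the edge
#' list (true edges plus decoys with assigned confidence counts), and an
#' inhibitor block obtained by clamping `spec$inhib_node` and
#' re-simulating. Deterministic given `spec$seed`.
#'
#' @param spec a [truth_spec()].
#' @return list: `truth` (per-site tier, family, parents, parameters),
#'   `interactions` ([interaction_list()]), `raw` (long replicate table),
#'   `dataset` (filtered `phospho_dataset` incl. the inhibitor block),
#'   `core` (the demo core).
#' @export
generate_truth <- function(spec) {
  core <- build_demo_core()
  grid <- motif_grid(spec$times)
  tp <- c(grid$t0, grid$ends)
  sim_times <- sort(unique(c(tp, grid$mids)))
  resp_core <- c("INSR", "AKT1", "PDE3B", "SLC2A4")

  core_nodes <- function(clamps = numeric()) {
    cond <- if (length(clamps)) condition(clamps = clamps) else NULL
    act <- protein_activities(core, cond, sim_times)
    nodes <- list()
    for (p in names(core$activity)) {
      f <- if (p %in% names(clamps)) clamps[[p]] else 1
      v <- act[[p]] * f
      nodes[[p]] <- list(protein = p,
                         mid = v[match(grid$mids, act$time)],
                         t0 = v[match(grid$t0, act$time)],
                         path = v[match(tp, act$time)])
    }
    nodes
  }

  with_seed(spec$seed, {
    np <- spec$n_proteins
    prot <- sprintf("TP%02d", seq_len(np))
    # balanced tier assignment, every tier non-empty
    tier <- sort(rep_len(seq_len(spec$tiers), np))
    fam_pool <- names(spec$family_mix)
    truth <- list()
    for (i in seq_len(np)) {
      parents_pool <- if (tier[i] == 1) resp_core
                      else prot[tier == tier[i] - 1]
      fam <- sample(fam_pool, 1, prob = spec$family_mix)
      need2 <- motif_families()$n_inputs[motif_families()$family == fam] == 2
      if (need2 && length(parents_pool) < 2)
        fam <- "phos"  # degenerate pool: fall back to one input
      need2 <- motif_families()$n_inputs[motif_families()$family == fam] == 2
      parents <- sample(parents_pool, if (need2) 2 else 1)
      truth[[prot[i]]] <- list(
        protein = prot[i], site = paste0(prot[i], "_s1"),
        tier = tier[i], family = fam, parents = parents,
        kin = sample_kin(fam),
        a = stats::runif(1, 0.5, 3), b = stats::runif(1, 0.2, 1))
    }

    simulate_truth <- function(nodes) {
      for (i in order(tier)) {
        tr <- truth[[prot[i]]]
        mp <- motif_path(tr$family, tr$kin,
                         lapply(tr$parents, function(p) nodes[[p]]$mid),
                         vapply(tr$parents, function(p) nodes[[p]]$t0,
                                numeric(1)), grid)
        vals <- c(mp$P0, mp$path)
        nodes[[tr$protein]] <- list(
          protein = tr$protein,
          mid = stats::approx(tp, vals, xout = grid$mids)$y,
          t0 = mp$P0, path = vals)
      }
      nodes
    }
    nodes_ctrl <- simulate_truth(core_nodes())
    cl <- stats::setNames(spec$inhib_factor, spec$inhib_node)
    nodes_inh <- simulate_truth(core_nodes(cl))

    n_noise <- max(0L, round(np * (1 - spec$responder_fraction) /
                               spec$responder_fraction))
    noise_prot <- if (n_noise) sprintf("NP%02d", seq_len(n_noise))
                  else character()
    noise_means <- lapply(seq_len(n_noise), function(i)
      stats::rnorm(length(spec$times), 1, 0.3))

    draw_reps <- function(mu) {
      sd <- pmax(spec$noise_floor, spec$cv * abs(mu))
      vapply(seq_len(spec$replicates), function(r)
        mu + stats::rnorm(length(mu), 0, sd), numeric(length(mu)))
    }
    rows <- list()
    add_block <- function(site, protein, condvals, condname, responder) {
      reps <- draw_reps(condvals)
      for (r in seq_len(ncol(reps))) {
        rows[[length(rows) + 1L]] <<- data.frame(
          site = site, protein = protein, condition = condname,
          time_min = spec$times, replicate = r, value = reps[, r],
          responder = responder)
      }
    }
    data_idx <- match(spec$times, c(grid$t0, grid$ends))
    for (p in prot) {
      tr <- truth[[p]]
      y_ctrl <- tr$a * nodes_ctrl[[p]]$path[data_idx] + tr$b
      y_inh <- tr$a * nodes_inh[[p]]$path[data_idx] + tr$b
      add_block(tr$site, p, y_ctrl, "control", TRUE)
      add_block(tr$site, p, y_inh, "inhibitor", TRUE)
    }
    for (i in seq_len(n_noise)) {
      site <- paste0(noise_prot[i], "_s1")
      add_block(site, noise_prot[i], noise_means[[i]], "control", FALSE)
      add_block(site, noise_prot[i], noise_means[[i]], "inhibitor", FALSE)
    }
    raw <- do.call(rbind, rows)
    rownames(raw) <- NULL

    # edge list: true edges with high confidence counts, decoys low
    erows <- list()
    for (p in prot) {
      tr <- truth[[p]]
      fam_type <- motif_families()$type[motif_families()$family ==
                                          tr$family]
      for (j in seq_along(tr$parents)) {
        sgn <- if (tr$family == "phosdephos") {
          if (j == 1) "+" else "-"
        } else if (fam_type == "dephos") "-" else "+"
        erows[[length(erows) + 1L]] <- data.frame(
          source = tr$parents[j], target = p, sign = sgn,
          n_primary_sources = sample(spec$true_conf[1]:spec$true_conf[2],
                                     1))
      }
    }
    true_edges <- do.call(rbind, erows)
    # decoys: model-protein -> non-downstream protein, never duplicating
    # a true edge
    desc <- list()
    all_prot <- c(resp_core, prot)
    children <- split(true_edges$target, true_edges$source)
    descendants <- function(p) {
      out <- character(); queue <- p
      while (length(queue)) {
        q <- queue[1]; queue <- queue[-1]
        ch <- setdiff(children[[q]], out)
        out <- c(out, ch); queue <- c(queue, ch)
      }
      out
    }
    true_key <- paste(true_edges$source, true_edges$target)
    n_decoy <- round(spec$decoy_ratio * nrow(true_edges))
    drows <- list(); tries <- 0L
    targets_all <- c(prot, noise_prot)
    while (length(drows) < n_decoy && tries < 50L * n_decoy + 100L) {
      tries <- tries + 1L
      src <- sample(all_prot, 1)
      tgt <- sample(setdiff(targets_all, c(src, descendants(src))), 1)
      if (paste(src, tgt) %in% true_key) next
      if (any(vapply(drows, function(d)
        d$source == src && d$target == tgt, TRUE))) next
      drows[[length(drows) + 1L]] <- data.frame(
        source = src, target = tgt, sign = "",
        n_primary_sources = sample(spec$decoy_conf[1]:spec$decoy_conf[2],
                                   1))
    }
    edges <- rbind(true_edges,
                   if (length(drows)) do.call(rbind, drows))
    il <- interaction_list(edges)

    list(truth = truth, interactions = il, raw = raw,
         dataset = filter_sites(raw), core = core,
         true_edges = true_edges, spec = spec,
         noise_sites = if (n_noise) paste0(noise_prot, "_s1")
                       else character())
  })
}

#' Generate a pure-noise dataset with decoy edges
#'
#' The negative control for the acceptance gate: sites whose mean
#' trajectory is an independent random draw at every time point (no
#' kinetic structure, tight replicate noise), each wired to the core by
#' decoy edges only. A sound chi-squared gate should accept almost none
#' of these candidates.
#'
#' @param n_sites number of noise sites.
#' @param edges_per_site decoy edges per site (sources drawn from the
#'   demo core's proteins).
#' @param times sampling grid (minutes).
#' @param replicates replicates per time point.
#' @param cv replicate noise coefficient of variation.
#' @param noise_floor absolute replicate noise floor.
#' @param mean_sd spread of the random site means around 1.
#' @param seed master seed.
#' @return list: `raw`, `dataset`, `interactions`, `core`.
#' @export
generate_null_data <- function(n_sites = 50L, edges_per_site = 2L,
                               times = c(0, 0.25, 0.5, 1, 2, 5, 10, 20,
                                         60),
                               replicates = 3L, cv = 0.05,
                               noise_floor = 0.01, mean_sd = 0.3,
                               seed = 1L) {
  core <- build_demo_core()
  core_prot <- names(core$activity)
  with_seed(seed, {
    prot <- sprintf("NP%02d", seq_len(n_sites))
    rows <- list(); erows <- list()
    for (i in seq_len(n_sites)) {
      mu <- stats::rnorm(length(times), 1, mean_sd)
      sd <- pmax(noise_floor, cv * abs(mu))
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site = paste0(prot[i], "_s1"), protein = prot[i],
          condition = "control", time_min = times, replicate = r,
          value = mu + stats::rnorm(length(mu), 0, sd),
          responder = FALSE)
      }
      for (src in sample(core_prot, min(edges_per_site,
                                        length(core_prot)))) {
        erows[[length(erows) + 1L]] <- data.frame(
          source = src, target = prot[i], sign = "",
          n_primary_sources = sample(1:8, 1))
      }
    }
    raw <- do.call(rbind, rows)
    rownames(raw) <- NULL
    list(raw = raw, dataset = filter_sites(raw),
         interactions = interaction_list(do.call(rbind, erows)),
         core = core)
  })
}

#' Score an expansion against its generating truth
#'
#' @param expanded an `expanded_model` produced from the truth's inputs.
#' @param truth the output of [generate_truth()].
#' @return list: `site_recall` (true sites accepted / true sites),
#'   `edge_precision` (accepted additions using >= 1 true edge / accepted
#'   additions), `motif_accuracy` (family match among correctly-edged
#'   true additions), `layer_agreement` (Spearman correlation between
#'   true tier and assigned layer), and the underlying counts.
#' @export
score_recovery <- function(expanded, truth) {
  true_sites <- vapply(truth$truth, `[[`, "", "site")
  universe <- c(true_sites, truth$noise_sites)
  acc <- names(expanded$sites)
  if (length(setdiff(acc, universe)))
    stop("mismatched site universes: expansion contains sites not in the truth",
         call. = FALSE)
  recall <- if (length(true_sites))
    length(intersect(acc, true_sites)) / length(true_sites) else NA_real_
  true_parent <- lapply(truth$truth, `[[`, "parents")
  names(true_parent) <- true_sites
  uses_true_edge <- vapply(acc, function(s) {
    if (!s %in% true_sites) return(FALSE)
    srcs <- expanded$sites[[s]]$edges$source
    any(srcs %in% true_parent[[s]])
  }, TRUE)
  precision <- if (length(acc)) mean(uses_true_edge) else NA_real_
  fam_by_site <- vapply(truth$truth, `[[`, "", "family")
  names(fam_by_site) <- true_sites
  good <- acc[uses_true_edge]
  motif_acc <- if (length(good))
    mean(vapply(good, function(s)
      expanded$sites[[s]]$family == fam_by_site[[s]], TRUE))
    else NA_real_
  tier_by_site <- vapply(truth$truth, `[[`, 0L, "tier")
  names(tier_by_site) <- true_sites
  tacc <- intersect(acc, true_sites)
  layer_agree <- if (length(tacc) >= 3) {
    tiers <- tier_by_site[tacc]
    lays <- vapply(tacc, function(s) expanded$sites[[s]]$layer, 0L)
    if (stats::sd(tiers) > 0 && stats::sd(lays) > 0)
      suppressWarnings(stats::cor(tiers, lays, method = "spearman"))
    else NA_real_
  } else NA_real_
  list(site_recall = recall, edge_precision = precision,
       motif_accuracy = motif_acc, layer_agreement = layer_agree,
       n_true = length(true_sites), n_accepted = length(acc),
       n_true_accepted = length(tacc))
}
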