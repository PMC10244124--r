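#' Expansion configuration
#'
#' Settings for the layered expansion engine.
#'
#' @param df degrees of freedom of the per-site chi-squared gate.
#' @param alpha significance level.
#' @param budget objective evaluations per motif-family fit.
#' @param restarts optimizer restarts within the budget.
#' @param seed master seed; per-site seeds derive from it and a stable
#'   site hash, so results do not depend on scheduling.
#' @param phases which phases to run, in order.
#' @param top_k data-driven candidate edges kept per unadded site.
#' @param dt_max,min_sub integration grid refinement (see [motif_grid()]).
#' @param jobs parallel workers for the pairwise tests within a sweep.
#' @param use_sign restrict motif families by the edge sign when present.
#' @param kin_bounds kinetic-parameter bounds (natural scale).
#' @param scale_bounds observable scale-parameter bounds (linear space).
#' @return a named list.
#' @export
expand_config <- function(df = 8, alpha = 0.05, budget = 2000, restarts = 3,
                          seed = 1L,
                          phases = c("responders", "all-data", "data-driven"),
                          top_k = 3L, dt_max = 0.5, min_sub = 4L,
                          jobs = 1L, use_sign = TRUE,
                          kin_bounds = c(1e-4, 1e4),
                          scale_bounds = c(0, 100)) {
  stopifnot(df >= 1, alpha > 0, alpha < 1, budget > 0, restarts >= 1)
  list(df = df, alpha = alpha, budget = budget, restarts = restarts,
       seed = as.integer(seed), phases = phases, top_k = as.integer(top_k),
       dt_max = dt_max, min_sub = as.integer(min_sub),
       jobs = as.integer(jobs), use_sign = use_sign,
       kin_bounds = kin_bounds, scale_bounds = scale_bounds)
}

stable_hash <- function(s) {
  # order-independent across platforms; stays below 2^31
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Sites adjacent to the model at a confidence level
#'
#' A site is adjacent iff its protein is the target of at least one edge
#' with `n_primary_sources >= level` whose source protein is already in
#' the model; sites already added are excluded. At the pseudo-level
#' `"data-driven"` only data-driven edges count, matched to the site they
#' were generated for.
#'
#' @param model_proteins character vector of proteins in core + layers.
#' @param interactions an [interaction_list()].
#' @param level integer confidence level or `"data-driven"`.
#' @param unadded_sites candidate site ids.
#' @param site_proteins named character: site -> protein.
#' @return named list: site -> data.frame of candidate edges (canonical
#'   order: descending confidence, then source name).
#' @export
find_adjacent <- function(model_proteins, interactions, level,
                          unadded_sites, site_proteins) {
  il <- interactions
  if (identical(level, "data-driven")) {
    il <- il[il$origin == "data-driven" & il$source %in% model_proteins, ,
             drop = FALSE]
  } else {
    il <- il[il$origin == "prior-knowledge" &
             il$n_primary_sources >= level &
             il$source %in% model_proteins, , drop = FALSE]
  }
  out <- list()
  for (s in unadded_sites) {
    pr <- site_proteins[[s]]
    e <- il[il$target == pr & il$source != pr, , drop = FALSE]
    if (nrow(e))
      e <- e[is.na(e$target_site) | e$target_site == s, , drop = FALSE]
    if (nrow(e)) {
      e <- e[order(-e$n_primary_sources, e$source), , drop = FALSE]
      rownames(e) <- NULL
      out[[s]] <- e
    }
  }
  out
}

# u trajectories for a set of edges, given frozen node trajectories.
# nodes: list node_id -> list(protein, mid, t0) ; edge source protein may
# be backed by a core node (id = protein) or an added site node.
edge_node <- function(nodes, edge) {
  if (!is.na(edge$source_node) && edge$source_node %in% names(nodes))
    return(edge$source_node)
  if (edge$source %in% names(nodes)) return(edge$source)
  # earliest-added site node of that protein (canonical: storage order)
  for (n in names(nodes)) if (nodes[[n]]$protein == edge$source) return(n)
  NA_character_
}

fit_motif <- function(family, u_mid, u0, y, sem, out_idx, grid, config,
                      seed) {
  fam <- motif_families()
  nk <- fam$n_kin[fam$family == family]
  lk <- log10(config$kin_bounds[1]); uk <- log10(config$kin_bounds[2])
  # only the kinetic parameters are searched; the observable mapping
  # y = a*P + b is a weighted least-squares subproblem solved in closed
  # form at every evaluation, with the slope clamped to its bounds
  # (a >= 0 keeps the motif's direction semantics)
  scale_fit <- function(p) {
    w <- affine_wls(p, y, sem)
    a <- min(max(w$a, config$scale_bounds[1]), config$scale_bounds[2])
    if (a != w$a) w <- affine_wls(p, y, sem, a = a)
    w
  }
  obj <- function(theta) {
    mp <- motif_path(family, 10^theta, u_mid, u0, grid)
    p <- mp$at_data[out_idx]
    if (any(!is.finite(p))) return(Inf)
    scale_fit(p)$cost
  }
  fr <- fit_global(obj, rep(lk, nk), rep(uk, nk),
                   budget = config$budget,
                   restarts = config$restarts, seed = seed)
  kin <- 10^fr$par
  mp <- motif_path(family, kin, u_mid, u0, grid)
  p <- mp$at_data[out_idx]
  if (any(!is.finite(p)))
    return(list(family = family, v = Inf, kin = kin, a = NA_real_,
                b = NA_real_, evals = fr$evals, seed = seed))
  w <- scale_fit(p)
  v <- if (is.finite(w$cost)) w$cost else Inf
  list(family = family, v = v, kin = kin, a = w$a, b = w$b,
       evals = fr$evals, seed = seed)
}

pick_best <- function(fits) {
  # lowest cost; ties (within 1e-9) broken by fewer parameters, then the
  # family order of motif_families()
  fam <- motif_families()
  ord <- order(vapply(fits, `[[`, 0, "v"),
               vapply(fits, function(f)
                 fam$n_kin[fam$family == f$family], 0L),
               vapply(fits, function(f)
                 match(f$family, fam$family), 0L))
  fits[[ord[1]]]
}

allowed_single <- function(sign, use_sign) {
  fam <- motif_families()
  f <- fam$family[fam$stage == "single"]
  if (!use_sign || is.na(sign) || sign == "") return(f)
  if (sign == "+") fam$family[fam$stage == "single" & fam$type == "phos"]
  else fam$family[fam$stage == "single" & fam$type == "dephos"]
}

candidate_skeleton <- function(site, edges, df, threshold) {
  list(site = site, edges = edges, family = NA_character_, v = Inf,
       kin = numeric(), a = NA_real_, b = NA_real_, accepted = FALSE,
       df = df, threshold = threshold, input_nodes = character())
}

#' Test a single-input attachment of a site
#'
#' Fits the allowed single-input motif families (phosphorylation,
#' dephosphorylation, saturated phosphorylation; restricted by the edge
#' sign when `use_sign`) with the upstream node's frozen trajectory as
#' forcing, keeps the family with the lowest cost, and accepts iff
#' `v* < chi2_threshold(df, alpha)`.
#'
#' @param site site id.
#' @param edge one-row edge data.frame.
#' @param nodes frozen node trajectories (internal format).
#' @param y,sem data means/SEMs at the site's data times.
#' @param out_idx index of the site's data times into the grid values.
#' @param grid a [motif_grid()].
#' @param config an [expand_config()].
#' @param seed fit seed.
#' @return an addition candidate (list; `accepted`, `v`, `family`, ...).
#' @export
test_single <- function(site, edge, nodes, y, sem, out_idx, grid, config,
                        seed) {
  thr <- chi2_threshold(config$df, config$alpha)
  cand <- candidate_skeleton(site, edge, config$df, thr)
  nid <- edge_node(nodes, edge)
  if (is.na(nid)) return(cand)
  nd <- nodes[[nid]]
  fams <- allowed_single(edge$sign, config$use_sign)
  fits <- lapply(seq_along(fams), function(i)
    fit_motif(fams[i], list(nd$mid), nd$t0, y, sem, out_idx, grid, config,
              (seed + i * 131L) %% 2147483647L))
  best <- pick_best(fits)
  cand[c("family", "v", "kin", "a", "b")] <-
    best[c("family", "v", "kin", "a", "b")]
  cand$input_nodes <- nid
  cand$accepted <- chi2_test(best$v, config$df, config$alpha)
  cand
}

#' Test a dual-input attachment of a site
#'
#' Pairs the best (lowest-cost) rejected single edge with another
#' candidate edge and fits the two-input families (double
#' phosphorylation, double dephosphorylation, phosphorylation +
#' dephosphorylation), restricted by signs when present.
#'
#' @inheritParams test_single
#' @param edge1,edge2 one-row edge data.frames; `edge1` is the best
#'   single edge.
#' @export
test_double <- function(site, edge1, edge2, nodes, y, sem, out_idx, grid,
                        config, seed) {
  thr <- chi2_threshold(config$df, config$alpha)
  edges <- rbind(edge1, edge2)
  cand <- candidate_skeleton(site, edges, config$df, thr)
  n1 <- edge_node(nodes, edge1); n2 <- edge_node(nodes, edge2)
  if (is.na(n1) || is.na(n2)) return(cand)
  u_mid <- list(nodes[[n1]]$mid, nodes[[n2]]$mid)
  u0 <- c(nodes[[n1]]$t0, nodes[[n2]]$t0)
  s1 <- edge1$sign; s2 <- edge2$sign
  fams <- c("phos2", "dephos2", "phosdephos")
  if (config$use_sign && !is.na(s1) && !is.na(s2) &&
      s1 != "" && s2 != "") {
    fams <- if (s1 == "+" && s2 == "+") "phos2"
            else if (s1 == "-" && s2 == "-") "dephos2"
            else "phosdephos"
    if (identical(fams, "phosdephos") && s1 == "-") {
      u_mid <- rev(u_mid); u0 <- rev(u0)  # phosphorylating input first
    }
  }
  fits <- lapply(seq_along(fams), function(i)
    fit_motif(fams[i], u_mid, u0, y, sem, out_idx, grid, config,
              (seed + i * 131L) %% 2147483647L))
  best <- pick_best(fits)
  cand[c("family", "v", "kin", "a", "b")] <-
    best[c("family", "v", "kin", "a", "b")]
  cand$input_nodes <- c(n1, n2)
  cand$accepted <- chi2_test(best$v, config$df, config$alpha)
  cand
}

#' Test the secondary-state attachment of a site
#'
#' Fits the three-pool chain (unphosphorylated -> phosphorylated ->
#' secondary -> unphosphorylated), used when single and dual-input motifs
#' failed; captures overshoot-and-return kinetics such as
#' internalization.
#'
#' @inheritParams test_single
#' @export
test_extra_state <- function(site, edge, nodes, y, sem, out_idx, grid,
                             config, seed) {
  thr <- chi2_threshold(config$df, config$alpha)
  cand <- candidate_skeleton(site, edge, config$df, thr)
  nid <- edge_node(nodes, edge)
  if (is.na(nid)) return(cand)
  nd <- nodes[[nid]]
  best <- fit_motif("extra", list(nd$mid), nd$t0, y, sem, out_idx, grid,
                    config, seed)
  cand[c("family", "v", "kin", "a", "b")] <-
    best[c("family", "v", "kin", "a", "b")]
  cand$input_nodes <- nid
  cand$accepted <- chi2_test(best$v, config$df, config$alpha)
  cand
}

edge_key <- function(edge) paste(edge$source, edge$target,
                                 edge$origin, sep = ">")

# Full per-site testing cascade (Algorithm: singles in canonical edge
# order, first acceptance wins; else doubles pairing the best rejected
# single edge; else the secondary-state chain). Pure given frozen nodes.
test_site <- function(site, edges, nodes, y, sem, out_idx, grid, config,
                      tested) {
  site_seed <- (config$seed + stable_hash(site)) %% 2147483647L
  fitctr <- 0L
  nseed <- function() {
    fitctr <<- fitctr + 1L
    (site_seed + fitctr * 1009L) %% 2147483647L
  }
  ledger <- list()
  note <- function(cand, stage, keys) {
    ledger[[length(ledger) + 1L]] <<- list(cand = cand, stage = stage,
                                           keys = keys)
  }
  best_rejected <- NULL
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, , drop = FALSE]
    key <- paste(site, edge_key(e), "single", sep = "|")
    if (key %in% tested) next
    cand <- test_single(site, e, nodes, y, sem, out_idx, grid, config,
                        nseed())
    note(cand, "single", key)
    if (cand$accepted) return(list(result = cand, ledger = ledger))
    if (is.null(best_rejected) || cand$v < best_rejected$v)
      best_rejected <- cand
  }
  if (!is.null(best_rejected) && nrow(edges) >= 2) {
    e1 <- best_rejected$edges
    for (i in seq_len(nrow(edges))) {
      e2 <- edges[i, , drop = FALSE]
      if (edge_key(e2) == edge_key(e1)) next
      key <- paste(site, edge_key(e1), edge_key(e2), "double", sep = "|")
      if (key %in% tested) next
      cand <- test_double(site, e1, e2, nodes, y, sem, out_idx, grid,
                          config, nseed())
      note(cand, "double", key)
      if (cand$accepted) return(list(result = cand, ledger = ledger))
    }
  }
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, , drop = FALSE]
    if (config$use_sign && !is.na(e$sign) && e$sign == "-") next
    key <- paste(site, edge_key(e), "extra", sep = "|")
    if (key %in% tested) next
    cand <- test_extra_state(site, e, nodes, y, sem, out_idx, grid,
                             config, nseed())
    note(cand, "extra", key)
    if (cand$accepted) return(list(result = cand, ledger = ledger))
  }
  list(result = NULL, ledger = ledger)
}

node_from_candidate <- function(cand, nodes, grid, protein) {
  mp <- motif_path(cand$family, cand$kin,
                   lapply(cand$input_nodes, function(n) nodes[[n]]$mid),
                   vapply(cand$input_nodes, function(n) nodes[[n]]$t0,
                          numeric(1)),
                   grid)
  tp <- c(grid$t0, grid$ends)
  vals <- c(mp$P0, mp$path)
  list(protein = protein,
       mid = stats::approx(tp, vals, xout = grid$mids)$y,
       t0 = mp$P0, path = vals)
}

#' Layered automatic model expansion
#'
#' Grows the core model outward by attaching phosphosites through kinetic
#' motifs, gated by the chi-squared test. Phases run in order:
#' (1) responder sites against prior-knowledge edges, sweeping confidence
#' levels from the highest down; (2) all sites, same confidence descent,
#' skipping (site, edge) pairs already tested; (3) data-driven candidate
#' edges generated from the agreement between included-node simulations
#' and unadded-site data. Within a level, adjacency sweeps repeat until no
#' site is accepted; each successful sweep becomes a layer. Upstream
#' trajectories of newly added nodes are computed once per layer and
#' frozen, so all tests within a sweep are independent and the result is
#' reproducible for a given master seed.
#'
#' @param core an [ode_model()] (must simulate).
#' @param dataset a filtered `phospho_dataset`.
#' @param interactions an [interaction_list()].
#' @param config an [expand_config()].
#' @return an `expanded_model`: core, ordered `layers` (each with phase,
#'   confidence level and accepted candidates), per-site lookup, the full
#'   test `ledger`, and the frozen `nodes`.
#' @export
expand_model <- function(core, dataset, interactions,
                         config = expand_config()) {
  ctrl <- dataset$summary[dataset$summary$condition == dataset$control, ]
  all_times <- sort(unique(ctrl$time))
  if (length(all_times) < 3) stop("need data at >= 3 times", call. = FALSE)
  grid <- motif_grid(all_times, config$dt_max, config$min_sub)
  tp <- c(grid$t0, grid$ends)

  sim_times <- sort(unique(c(tp, grid$mids)))
  core_act <- tryCatch(protein_activities(core, NULL, sim_times),
                       error = function(e)
                         stop("core model is not simulatable: ",
                              conditionMessage(e), call. = FALSE))
  nodes <- list()
  for (p in names(core$activity)) {
    v <- core_act[[p]]
    nodes[[p]] <- list(protein = p,
                       mid = v[match(grid$mids, core_act$time)],
                       t0 = v[match(grid$t0, core_act$time)],
                       path = v[match(tp, core_act$time)])
  }
  core_proteins <- names(core$activity)

  sites <- dataset_sites(dataset)
  site_proteins <- vapply(sites, function(s)
    ctrl$protein[ctrl$site == s][1], "")
  site_data <- lapply(sites, function(s) {
    b <- ctrl[ctrl$site == s, ]
    b <- b[order(b$time), ]
    list(y = b$mean, sem = b$sem,
         out_idx = match(b$time, all_times))
  })
  names(site_data) <- sites

  tested <- character()
  ledger_rows <- list()
  layers <- list()
  added <- list()   # site -> candidate (+ layer, phase, level)
  il <- interactions
  run_lapply <- function(X, FUN) {
    if (config$jobs > 1L && .Platform$OS.type == "unix")
      parallel::mclapply(X, FUN, mc.cores = config$jobs)
    else lapply(X, FUN)
  }

  do_sweep <- function(phase, level, phase_sites) {
    unadded <- setdiff(phase_sites, names(added))
    adj <- find_adjacent(unique(c(core_proteins,
                                  vapply(added, function(a) a$protein, ""))),
                         il, level, unadded, site_proteins)
    if (!length(adj)) return(FALSE)
    ord_seed <- (config$seed +
                   stable_hash(paste("sweep", phase, level,
                                     length(layers)))) %% 2147483647L
    site_order <- with_seed(ord_seed, sample(names(adj)))
    res <- run_lapply(site_order, function(s) {
      sd <- site_data[[s]]
      test_site(s, adj[[s]], nodes, sd$y, sd$sem, sd$out_idx, grid,
                config, tested)
    })
    names(res) <- site_order
    # merge in canonical site order, independent of scheduling
    accepted_any <- FALSE
    new_nodes <- list()
    for (s in sort(site_order)) {
      for (entry in res[[s]]$ledger) {
        cand <- entry$cand
        tested <<- c(tested, entry$keys)
        ledger_rows[[length(ledger_rows) + 1L]] <<- data.frame(
          site = s, stage = entry$stage,
          edges = paste(apply(cand$edges, 1, function(r)
            paste0(r[["source"]], ">", r[["target"]])), collapse = ";"),
          family = cand$family, v = cand$v, accepted = cand$accepted,
          phase = phase, level = as.character(level),
          layer = length(layers) + 1L)
      }
      cand <- res[[s]]$result
      if (!is.null(cand)) {
        cand$phase <- phase
        cand$level <- level
        cand$layer <- length(layers) + 1L
        cand$protein <- site_proteins[[s]]
        added[[s]] <<- cand
        new_nodes[[s]] <- cand
        accepted_any <- TRUE
      }
    }
    if (accepted_any) {
      # freeze trajectories of the new layer's nodes
      for (s in names(new_nodes))
        nodes[[s]] <<- node_from_candidate(new_nodes[[s]], nodes, grid,
                                           site_proteins[[s]])
      layers[[length(layers) + 1L]] <<- list(
        index = length(layers) + 1L, phase = phase, level = level,
        sites = sort(names(new_nodes)),
        candidates = new_nodes[sort(names(new_nodes))])
    }
    accepted_any
  }

  phase_site_sets <- list(
    "responders" = names(dataset$responders)[dataset$responders],
    "all-data" = sites,
    "data-driven" = sites)

  for (phase in config$phases) {
    phase_sites <- intersect(phase_site_sets[[phase]], sites)
    if (phase == "data-driven") {
      unadded <- setdiff(phase_sites, names(added))
      if (!length(unadded)) next
      dd <- data_driven_candidates(nodes, unadded, dataset, site_proteins,
                                   grid, config$top_k)
      if (!nrow(dd)) next
      il <- interaction_list(rbind(as.data.frame(il), as.data.frame(dd)))
      levels <- "data-driven"
    } else {
      levels <- confidence_levels(il)
    }
    for (lv in levels) {
      repeat {
        if (!do_sweep(phase, lv, phase_sites)) break
      }
    }
  }

  ledger <- if (length(ledger_rows)) do.call(rbind, ledger_rows)
            else data.frame()
  structure(list(core = core, layers = layers, sites = added,
                 nodes = nodes, grid = grid, data_times = all_times,
                 config = config, interactions = il, ledger = ledger,
                 site_proteins = site_proteins),
            class = "expanded_model")
}

#' @export
print.expanded_model <- function(x, ...) {
  cat("expanded_model:", length(x$sites), "sites in", length(x$layers),
      "layers on top of the core\n")
  invisible(x)
}

#' Data-driven candidate edges for unadded sites
#'
#' Scores every included node against each unadded site's data by the
#' cost of the best affine mapping (closed-form weighted least squares)
#' of the node's simulated trajectory onto the site's means, and keeps
#' the `top_k` best nodes as data-driven edges ranked below every
#' prior-knowledge confidence level.
#'
#' @param nodes frozen node trajectories of an expansion run.
#' @param unadded_sites site ids not yet in the model.
#' @param dataset a `phospho_dataset`.
#' @param site_proteins named character site -> protein.
#' @param grid the expansion [motif_grid()].
#' @param top_k edges kept per site.
#' @return an [interaction_list()] of data-driven edges.
#' @export
data_driven_candidates <- function(nodes, unadded_sites, dataset,
                                   site_proteins, grid, top_k = 3L) {
  tp <- c(grid$t0, grid$ends)
  rows <- list()
  for (s in unadded_sites) {
    b <- site_block(dataset, s)
    idx <- match(b$time, tp)
    sc <- vapply(names(nodes), function(n) {
      x <- nodes[[n]]$path[idx]
      affine_wls(x, b$mean, b$sem)$cost
    }, numeric(1))
    keep <- names(sort(sc))[seq_len(min(top_k, length(sc)))]
    for (j in seq_along(keep)) {
      n <- keep[j]
      rows[[length(rows) + 1L]] <- data.frame(
        source = nodes[[n]]$protein, target = site_proteins[[s]],
        sign = "", n_primary_sources = 0L, origin = "data-driven",
        target_site = s, source_node = n, dd_rank = j)
    }
  }
  if (!length(rows))
    return(interaction_list(data.frame(source = character(),
                                       target = character())))
  interaction_list(do.call(rbind, rows))
}

#' Maximal-model size under a top-down construction
#'
#' Filters the interaction list to edges whose source and target proteins
#' both carry data-covered sites, then applies the counting rule: each
#' covered site contributes a phosphorylated and an unphosphorylated
#' state (2 states) plus one return parameter, and each retained
#' interaction contributes one input parameter.
#'
#' @param interactions an [interaction_list()].
#' @param dataset a `phospho_dataset`.
#' @return named vector `n_states`, `n_parameters`.
#' @export
estimate_maximal_size <- function(interactions, dataset) {
  prot <- unique(dataset$summary$protein)
  il <- interactions[interactions$source %in% prot &
                     interactions$target %in% prot, , drop = FALSE]
  covered <- unique(dataset$summary$site[
    dataset$summary$protein %in% unique(il$target)])
  n_sites <- length(covered)
  c(n_states = 2L * n_sites,
    n_parameters = n_sites + nrow(il))
}

#' Re-simulate an expanded model under a condition
#'
#' Simulates the core under `cond`, then propagates layer by layer
#' through the stored motifs. Clamps (by protein, core state, or site id)
#' scale the clamped node's outgoing trajectory — and, for core states,
#' its value inside other core rates — by the given factor.
#'
#' @param x an `expanded_model`.
#' @param cond a [condition()] or `NULL`; its `clamps` entry is honored.
#' @param times evaluation times (defaults to the data times).
#' @return list: `times`, `site_obs` (matrix sites x times of observable
#'   values), `site_frac` (phosphorylated fractions), `nodes`.
#' @export
simulate_expanded <- function(x, cond = NULL, times = x$data_times) {
  grid <- x$grid
  tp <- c(grid$t0, grid$ends)
  sim_times <- sort(unique(c(tp, grid$mids)))
  clamps <- if (is.null(cond)) numeric() else cond$clamps
  core_clamps <- clamps[names(clamps) %in%
                          c(x$core$states$name, names(x$core$activity))]
  core_cond <- if (is.null(cond)) NULL else
    condition(cond$initial_scalings, cond$effect_scalings,
              cond$input_schedule, core_clamps)
  act <- protein_activities(x$core, core_cond, sim_times)
  clamp_factor <- function(node_id, protein) {
    f <- 1
    if (node_id %in% names(clamps)) f <- f * clamps[[node_id]]
    else if (protein %in% names(clamps)) f <- f * clamps[[protein]]
    f
  }
  nodes <- list()
  for (p in names(x$core$activity)) {
    f <- clamp_factor(p, p)
    v <- act[[p]] * f
    nodes[[p]] <- list(protein = p,
                       mid = v[match(grid$mids, act$time)],
                       t0 = v[match(grid$t0, act$time)],
                       path = v[match(tp, act$time)])
  }
  site_obs <- list(); site_frac <- list()
  for (ly in x$layers) {
    for (s in names(ly$candidates)) {
      cand <- ly$candidates[[s]]
      nd <- node_from_candidate(cand, nodes, grid, cand$protein)
      frac <- stats::approx(tp, nd$path, xout = times, rule = 2)$y
      site_frac[[s]] <- frac
      site_obs[[s]] <- cand$a * frac + cand$b
      f <- clamp_factor(s, cand$protein)
      if (f != 1) {
        nd$mid <- nd$mid * f; nd$t0 <- nd$t0 * f; nd$path <- nd$path * f
      }
      nodes[[s]] <- nd
    }
  }
  list(times = times,
       site_obs = do.call(rbind, site_obs),
       site_frac = do.call(rbind, site_frac),
       nodes = nodes)
}

#' Verify the feed-forward invariant of an expansion
#'
#' Every input edge of a layer-k site must originate in the core or in a
#' layer with smaller index.
#'
#' @param x an `expanded_model`.
#' @return `TRUE` (invisibly) or an error.
#' @export
verify_feed_forward <- function(x) {
  layer_of <- c()
  for (ly in x$layers) for (s in ly$sites) layer_of[[s]] <- ly$index
  for (ly in x$layers) {
    for (s in names(ly$candidates)) {
      for (n in ly$candidates[[s]]$input_nodes) {
        src_layer <- if (n %in% names(layer_of)) layer_of[[n]] else 0L
        if (src_layer >= ly$index)
          stop("feed-forward violation: ", s, " (layer ", ly$index,
               ") takes input from ", n, " (layer ", src_layer, ")",
               call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Re-verify acceptance soundness of an expansion
#'
#' Recomputes every accepted site's cost from its stored parameters and
#' checks it is below the stored threshold.
#'
#' @param x an `expanded_model`.
#' @param dataset the dataset used for the expansion.
#' @param tol numeric slack on the recomputed cost.
#' @return `TRUE` (invisibly) or an error.
#' @export
verify_acceptance <- function(x, dataset, tol = 1e-6) {
  sim <- simulate_expanded(x, NULL, x$data_times)
  for (s in names(x$sites)) {
    b <- site_block(dataset, s)
    yhat <- sim$site_obs[s, match(b$time, sim$times)]
    v <- cost_nssr(b$mean, yhat, b$sem)
    if (!(v < x$sites[[s]]$threshold + tol))
      stop("acceptance soundness violated for ", s, ": recomputed v = ",
           format(v), " >= ", format(x$sites[[s]]$threshold),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize an expanded model to a directory
#'
#' Writes the core model file, `layers.json` (per-site motif, edges,
#' parameters, cost, phase, confidence), `ledger.csv` (every tested
#' candidate) and `expansion.log` (seed and config echo).
#'
#' @param x an `expanded_model`.
#' @param dir output directory (created if needed).
#' @export
write_expanded <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model(x$core, file.path(dir, "core_model.txt"))
  lj <- lapply(x$layers, function(ly) {
    list(index = ly$index, phase = ly$phase, level = as.character(ly$level),
         sites = lapply(ly$candidates, function(cand) list(
           protein = cand$protein, family = cand$family,
           edges = paste(apply(cand$edges, 1, function(r)
             paste0(r[["source"]], ">", r[["target"]])), collapse = ";"),
           inputs = as.list(cand$input_nodes),
           kin = as.list(round(cand$kin, 10)),
           a = round(cand$a, 10), b = round(cand$b, 10),
           v = round(cand$v, 8), df = cand$df,
           threshold = round(cand$threshold, 8))))
  })
  top <- list(data_times = x$data_times,
              dt_max = x$config$dt_max, min_sub = x$config$min_sub,
              seed = x$config$seed, layers = lj)
  jsonlite::write_json(top, file.path(dir, "layers.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(x$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  writeLines(c(paste("seed:", x$config$seed),
               paste("df:", x$config$df),
               paste("alpha:", x$config$alpha),
               paste("budget:", x$config$budget),
               paste("phases:", paste(x$config$phases, collapse = ","))),
             file.path(dir, "expansion.log"))
  invisible(dir)
}

#' Reload an expanded model from a serialized directory
#'
#' Rebuilds an `expanded_model` from `core_model.txt` and `layers.json`
#' as written by [write_expanded()]; sufficient for re-simulation,
#' scenario prediction and recovery scoring.
#'
#' @param dir directory written by [write_expanded()].
#' @return an `expanded_model`.
#' @export
read_expanded <- function(dir) {
  core <- read_model(file.path(dir, "core_model.txt"))
  top <- jsonlite::read_json(file.path(dir, "layers.json"),
                             simplifyVector = FALSE)
  data_times <- unlist(top$data_times)
  grid <- motif_grid(data_times, top$dt_max, top$min_sub)
  layers <- list(); added <- list()
  for (ly in top$layers) {
    cands <- list()
    for (s in names(ly$sites)) {
      cj <- ly$sites[[s]]
      edges <- do.call(rbind, lapply(strsplit(cj$edges, ";")[[1]],
                                     function(e) {
        st <- strsplit(e, ">")[[1]]
        data.frame(source = st[1], target = st[2], sign = "",
                   n_primary_sources = NA_integer_, origin = NA_character_,
                   target_site = NA_character_,
                   source_node = NA_character_)
      }))
      cands[[s]] <- list(site = s, edges = edges, family = cj$family,
                         v = cj$v, kin = unlist(cj$kin), a = cj$a,
                         b = cj$b, accepted = TRUE, df = cj$df,
                         threshold = cj$threshold,
                         input_nodes = unlist(cj$inputs),
                         phase = ly$phase, level = ly$level,
                         layer = ly$index, protein = cj$protein)
      added[[s]] <- cands[[s]]
    }
    layers[[length(layers) + 1L]] <- list(index = ly$index,
                                          phase = ly$phase,
                                          level = ly$level,
                                          sites = sort(names(cands)),
                                          candidates = cands)
  }
  structure(list(core = core, layers = layers, sites = added,
                 nodes = NULL, grid = grid, data_times = data_times,
                 config = expand_config(seed = top$seed,
                                        dt_max = top$dt_max,
                                        min_sub = top$min_sub),
                 interactions = NULL, ledger = NULL,
                 site_proteins = vapply(added, function(a) a$protein, "")),
            class = "expanded_model")
}
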