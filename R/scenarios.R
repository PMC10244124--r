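direction_of <- function(rel_change, tol = 1e-3) {
  if (!is.finite(rel_change) || abs(rel_change) < tol) "unclear"
  else if (rel_change > 0) "increase" else "decrease"
}

#' Predict the per-site effect of a kinase inhibitor
#'
#' Simulates the expanded model with and without a multiplicative clamp
#' on the inhibited node(s) and compares the predicted direction of
#' change at `t_eval` against the inhibitor-block data. A site's observed
#' direction comes from the difference of means (inhibitor minus control)
#' at `t_eval`; if that difference plus/minus one combined SEM spans
#' zero, or the inhibitor block has fewer than two replicates there, the
#' site is ignored. Accuracy is reported per layer over evaluable sites.
#'
#' @param x an `expanded_model`.
#' @param clamp a [condition()] whose `clamps` name the inhibited
#'   protein(s)/state(s) with a factor in \[0, 1\].
#' @param dataset a `phospho_dataset` containing the inhibitor block.
#' @param inhibitor_condition name of the inhibitor condition block.
#' @param t_eval evaluation time (minutes after stimulation).
#' @param tol relative-change floor below which a prediction is
#'   "unclear".
#' @return a `direction_report`: list with `per_site` (data.frame),
#'   `per_layer` (data.frame with `fraction_correct`), `ignored` counts.
#' @export
predict_inhibition <- function(x, clamp, dataset,
                               inhibitor_condition = "inhibitor",
                               t_eval = 20, tol = 1e-3) {
  if (!inhibitor_condition %in% dataset$summary$condition)
    stop("dataset has no '", inhibitor_condition, "' block", call. = FALSE)
  base <- simulate_expanded(x, NULL, t_eval)
  inh <- simulate_expanded(x, clamp, t_eval)
  layer_of <- c()
  for (ly in x$layers) for (s in ly$sites) layer_of[[s]] <- ly$index
  rows <- list()
  for (s in names(x$sites)) {
    y0 <- base$site_obs[s, 1]; y1 <- inh$site_obs[s, 1]
    rel <- if (abs(y0) > 1e-12) (y1 - y0) / abs(y0) else y1 - y0
    pred <- direction_of(rel, tol)
    bc <- site_block(dataset, s, dataset$control)
    bi <- site_block(dataset, s, inhibitor_condition)
    ic <- which(bc$time == t_eval); ii <- which(bi$time == t_eval)
    status <- "evaluable"; obs <- NA_character_
    if (!length(ii) || !length(ic)) {
      status <- "no data at t_eval"
    } else if (bi$n[ii] < 2) {
      status <- "fewer than two repeats"
    } else {
      delta <- bi$mean[ii] - bc$mean[ic]
      se <- sqrt(bi$sem[ii]^2 + bc$sem[ic]^2)
      if (delta - se < 0 && delta + se > 0) {
        status <- "unclear observed effect"
      } else obs <- if (delta > 0) "increase" else "decrease"
    }
    rows[[s]] <- data.frame(site = s, layer = layer_of[[s]],
                            predicted = pred, observed = obs,
                            status = status,
                            correct = identical(pred, obs))
  }
  per_site <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), layer = integer(),
               predicted = character(), observed = character(),
               status = character(), correct = logical())
  rownames(per_site) <- NULL
  ev <- per_site[per_site$status == "evaluable", ]
  per_layer <- if (nrow(ev)) {
    agg <- stats::aggregate(correct ~ layer, ev, mean)
    n <- stats::aggregate(correct ~ layer, ev, length)
    data.frame(layer = agg$layer, n_evaluable = n$correct,
               fraction_correct = agg$correct)
  } else data.frame(layer = integer(), n_evaluable = integer(),
                    fraction_correct = numeric())
  ignored <- table(per_site$status[per_site$status != "evaluable"])
  structure(list(per_site = per_site, per_layer = per_layer,
                 ignored = ignored, t_eval = t_eval),
            class = "direction_report")
}

#' @export
print.direction_report <- function(x, ...) {
  ev <- x$per_site$status == "evaluable"
  cat("direction_report at t =", x$t_eval, "min:", sum(ev), "evaluable,",
      sum(!ev), "ignored")
  if (any(ev)) cat("; overall accuracy",
                   format(mean(x$per_site$correct[ev]), digits = 3))
  cat("\n")
  invisible(x)
}

#' Propagate a type-2-diabetes condition through the expanded model
#'
#' Simulates the expanded model under the normal and the T2D condition
#' (initial-value scalings and effect scalings on the core; kinetic
#' parameters unchanged) and reports the per-site fold change of the site
#' observable at `t_eval` relative to normal. Sites unaffected by the
#' perturbation have fold change 1; a normal-condition value below
#' `1e-12` yields `NA` (undefined ratio).
#'
#' @param x an `expanded_model`.
#' @param t2d a [condition()].
#' @param t_eval evaluation time in minutes.
#' @return named numeric vector of fold changes per site.
#' @export
t2d_propagate <- function(x, t2d, t_eval = 20) {
  base <- simulate_expanded(x, NULL, t_eval)
  cond <- simulate_expanded(x, t2d, t_eval)
  if (is.null(base$site_obs)) return(stats::setNames(numeric(), character()))
  out <- vapply(rownames(base$site_obs), function(s) {
    y0 <- base$site_obs[s, 1]
    y1 <- cond$site_obs[s, 1]
    if (abs(y0) < 1e-12) NA_real_ else y1 / y0
  }, numeric(1))
  out
}

#' Write a direction report to CSV/JSON
#'
#' @param rep a `direction_report`.
#' @param dir output directory.
#' @export
write_direction_report <- function(rep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$per_site, file.path(dir, "per_site.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$per_layer, file.path(dir, "per_layer.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(t_eval = rep$t_eval,
         n_evaluable = sum(rep$per_site$status == "evaluable"),
         ignored = as.list(rep$ignored),
         per_layer = rep$per_layer),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
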