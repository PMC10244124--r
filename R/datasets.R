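#' Filter a raw phosphosite replicate table into a dataset
#'
#' Drops every site for which any control-condition time point has fewer
#' than two replicates, then computes per (site, condition, time) the mean,
#' the SEM (sample standard deviation / sqrt(n)) and the replicate count.
#' SEMs below `sem_floor_abs` are raised to
#' `max(sem_floor_abs, sem_floor_frac * range(site means))` so the
#' normalized-residual cost never divides by ~0.
#'
#' @param raw data.frame with columns `site`, `protein`, `condition`,
#'   `time_min`, `replicate`, `value` and optionally `responder`.
#' @param control name of the control condition block.
#' @param sem_floor_abs,sem_floor_frac SEM floor (absolute, and as a
#'   fraction of the per-site mean range).
#' @return a `phospho_dataset`: list with `summary` (site, protein,
#'   condition, time, mean, sem, n), `responders` (named logical per site)
#'   and `control`.
#' @export
filter_sites <- function(raw, control = "control",
                         sem_floor_abs = 1e-6, sem_floor_frac = 0.05) {
  req <- c("site", "protein", "condition", "time_min", "replicate", "value")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0) {
    return(structure(list(summary = data.frame(
      site = character(), protein = character(), condition = character(),
      time = numeric(), mean = numeric(), sem = numeric(), n = integer()),
      responders = logical(), control = control),
      class = "phospho_dataset"))
  }
  stopifnot(all(raw$time_min >= 0))
  agg <- stats::aggregate(value ~ site + protein + condition + time_min,
                          data = raw, FUN = function(v)
                            c(mean = mean(v), sd = stats::sd(v),
                              n = length(v)))
  sm <- data.frame(site = agg$site, protein = agg$protein,
                   condition = agg$condition, time = agg$time_min,
                   mean = agg$value[, "mean"],
                   sem = agg$value[, "sd"] / sqrt(agg$value[, "n"]),
                   n = as.integer(agg$value[, "n"]))
  # replicate rule on the control block: any time point with n < 2 drops
  # the whole site
  ctrl <- sm[sm$condition == control, ]
  bad_sites <- unique(ctrl$site[ctrl$n < 2])
  no_ctrl <- setdiff(unique(sm$site), unique(ctrl$site))
  sm <- sm[!sm$site %in% c(bad_sites, no_ctrl), , drop = FALSE]
  # SEM floor per site
  for (s in unique(sm$site)) {
    i <- sm$site == s
    rng <- diff(range(sm$mean[i]))
    fl <- max(sem_floor_abs, sem_floor_frac * rng)
    j <- i & (is.na(sm$sem) | sm$sem < fl)
    sm$sem[j] <- fl
  }
  sm <- sm[order(sm$site, sm$condition, sm$time), , drop = FALSE]
  rownames(sm) <- NULL
  responders <- logical()
  if ("responder" %in% names(raw)) {
    lab <- unique(raw[, c("site", "responder")])
    lab <- lab[lab$site %in% sm$site, ]
    responders <- stats::setNames(as.logical(lab$responder), lab$site)
  }
  structure(list(summary = sm, responders = responders, control = control),
            class = "phospho_dataset")
}

#' @export
print.phospho_dataset <- function(x, ...) {
  cat("phospho_dataset:", length(unique(x$summary$site)), "sites,",
      length(unique(x$summary$condition)), "condition(s)\n")
  invisible(x)
}

dataset_sites <- function(ds) unique(ds$summary$site)

subset_sites <- function(ds, sites) {
  ds$summary <- ds$summary[ds$summary$site %in% sites, , drop = FALSE]
  ds$responders <- ds$responders[names(ds$responders) %in% sites]
  ds
}

site_block <- function(ds, site, cond = ds$control) {
  b <- ds$summary[ds$summary$site == site & ds$summary$condition == cond, ]
  b[order(b$time), , drop = FALSE]
}

#' Split a dataset into responders and nonresponders
#'
#' Labels are supplied (the source data's inhibitor-based classification),
#' not recomputed. The two outputs partition the input exactly.
#'
#' @param ds a `phospho_dataset`.
#' @param labels named logical vector site -> responder; defaults to the
#'   labels carried by the dataset.
#' @return list with elements `responders`, `nonresponders`.
#' @export
split_responders <- function(ds, labels = ds$responders) {
  sites <- dataset_sites(ds)
  unlabeled <- setdiff(sites, names(labels))
  if (length(unlabeled))
    stop("unlabeled site(s): ", paste(utils::head(unlabeled, 5),
                                      collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(labels), sites)
  if (length(unknown))
    stop("label(s) for unknown site(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  resp <- names(labels)[labels]
  list(responders = subset_sites(ds, resp),
       nonresponders = subset_sites(ds, setdiff(sites, resp)))
}

#' Build an interaction list
#'
#' Directed protein-protein edges graded by the number of primary
#' literature sources. Duplicate (source, target) pairs are merged keeping
#' the maximum count. Data-driven edges (origin `"data-driven"`) always
#' rank below every prior-knowledge confidence level.
#'
#' @param edges data.frame with columns `source`, `target`, optional
#'   `sign` (`"+"`, `"-"` or `""`), `n_primary_sources`, optional `origin`
#'   and `target_site`.
#' @return an `interaction_list` data.frame.
#' @export
interaction_list <- function(edges) {
  if (!all(c("source", "target") %in% names(edges)))
    stop("interaction list needs source and target columns", call. = FALSE)
  n <- nrow(edges)
  if (is.null(edges$sign)) edges$sign <- character(n)
  edges$sign[is.na(edges$sign)] <- ""
  if (is.null(edges$n_primary_sources))
    edges$n_primary_sources <- integer(n)
  if (any(is.na(edges$n_primary_sources)) ||
      any(edges$n_primary_sources < 0))
    stop("n_primary_sources must be non-negative", call. = FALSE)
  if (is.null(edges$origin))
    edges$origin <- rep("prior-knowledge", n)
  if (is.null(edges$target_site))
    edges$target_site <- rep(NA_character_, n)
  if (is.null(edges$source_node))
    edges$source_node <- rep(NA_character_, n)
  if (is.null(edges$dd_rank)) edges$dd_rank <- rep(NA_integer_, n)
  edges <- edges[, c("source", "target", "sign", "n_primary_sources",
                     "origin", "target_site", "source_node", "dd_rank")]
  # merge duplicates keeping max count
  key <- paste(edges$source, edges$target, edges$origin, edges$target_site,
               sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -edges$n_primary_sources)
    edges <- edges[ord, ][!duplicated(key[ord]), , drop = FALSE]
  }
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("interaction_list", "data.frame")
  edges
}

#' Read an interaction list from TSV
#'
#' Expected columns: `source`, `target`, `sign` (optional), and
#' `n_primary_sources`, as in an OmniPath-style export.
#'
#' @param path TSV file path.
#' @return an `interaction_list`.
#' @export
load_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  interaction_list(tab)
}

#' Distinct confidence levels, highest first
#'
#' @param il an `interaction_list`.
#' @return strictly decreasing integer vector of distinct
#'   `n_primary_sources` among prior-knowledge edges.
#' @export
confidence_levels <- function(il) {
  pk <- il$n_primary_sources[il$origin == "prior-knowledge"]
  sort(unique(pk), decreasing = TRUE)
}

#' Write a dataset / interaction list in the package's exchange formats
#'
#' @param raw long-format replicate table (see [filter_sites()]).
#' @param path output file.
#' @export
write_phospho_csv <- function(raw, path) {
  utils::write.csv(raw, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phospho_csv
#' @param il an `interaction_list`.
#' @export
write_interactions_tsv <- function(il, path) {
  utils::write.table(il[, c("source", "target", "sign",
                            "n_primary_sources")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format phosphosite replicate table
#'
#' @param path CSV file with columns
#'   `site,protein,condition,time_min,replicate,value[,responder]`.
#' @return data.frame.
#' @export
read_phospho_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
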