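#' Simultaneous-infected time series
#'
#' The pointwise sum of active infected, isolated and true-positive
#' quarantined individuals: everyone currently carrying the infection,
#' whether free or confined. For an ensemble the per-step ensemble-mean
#' compartments are summed (so the peak of this series is the peak of the
#' mean curve, not the mean of per-run peaks).
#'
#' @param x A `bubble_run`, `bubble_ensemble`, or a data frame with columns
#'   `I_active`, `isolated` and `quarantined_true_positive`.
#' @return Numeric vector, one value per step.
#' @export
simultaneous_infected_series <- function(x) {
  df <- if (inherits(x, "bubble_run")) x$epi
        else if (inherits(x, "bubble_ensemble")) x$epi_mean
        else x
  df$I_active + df$isolated + df$quarantined_true_positive
}

#' Knowledge milestone times
#'
#' First days on which the population-mean number of acquired pieces reaches
#' (i) the amount of knowledge initially contained in one bubble,
#' `n_pieces / n_bubbles` (2 pieces for 20 pieces in 10 bubbles), (ii) 50% of
#' all pieces (10) and (iii) 80% of all pieces (16). Crossings use the first
#' day with mean >= threshold, at the daily resolution of the knowledge
#' update; a threshold never crossed within the horizon is reported as `NA`.
#'
#' @param knowledge_series Data frame with columns `day` and
#'   `mean_knowledge`, or a numeric vector of daily means for days `0, 1,
#'   ...`.
#' @param n_pieces Total number of knowledge pieces.
#' @param n_bubbles Number of bubbles.
#' @return Named numeric vector `c(t_bubble, t_50, t_80)` in days.
#' @export
knowledge_milestones <- function(knowledge_series, n_pieces = 20, n_bubbles = 10) {
  if (is.data.frame(knowledge_series)) {
    days <- knowledge_series$day
    vals <- knowledge_series$mean_knowledge
  } else {
    vals <- knowledge_series
    days <- seq_along(vals) - 1
  }
  thresholds <- c(t_bubble = n_pieces / n_bubbles,
                  t_50 = 0.5 * n_pieces, t_80 = 0.8 * n_pieces)
  vapply(thresholds, function(thr) {
    hit <- which(vals >= thr)
    if (length(hit)) days[hit[1]] else NA_real_
  }, 0)
}

#' Collateral confinement
#'
#' The social cost of quarantining: the percentage of the population confined
#' (isolated or quarantined) at least once during a run while never having
#' been infected, averaged over the ensemble.
#'
#' @param x A `bubble_ensemble` or a list of `bubble_run`s.
#' @return Percentage in `[0, 100]`.
#' @export
collateral_confinement <- function(x) {
  runs <- if (inherits(x, "bubble_ensemble")) x$runs else x
  per_run <- vapply(runs, function(r) {
    mean(r$ever_confined & !r$ever_infected)
  }, 0)
  100 * mean(per_run)
}

#' Realized modularity ratio
#'
#' Diagnostic of whether generated (and intervention-thinned) layers actually
#' exhibit the configured modularity: per window, the realized within-bubble
#' link density divided by the realized between-bubble link density,
#' \eqn{\hat p = (l_{intra}/m_{intra}) / (l_{inter}/m_{inter})}, with pair
#' counts `m` restricted to unconfined nodes. Windows with no inter-bubble
#' links (or no inter pairs) are reported as `NA`, never as `Inf`.
#'
#' For a `temporal_network` the full node set is used; for a `bubble_run` the
#' per-step free-node pair counts recorded during simulation are used, so the
#' series reflects confinement as it happened.
#'
#' @param x A `temporal_network` or a `bubble_run`.
#' @param window_steps Steps aggregated per window (default one day's worth,
#'   taken from the configuration when available).
#' @return Numeric vector of per-window realized ratios.
#' @export
realized_modularity <- function(x, window_steps = NULL) {
  if (inherits(x, "temporal_network")) {
    memb <- x$membership
    n_bubbles <- max(memb)
    pc <- free_pair_counts(rep(TRUE, length(memb)), memb, n_bubbles)
    counts <- t(vapply(x$layers, function(l) {
      if (nrow(l) == 0) return(c(0, 0))
      same <- memb[l[, 1]] == memb[l[, 2]]
      c(sum(same), sum(!same))
    }, c(0, 0)))
    df <- data.frame(intra_links = counts[, 1], inter_links = counts[, 2],
                     intra_pairs_free = unname(pc["intra"]),
                     inter_pairs_free = unname(pc["inter"]))
    if (is.null(window_steps)) {
      window_steps <- if (!is.null(x$config)) x$config$steps_per_day else 12L
    }
  } else if (inherits(x, "bubble_run")) {
    df <- x$diagnostics
    if (is.null(window_steps)) window_steps <- x$scenario$network$steps_per_day
  } else {
    stop("x must be a temporal_network or a bubble_run")
  }
  n <- nrow(df)
  if (n == 0) return(numeric(0))
  win <- (seq_len(n) - 1L) %/% window_steps
  agg <- rowsum(as.matrix(df[c("intra_links", "inter_links",
                               "intra_pairs_free", "inter_pairs_free")]), win,
                na.rm = FALSE)
  intra_d <- agg[, "intra_links"] / agg[, "intra_pairs_free"]
  inter_d <- agg[, "inter_links"] / agg[, "inter_pairs_free"]
  ratio <- ifelse(agg[, "inter_links"] > 0 & agg[, "inter_pairs_free"] > 0,
                  intra_d / inter_d, NA_real_)
  unname(ratio)
}

#' Scenario indicators
#'
#' The scalar summaries reported for each scenario ensemble: the peak of the
#' ensemble-mean simultaneous-infected curve (count and % of the population),
#' the peak of the mean active-infected curve, per-run peaks (for
#' dispersion), the knowledge milestone times, collateral confinement and
#' the mean realized modularity ratio.
#'
#' @param ens A `bubble_ensemble`.
#' @return Named list of indicators.
#' @export
indicators <- function(ens) {
  stopifnot(inherits(ens, "bubble_ensemble"))
  N <- ens$scenario$network$n_nodes
  si <- simultaneous_infected_series(ens)
  per_run_peaks <- vapply(ens$runs, function(r)
    max(simultaneous_infected_series(r)), 0)
  ms <- knowledge_milestones(ens$knowledge_mean,
                             n_pieces = ens$scenario$knowledge$n_pieces,
                             n_bubbles = ens$scenario$network$n_bubbles)
  p_hats <- unlist(lapply(ens$runs, function(r) realized_modularity(r)))
  list(
    peak_simultaneous_infected = max(si),
    peak_simultaneous_infected_pct = 100 * max(si) / N,
    peak_active_infected = max(ens$epi_mean$I_active),
    per_run_peaks = per_run_peaks,
    t_bubble = unname(ms["t_bubble"]),
    t_50 = unname(ms["t_50"]),
    t_80 = unname(ms["t_80"]),
    collateral_confinement_pct = collateral_confinement(ens),
    realized_p_ratio = mean(p_hats, na.rm = TRUE)
  )
}

#' Write per-run and ensemble CSV outputs plus an indicator JSON
#'
#' Writes the external file interface of a scenario ensemble: one epidemic
#' time-series CSV per run (`run-<k>-epi.csv`), one daily knowledge CSV per
#' run (`run-<k>-knowledge.csv`), the ensemble-mean series
#' (`ensemble-epi.csv`, `ensemble-knowledge.csv`) and `indicators.json`.
#'
#' @param ens A `bubble_ensemble`.
#' @param dir Output directory (created if missing).
#' @param per_run Write per-run CSVs as well as ensemble means.
#' @return `dir`, invisibly.
#' @export
write_ensemble_outputs <- function(ens, dir, per_run = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (per_run) {
    for (k in seq_along(ens$runs)) {
      r <- ens$runs[[k]]
      utils::write.csv(r$epi, file.path(dir, sprintf("run-%03d-epi.csv", k)),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(r$knowledge,
                       file.path(dir, sprintf("run-%03d-knowledge.csv", k)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  utils::write.csv(ens$epi_mean, file.path(dir, "ensemble-epi.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ens$knowledge_mean, file.path(dir, "ensemble-knowledge.csv"),
                   row.names = FALSE, quote = FALSE)
  ind <- ens$indicators
  ind$per_run_peaks <- NULL
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(ind, file.path(dir, "indicators.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(indicator = names(ind),
                                value = unlist(ind)),
                     file.path(dir, "indicators.csv"), row.names = FALSE)
  }
  invisible(dir)
}
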