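#' Scenario: a fully specified co-simulation setting
#'
#' Couples a network configuration, disease parameters and knowledge
#' parameters with a horizon and ensemble size. The reference setting mirrors
#' the study design: 680 nodes in 10 bubbles of 68, 400 expected links per
#' 2-hour layer, one index infection, 20 knowledge pieces each seeded on one
#' random node.
#'
#' @param network A [network_config()].
#' @param epi An [epi_params()].
#' @param knowledge A [knowledge_params()].
#' @param horizon_days Simulated days per run.
#' @param n_runs Ensemble size for [run_ensemble()].
#' @param master_seed Integer seed from which per-run streams are derived.
#' @param early_stop Stop a run early once no infected individuals remain
#'   and mean knowledge has reached 80% of all pieces (series are padded with
#'   their final values, which are constant for the epidemic and a lower
#'   bound for knowledge beyond the last milestone).
#' @return Object of class `scenario`.
#' @examples
#' sc <- scenario(network_config(p = 5), epi_params(eps_I = 0.1),
#'                knowledge_params(), horizon_days = 30, n_runs = 2)
#' @export
scenario <- function(network, epi = epi_params(), knowledge = knowledge_params(),
                     horizon_days = 150, n_runs = 200, master_seed = 1L,
                     early_stop = TRUE) {
  stopifnot(inherits(network, "network_config"), inherits(epi, "epi_params"),
            inherits(knowledge, "knowledge_params"),
            horizon_days >= 1, n_runs >= 1)
  structure(list(network = network, epi = epi, knowledge = knowledge,
                 horizon_days = as.integer(horizon_days),
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 early_stop = isTRUE(early_stop)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d days x %d runs (seed %d)\n", x$horizon_days,
              x$n_runs, x$master_seed))
  print(x$network); print(x$epi)
  cat(sprintf("<knowledge_params> %d pieces, threshold K=%d\n",
              x$knowledge$n_pieces, x$knowledge$K))
  invisible(x)
}

# Free-pair counts by bubble for the realized-modularity diagnostic.
free_pair_counts <- function(free, membership, n_bubbles) {
  f <- tabulate(membership[free], nbins = n_bubbles)
  Ftot <- sum(f)
  c(intra = sum(f * (f - 1) / 2), inter = sum(f * (Ftot - f) / 2))
}

#' Run one coupled disease/knowledge simulation
#'
#' Per 2-hour step: sample the contact layer (respecting the active bubble
#' matching when pairing is on), strip all edges touching confined nodes,
#' log the surviving contacts for tracing, run disease transmission, advance
#' progression (with tracing of any new isolations), and accumulate knowledge
#' exposures. At each 24-hour boundary the knowledge transmission snapshot is
#' refreshed. The disease is seeded with one index case ([seed_infection()]),
#' knowledge with one holder per piece ([seed_knowledge()]), both at step 0.
#'
#' @param sc A [scenario()].
#' @param curve An [infectivity_curve()].
#' @param run_seed Optional integer seed (set before any random draw).
#' @param track_knowledge Set `FALSE` to skip the knowledge process.
#' @return Object of class `bubble_run`: per-step epidemic series `epi`
#'   (columns `step, day, S, I_active, isolated, quarantined_total,
#'   quarantined_true_positive, R`), daily `knowledge` series (`day,
#'   mean_knowledge, frac_full`), per-node `ever_infected` / `ever_confined`
#'   flags, the index case's offspring count `index_offspring`, per-step
#'   link-classification `diagnostics`, and `terminated_day` if the run
#'   stopped early.
#' @export
run_once <- function(sc, curve = infectivity_curve(), run_seed = NULL,
                     track_knowledge = TRUE) {
  if (!is.null(run_seed)) set.seed(run_seed)
  cfg <- sc$network
  spd <- cfg$steps_per_day
  step_days <- 1 / spd
  horizon_steps <- sc$horizon_days * spd
  tables <- layer_tables(cfg)
  schedule <- if (cfg$pairing_period_days > 0) {
    round_robin_schedule(cfg$n_bubbles, cfg$pairing_period_days, spd)
  } else NULL

  state <- epi_state(cfg$n_nodes, sc$epi, spd)
  state <- seed_infection(state, sc$epi)
  index <- which(state$status == .I)
  kstate <- knowledge_state(cfg$n_nodes, sc$knowledge)
  if (track_knowledge) kstate <- seed_knowledge(kstate, sc$knowledge)

  epi_mat <- matrix(0L, horizon_steps, 6,
                    dimnames = list(NULL, c("S", "I_active", "isolated",
                                            "quarantined_total",
                                            "quarantined_true_positive", "R")))
  diag_mat <- matrix(0, horizon_steps, 4,
                     dimnames = list(NULL, c("intra_links", "inter_links",
                                             "intra_pairs_free",
                                             "inter_pairs_free")))
  k_series <- rep(NA_real_, sc$horizon_days + 1L)
  k_full <- rep(NA_real_, sc$horizon_days + 1L)
  k_series[1] <- mean_knowledge(kstate)
  k_full[1] <- mean(rowSums(kstate$acquired) == sc$knowledge$n_pieces)
  memb <- cfg$membership
  terminated_day <- NA_integer_
  last_step <- horizon_steps

  for (day in seq_len(sc$horizon_days)) {
    for (s in seq_len(spd)) {
      step <- (day - 1L) * spd + s
      layer <- sample_layer_tbl(cfg, tables, active_matching(schedule, step))
      free <- state$conf == .FREE
      if (nrow(layer)) {
        layer <- layer[free[layer[, 1]] & free[layer[, 2]], , drop = FALSE]
      }
      state <- record_contacts(state, layer, step)
      state <- transmission_step(state, layer, sc$epi, curve)
      state <- progression_step(state, sc$epi, curve, step_days, step)
      for (v in state$new_isolations) {
        state <- trace_and_quarantine(state, v, sc$epi, step)
      }
      if (track_knowledge) kstate <- exposure_step(kstate, layer)

      epi_mat[step, ] <- c(sum(state$status == .S),
                           sum(state$status == .I & state$conf == .FREE),
                           sum(state$conf == .ISO),
                           sum(state$conf == .QUAR),
                           sum(state$conf == .QUAR & state$status == .I),
                           sum(state$status == .R))
      if (nrow(layer)) {
        same <- memb[layer[, 1]] == memb[layer[, 2]]
        diag_mat[step, 1:2] <- c(sum(same), sum(!same))
      }
      diag_mat[step, 3:4] <- free_pair_counts(free, memb, cfg$n_bubbles)
    }
    if (track_knowledge) {
      kstate <- daily_update(kstate)
      k_series[day + 1L] <- mean_knowledge(kstate)
      k_full[day + 1L] <- mean(rowSums(kstate$acquired) == sc$knowledge$n_pieces)
    }
    if (sc$early_stop && sum(state$status == .I) == 0 && track_knowledge &&
        k_series[day + 1L] >= 0.8 * sc$knowledge$n_pieces) {
      terminated_day <- day
      last_step <- day * spd
      break
    }
  }

  if (last_step < horizon_steps) {   # pad: epidemic is frozen, knowledge bounded below
    pad <- (last_step + 1L):horizon_steps
    epi_mat[pad, ] <- matrix(epi_mat[last_step, ], length(pad), 6, byrow = TRUE)
    diag_mat[pad, ] <- NA_real_
    k_series[(terminated_day + 2L):(sc$horizon_days + 1L)] <- k_series[terminated_day + 1L]
    k_full[(terminated_day + 2L):(sc$horizon_days + 1L)] <- k_full[terminated_day + 1L]
  }

  structure(list(
    epi = data.frame(step = seq_len(horizon_steps),
                     day = (seq_len(horizon_steps) - 1L) %/% spd + 1L,
                     epi_mat),
    knowledge = data.frame(day = 0:sc$horizon_days,
                           mean_knowledge = k_series, frac_full = k_full),
    ever_infected = state$ever_infected,
    ever_confined = state$ever_confined,
    index_offspring = sum(state$infector == index, na.rm = TRUE),
    diagnostics = data.frame(step = seq_len(horizon_steps), diag_mat),
    terminated_day = terminated_day,
    scenario = sc
  ), class = "bubble_run")
}

#' @export
print.bubble_run <- function(x, ...) {
  si <- simultaneous_infected_series(x)
  cat(sprintf(
    "<bubble_run> %d days; peak simultaneous infected %d (%.1f%%); final mean knowledge %.2f\n",
    x$scenario$horizon_days, max(si),
    100 * max(si) / x$scenario$network$n_nodes,
    x$knowledge$mean_knowledge[nrow(x$knowledge)]))
  invisible(x)
}

#' Run a Monte-Carlo ensemble of a scenario
#'
#' Executes `n_runs` independent runs with per-run seeds derived from the
#' scenario's `master_seed` (drawn once from the master stream, so each run
#' has a distinct, reproducible stream), then averages the epidemic and
#' knowledge series pointwise and computes the scenario [indicators()].
#'
#' @param sc A [scenario()].
#' @param curve An [infectivity_curve()].
#' @param track_knowledge Set `FALSE` to skip the knowledge process.
#' @return Object of class `bubble_ensemble`: the per-run results (`runs`),
#'   pointwise ensemble-mean series (`epi_mean`, `knowledge_mean`), the
#'   `indicators` list and the scenario.
#' @export
run_ensemble <- function(sc, curve = infectivity_curve(), track_knowledge = TRUE) {
  set.seed(sc$master_seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, sc$n_runs)
  runs <- lapply(run_seeds, function(seed) {
    run_once(sc, curve, run_seed = seed, track_knowledge = track_knowledge)
  })
  epi_cols <- c("S", "I_active", "isolated", "quarantined_total",
                "quarantined_true_positive", "R")
  epi_mean <- Reduce(`+`, lapply(runs, function(r) as.matrix(r$epi[epi_cols]))) /
    length(runs)
  epi_mean <- data.frame(step = runs[[1]]$epi$step, day = runs[[1]]$epi$day,
                         epi_mean)
  k_mean <- Reduce(`+`, lapply(runs, function(r)
    as.matrix(r$knowledge[c("mean_knowledge", "frac_full")]))) / length(runs)
  k_mean <- data.frame(day = runs[[1]]$knowledge$day, k_mean)
  ens <- structure(list(runs = runs, epi_mean = epi_mean,
                        knowledge_mean = k_mean, scenario = sc),
                   class = "bubble_ensemble")
  ens$indicators <- indicators(ens)
  ens
}

#' @export
print.bubble_ensemble <- function(x, ...) {
  ind <- x$indicators
  cat(sprintf("<bubble_ensemble> %d runs of %d days\n", length(x$runs),
              x$scenario$horizon_days))
  cat(sprintf("  peak simultaneous infected: %.1f (%.1f%% of N)\n",
              ind$peak_simultaneous_infected, ind$peak_simultaneous_infected_pct))
  cat(sprintf("  knowledge milestones (days): bubble %s, 50%% %s, 80%% %s\n",
              format(ind$t_bubble), format(ind$t_50), format(ind$t_80)))
  cat(sprintf("  collateral confinement: %.1f%%\n", ind$collateral_confinement_pct))
  invisible(x)
}

#' Indicator table over a list of scenarios
#'
#' Runs each scenario's ensemble and collects its scalar indicators together
#' with the scenario's main parameters into one tidy table (one row per
#' scenario), as used for intervention sweeps over the quarantine probability
#' `eps_T`, the modularity `p` and the pairing period `d`.
#'
#' @param scenarios List of [scenario()] objects.
#' @param curve An [infectivity_curve()].
#' @return A `data.frame` with scenario descriptors (`p`, `eps_I`, `eps_T`,
#'   `pairing_d`, `n_runs`) and indicator columns.
#' @export
sweep_scenarios <- function(scenarios, curve = infectivity_curve()) {
  if (!length(scenarios)) return(data.frame())
  rows <- lapply(scenarios, function(sc) {
    ens <- run_ensemble(sc, curve)
    ind <- ens$indicators
    data.frame(p = sc$network$p, eps_I = sc$epi$eps_I, eps_T = sc$epi$eps_T,
               pairing_d = sc$network$pairing_period_days,
               n_runs = sc$n_runs,
               peak_simultaneous_infected = ind$peak_simultaneous_infected,
               peak_simultaneous_infected_pct = ind$peak_simultaneous_infected_pct,
               peak_active_infected = ind$peak_active_infected,
               t_bubble = ind$t_bubble, t_50 = ind$t_50, t_80 = ind$t_80,
               collateral_confinement_pct = ind$collateral_confinement_pct,
               realized_p_ratio = ind$realized_p_ratio)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
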