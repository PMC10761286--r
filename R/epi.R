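#' Infection-age profiles: infectiousness and symptom onset
#'
#' The disease model is non-Markovian: an infected individual's per-contact
#' transmission probability is `beta * omega(tau)`, where `tau` is the time
#' since their own infection (days), and symptom onset follows the cumulative
#' distribution `s(tau)`.
#'
#' The default `omega` is a gamma-shaped curve with its mode at
#' `peak_day` (5 days), truncated at `cutoff_days` (the 10-day infectious
#' period) and normalized to peak value 1, so `beta` is the maximum
#' per-contact transmission probability. The default `s` is a log-normal
#' incubation CDF with median `incubation_median_days` (5.5 days); symptomatic
#' individuals eventually show symptoms with probability 1 (the 80/20
#' symptomatic/asymptomatic split lives in [epi_params()]).
#'
#' Custom functions can be supplied through `omega_fn` / `s_fn`, e.g. a
#' constant-infectiousness profile for analytic checks.
#'
#' @param peak_day Infection age (days) of maximal infectiousness.
#' @param shape Gamma shape of the infectiousness curve (controls its width;
#'   shape 9 with mode 5 gives a standard deviation of about 1.9 days).
#' @param cutoff_days Infectious period: `omega` is 0 at and beyond this age.
#' @param incubation_median_days Median of the symptom-onset distribution.
#' @param incubation_sdlog Log-scale standard deviation of the onset CDF.
#' @param omega_fn,s_fn Optional replacement functions of `tau` (days).
#' @return Object of class `infectivity_curve` with elements `omega` and `s`.
#' @examples
#' crv <- infectivity_curve()
#' crv$omega(5)    # 1: peak infectiousness
#' crv$s(5.5)      # 0.5: median onset
#' @export
infectivity_curve <- function(peak_day = 5, shape = 9, cutoff_days = 10,
                              incubation_median_days = 5.5,
                              incubation_sdlog = 0.45,
                              omega_fn = NULL, s_fn = NULL) {
  if (is.null(omega_fn)) {
    rate <- (shape - 1) / peak_day
    peak_val <- stats::dgamma(peak_day, shape = shape, rate = rate)
    omega_fn <- function(tau) {
      ifelse(tau >= 0 & tau < cutoff_days,
             stats::dgamma(tau, shape = shape, rate = rate) / peak_val, 0)
    }
  }
  if (is.null(s_fn)) {
    mlog <- log(incubation_median_days)
    s_fn <- function(tau) {
      ifelse(tau <= 0, 0, stats::plnorm(tau, meanlog = mlog, sdlog = incubation_sdlog))
    }
  }
  structure(list(omega = omega_fn, s = s_fn, peak_day = peak_day,
                 cutoff_days = cutoff_days), class = "infectivity_curve")
}

# Transmission scale calibrated (see calibrate_beta) so the basic reproduction
# number on the reference network (680 nodes, 10 bubbles, 400 links/layer,
# p = 5, eps_I = 0.1, eps_T = 0) is 1.64.
.default_beta <- 0.0503

#' Disease-model parameters
#'
#' @param eps_I Per-day probability that a symptomatic individual is
#'   identified and isolated (applied each step as the per-step hazard
#'   `1 - (1 - eps_I)^(1/steps_per_day)`, so the daily probability is `eps_I`
#'   for any step size).
#' @param eps_T Per-contact probability that a traced contact of a newly
#'   isolated individual is preventively quarantined.
#' @param symptomatic_fraction Probability a new infection will eventually be
#'   symptomatic (0.80).
#' @param infectious_period_days Days from infection to natural recovery (10).
#' @param isolation_days Duration of isolation; at its end the individual is
#'   recovered (10).
#' @param quarantine_days Duration of preventive quarantine (10).
#' @param tracing_window_days Depth of the contact log used for tracing (7).
#' @param beta Overall transmission scale multiplying `omega(tau)`; default
#'   calibrated so the basic reproduction number on the reference network is
#'   1.64 (see [calibrate_beta()]).
#' @param seed_tau_min_days,seed_tau_max_days The index case starts with an
#'   infection age drawn uniformly from this range (0 to 10 days).
#' @return Object of class `epi_params`.
#' @export
epi_params <- function(eps_I = 0.1, eps_T = 0, symptomatic_fraction = 0.8,
                       infectious_period_days = 10, isolation_days = 10,
                       quarantine_days = 10, tracing_window_days = 7,
                       beta = .default_beta,
                       seed_tau_min_days = 0, seed_tau_max_days = 10) {
  stopifnot(eps_I >= 0, eps_I <= 1, eps_T >= 0, eps_T <= 1,
            symptomatic_fraction >= 0, symptomatic_fraction <= 1,
            infectious_period_days > 0, isolation_days > 0,
            quarantine_days > 0, tracing_window_days > 0,
            beta >= 0, beta <= 1,
            seed_tau_min_days >= 0, seed_tau_max_days >= seed_tau_min_days)
  structure(as.list(environment()), class = "epi_params")
}

#' @export
print.epi_params <- function(x, ...) {
  cat(sprintf(
    "<epi_params> beta=%.4g eps_I=%.3g eps_T=%.3g symptomatic=%.0f%%\n",
    x$beta, x$eps_I, x$eps_T, 100 * x$symptomatic_fraction))
  cat(sprintf("  infectious %gd, isolation %gd, quarantine %gd, tracing %gd\n",
              x$infectious_period_days, x$isolation_days, x$quarantine_days,
              x$tracing_window_days))
  invisible(x)
}

# status codes
.S <- 0L; .I <- 1L; .R <- 2L
# confinement codes
.FREE <- 0L; .ISO <- 1L; .QUAR <- 2L

#' Fresh epidemiological state
#'
#' All nodes susceptible and unconfined, with an empty rolling contact log of
#' `tracing_window_days * steps_per_day` steps.
#'
#' @param n_nodes Number of nodes.
#' @param params An [epi_params()].
#' @param steps_per_day Epidemic updates per day.
#' @return Object of class `epi_state`. Core fields: `status` (0 = S, 1 = I,
#'   2 = R), `conf` (0 = free, 1 = isolated, 2 = quarantined), `conf_end`
#'   (absolute step of release), `tau` (infection age in days, `NA` unless
#'   infected at some point), symptom flags, `ever_infected`/`ever_confined`
#'   histories and `infector`.
#' @export
epi_state <- function(n_nodes, params, steps_per_day = 12) {
  window <- as.integer(params$tracing_window_days * steps_per_day)
  structure(list(
    n_nodes = as.integer(n_nodes),
    steps_per_day = as.integer(steps_per_day),
    status = rep(.S, n_nodes),
    conf = rep(.FREE, n_nodes),
    conf_end = rep(NA_integer_, n_nodes),
    tau = rep(NA_real_, n_nodes),
    will_sym = rep(FALSE, n_nodes),
    symptomatic = rep(FALSE, n_nodes),
    ever_infected = rep(FALSE, n_nodes),
    ever_confined = rep(FALSE, n_nodes),
    infector = rep(NA_integer_, n_nodes),
    contact_log = vector("list", window),
    log_steps = rep(-1L, window),
    new_isolations = integer(0),
    last_new_infected = integer(0)
  ), class = "epi_state")
}

#' @export
print.epi_state <- function(x, ...) {
  cat(sprintf("<epi_state> N=%d  S=%d I=%d R=%d | isolated=%d quarantined=%d\n",
              x$n_nodes, sum(x$status == .S), sum(x$status == .I),
              sum(x$status == .R), sum(x$conf == .ISO), sum(x$conf == .QUAR)))
  invisible(x)
}

#' Seed the index case
#'
#' Infects exactly one uniformly chosen node with an infection age drawn
#' uniformly from `[seed_tau_min_days, seed_tau_max_days]` (0 to 10 days by
#' default) and draws its symptomatic fate.
#'
#' @param state A fresh [epi_state()] (errors if any node is non-susceptible).
#' @param params An [epi_params()].
#' @return The updated state.
#' @export
seed_infection <- function(state, params) {
  if (any(state$status != .S)) stop("seed_infection requires an all-susceptible state")
  node <- sample.int(state$n_nodes, 1L)
  state$status[node] <- .I
  state$tau[node] <- stats::runif(1, params$seed_tau_min_days, params$seed_tau_max_days)
  state$will_sym[node] <- stats::runif(1) < params$symptomatic_fraction
  state$ever_infected[node] <- TRUE
  state
}

# Append a (confinement-stripped) layer to the rolling contact log.
record_contacts <- function(state, layer, step) {
  window <- length(state$contact_log)
  slot <- (step - 1L) %% window + 1L
  state$contact_log[[slot]] <- layer
  state$log_steps[slot] <- step
  state
}

#' Disease transmission over one contact layer
#'
#' For every contact between a free infected node `i` and a free susceptible
#' node `j`, `j` becomes infected with probability `beta * omega(tau_i)`,
#' independently per contact. If several infectors succeed on the same node in
#' the same step, one is attributed at random. Newly infected nodes start at
#' `tau = 0` and draw their symptomatic fate.
#'
#' @param state An [epi_state()]; confined nodes are assumed to have been
#'   stripped from `layer` already.
#' @param layer Two-column contact matrix.
#' @param params An [epi_params()].
#' @param curve An [infectivity_curve()].
#' @return The updated state; `state$last_new_infected` holds the indices
#'   infected in this step.
#' @export
transmission_step <- function(state, layer, params, curve) {
  state$last_new_infected <- integer(0)
  if (nrow(layer) == 0 || params$beta == 0) return(state)
  a <- layer[, 1]; b <- layer[, 2]
  free <- state$conf == .FREE
  inf_a <- state$status[a] == .I & free[a]
  inf_b <- state$status[b] == .I & free[b]
  sus_a <- state$status[a] == .S & free[a]
  sus_b <- state$status[b] == .S & free[b]
  src <- c(a[inf_a & sus_b], b[inf_b & sus_a])
  tgt <- c(b[inf_a & sus_b], a[inf_b & sus_a])
  if (length(src) == 0) return(state)
  pr <- params$beta * curve$omega(state$tau[src])
  hit <- stats::runif(length(pr)) < pr
  src <- src[hit]; tgt <- tgt[hit]
  if (length(tgt) == 0) return(state)
  if (length(tgt) > 1) {
    perm <- sample.int(length(tgt))       # random infector attribution on ties
    src <- src[perm]; tgt <- tgt[perm]
    keep <- !duplicated(tgt)
    src <- src[keep]; tgt <- tgt[keep]
  }
  state$status[tgt] <- .I
  state$tau[tgt] <- 0
  state$will_sym[tgt] <- stats::runif(length(tgt)) < params$symptomatic_fraction
  state$ever_infected[tgt] <- TRUE
  state$infector[tgt] <- src
  state$last_new_infected <- tgt
  state
}

#' Within-host progression, isolation and confinement bookkeeping
#'
#' Advances infection ages by `step_days`; fires symptom onset for
#' symptomatic-fated nodes via the incremental hazard
#' `[s(tau + d) - s(tau)] / [1 - s(tau)]` (so onset times follow `s`);
#' isolates symptomatic free or quarantined infected nodes with the per-step
#' hazard `1 - (1 - eps_I)^step_days`; recovers non-isolated infected nodes
#' whose age reaches the infectious period; releases confined nodes whose
#' timer has expired (isolated nodes become recovered at release).
#'
#' @param state An [epi_state()].
#' @param params An [epi_params()].
#' @param curve An [infectivity_curve()].
#' @param step_days Step length in days (`1 / steps_per_day`).
#' @param step Current absolute step index.
#' @return The updated state; `state$new_isolations` holds nodes isolated in
#'   this step (their contacts still need [trace_and_quarantine()]).
#' @export
progression_step <- function(state, params, curve, step_days, step) {
  state$new_isolations <- integer(0)
  inf <- state$status == .I
  if (any(inf)) {
    old_tau <- state$tau[inf]
    new_tau <- old_tau + step_days
    state$tau[inf] <- new_tau
    # symptom onset
    cand <- which(inf & state$will_sym & !state$symptomatic)
    if (length(cand)) {
      s_old <- curve$s(state$tau[cand] - step_days)
      s_new <- curve$s(state$tau[cand])
      h <- ifelse(s_old >= 1, 1, (s_new - s_old) / (1 - s_old))
      fire <- stats::runif(length(cand)) < h
      state$symptomatic[cand[fire]] <- TRUE
    }
  }
  # isolation of symptomatic, not-yet-isolated infected nodes
  if (params$eps_I > 0) {
    elig <- which(state$status == .I & state$symptomatic & state$conf != .ISO)
    if (length(elig)) {
      h_iso <- 1 - (1 - params$eps_I)^step_days
      fire <- stats::runif(length(elig)) < h_iso
      new_iso <- elig[fire]
      if (length(new_iso)) {
        state$conf[new_iso] <- .ISO
        state$conf_end[new_iso] <- step + as.integer(params$isolation_days *
                                                       state$steps_per_day)
        state$ever_confined[new_iso] <- TRUE
        state$new_isolations <- new_iso
      }
    }
  }
  # natural recovery (isolated nodes recover at the end of isolation instead);
  # small tolerance absorbs accumulated floating error in the age increments
  rec <- state$status == .I & state$conf != .ISO &
    !is.na(state$tau) & state$tau >= params$infectious_period_days - 1e-9
  state$status[rec] <- .R
  # confinement expiry
  expired <- !is.na(state$conf_end) & state$conf != .FREE & step >= state$conf_end
  if (any(expired)) {
    iso_exp <- expired & state$conf == .ISO
    state$status[iso_exp] <- .R
    state$conf[expired] <- .FREE
    state$conf_end[expired] <- NA_integer_
  }
  state
}

# Distinct partners of `node` over the trailing tracing window.
recent_contacts <- function(state, node, step) {
  window <- length(state$contact_log)
  slots <- which(state$log_steps > step - window & state$log_steps > 0L)
  if (!length(slots)) return(integer(0))
  partners <- unlist(lapply(slots, function(s) {
    m <- state$contact_log[[s]]
    if (is.null(m) || nrow(m) == 0) return(integer(0))
    c(m[m[, 1] == node, 2], m[m[, 2] == node, 1])
  }), use.names = FALSE)
  unique(partners)
}

#' Contact tracing and preventive quarantine
#'
#' Each distinct partner of a newly isolated node over the trailing 7-day
#' contact window is quarantined independently with probability `eps_T`,
#' unless recovered, already isolated or already quarantined. Quarantine lasts
#' `quarantine_days`; quarantined infected nodes ("true positives") that show
#' symptoms are promoted to isolation by [progression_step()], triggering
#' their own tracing.
#'
#' @param state An [epi_state()].
#' @param isolated_node Node that has just transitioned to isolated.
#' @param params An [epi_params()].
#' @param step Current absolute step index.
#' @return The updated state.
#' @export
trace_and_quarantine <- function(state, isolated_node, params, step) {
  if (params$eps_T == 0) return(state)
  partners <- recent_contacts(state, isolated_node, step)
  partners <- partners[state$status[partners] != .R &
                         state$conf[partners] == .FREE]
  if (!length(partners)) return(state)
  hit <- partners[stats::runif(length(partners)) < params$eps_T]
  if (length(hit)) {
    state$conf[hit] <- .QUAR
    state$conf_end[hit] <- step + as.integer(params$quarantine_days *
                                               state$steps_per_day)
    state$ever_confined[hit] <- TRUE
  }
  state
}

#' Estimate the reproduction number by direct offspring counting
#'
#' Runs `n_runs` independent epidemic-only simulations on the configured
#' network and returns the mean number of secondary infections directly
#' caused by the index case. By default (`index_tau0 = NULL`) the index is
#' seeded exactly as in scenario runs, with a uniform 0-10-day initial
#' infection age, so the part of the infectious period already spent is
#' discounted — this is the quantity the reported reproduction number refers
#' to. Passing `index_tau0 = 0` observes the index from the moment of
#' infection instead (the branching-process mean of a fresh infection).
#'
#' @param config A [network_config()].
#' @param params An [epi_params()].
#' @param curve An [infectivity_curve()].
#' @param n_runs Number of independent simulations.
#' @param index_tau0 Initial infection age of the index case in days, or
#'   `NULL` for the model's random seeding.
#' @return Mean offspring count (numeric scalar) with attribute `"se"` (the
#'   Monte-Carlo standard error) and `"offspring"` (the per-run counts).
#' @export
estimate_R0 <- function(config, params, curve, n_runs = 1000,
                        index_tau0 = NULL) {
  stopifnot(n_runs >= 1)
  tables <- layer_tables(config)
  schedule <- if (config$pairing_period_days > 0) {
    round_robin_schedule(config$n_bubbles, config$pairing_period_days,
                         config$steps_per_day)
  } else NULL
  offspring <- vapply(seq_len(n_runs), function(r) {
    index_offspring_once(config, params, curve, index_tau0, tables, schedule)
  }, 0)
  out <- mean(offspring)
  attr(out, "se") <- stats::sd(offspring) / sqrt(n_runs)
  attr(out, "offspring") <- offspring
  out
}

# One epidemic-only run, terminated once the index case can no longer
# transmit; returns its direct offspring count.
index_offspring_once <- function(config, params, curve, index_tau0,
                                 tables = layer_tables(config),
                                 schedule = NULL) {
  spd <- config$steps_per_day
  step_days <- 1 / spd
  if (is.null(schedule) && config$pairing_period_days > 0) {
    schedule <- round_robin_schedule(config$n_bubbles, config$pairing_period_days, spd)
  }
  state <- epi_state(config$n_nodes, params, spd)
  state <- seed_infection(state, params)
  index <- which(state$status == .I)
  if (!is.null(index_tau0)) state$tau[index] <- index_tau0
  max_steps <- as.integer((params$seed_tau_max_days + params$infectious_period_days +
                             params$isolation_days + 1) * spd)
  for (step in seq_len(max_steps)) {
    layer <- sample_layer_tbl(config, tables, active_matching(schedule, step))
    if (nrow(layer)) {
      free <- state$conf == .FREE
      layer <- layer[free[layer[, 1]] & free[layer[, 2]], , drop = FALSE]
    }
    state <- record_contacts(state, layer, step)
    state <- transmission_step(state, layer, params, curve)
    state <- progression_step(state, params, curve, step_days, step)
    for (v in state$new_isolations) {
      state <- trace_and_quarantine(state, v, params, step)
    }
    # isolated index nodes recover at release and never transmit again
    if (state$status[index] != .I || state$conf[index] == .ISO) break
  }
  sum(state$infector == index, na.rm = TRUE)
}

#' Calibrate the transmission scale to a target reproduction number
#'
#' Iteratively rescales `beta` so that [estimate_R0()] matches `target_r0`
#' (offspring counts are nearly linear in `beta` at these scales, so damped
#' proportional updates converge in a few rounds), then re-estimates at the
#' final value with `n_final` runs.
#'
#' @param config A [network_config()].
#' @param params An [epi_params()] providing the starting `beta`.
#' @param curve An [infectivity_curve()].
#' @param target_r0 Target reproduction number (1.64 for the reference
#'   parameter setting).
#' @param n_runs Simulations per calibration iteration.
#' @param n_iter Calibration iterations.
#' @param n_final Simulations for the confirmatory estimate.
#' @param index_tau0 Passed to [estimate_R0()].
#' @return List with `beta`, the confirmatory `r0_hat` (with its `se`
#'   attribute) and the iteration `trace`.
#' @export
calibrate_beta <- function(config, params, curve, target_r0 = 1.64,
                           n_runs = 400, n_iter = 5, n_final = 1000,
                           index_tau0 = NULL) {
  beta <- params$beta
  trace <- data.frame(iter = integer(0), beta = numeric(0), r0_hat = numeric(0))
  for (it in seq_len(n_iter)) {
    params$beta <- beta
    r0_hat <- estimate_R0(config, params, curve, n_runs, index_tau0)
    trace <- rbind(trace, data.frame(iter = it, beta = beta,
                                     r0_hat = as.numeric(r0_hat)))
    if (r0_hat <= 0) {   # too small to measure: climb
      beta <- min(1, beta * 4)
      next
    }
    beta <- min(1, beta * (target_r0 / as.numeric(r0_hat))^0.8)
  }
  params$beta <- beta
  r0_hat <- estimate_R0(config, params, curve, n_final, index_tau0)
  list(beta = beta, r0_hat = r0_hat, trace = trace)
}
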