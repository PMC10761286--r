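test_that("index-case seeding infects exactly one node with age in [0, 10]", {
  par <- epi_params()
  set.seed(1)
  st <- seed_infection(epi_state(680, par), par)
  expect_equal(sum(st$status == 1L), 1L)
  expect_equal(sum(st$status == 0L), 679L)
  tau0 <- st$tau[st$status == 1L]
  expect_gte(tau0, 0); expect_lte(tau0, 10)
  expect_error(seed_infection(st, par), "susceptible")

  taus <- vapply(1:2000, function(i) {
    s <- seed_infection(epi_state(10, par), par)
    s$tau[s$status == 1L]
  }, 0)
  expect_equal(mean(taus), 5, tolerance = 0.1)   # uniform over [0, 10]
})

test_that("per-contact transmission probability is beta * omega(tau)", {
  crv <- infectivity_curve()
  par0 <- epi_params(beta = 0)
  lay <- cbind(1L, 2L)

  st <- infected_state(2, par0, nodes = 1, taus = 4)
  set.seed(2)
  for (i in 1:20) {
    st2 <- transmission_step(st, lay, par0, crv)
    expect_equal(st2$status, st$status)   # beta = 0: no infections ever
  }

  # S-S contact changes nothing
  par <- epi_params(beta = 0.5)
  ss <- epi_state(2, par)
  expect_equal(transmission_step(ss, lay, par, crv)$status, c(0L, 0L))

  # Monte-Carlo infection fraction on a repeated single S-I edge at fixed tau
  tau_fix <- 4
  target <- par$beta * crv$omega(tau_fix)
  M <- 40000
  set.seed(3)
  base <- infected_state(2, par, nodes = 1, taus = tau_fix)
  hits <- sum(vapply(seq_len(M), function(i) {
    transmission_step(base, lay, par, crv)$status[2] == 1L
  }, NA))
  se <- sqrt(target * (1 - target) / M)
  expect_lt(abs(hits / M - target), 4 * se)
})

test_that("untreated infections recover exactly at the infectious period", {
  par <- epi_params(eps_I = 0, beta = 0)
  crv <- infectivity_curve()
  st <- infected_state(3, par, nodes = 2, taus = 0, will_sym = TRUE)
  step_days <- 1 / 12
  for (step in 1:119) {
    st <- progression_step(st, par, crv, step_days, step)
    expect_equal(st$status[2], 1L)            # still infected below 10 days
    expect_length(st$new_isolations, 0)       # eps_I = 0: no isolations ever
  }
  st <- progression_step(st, par, crv, step_days, 120L)
  expect_equal(st$status[2], 2L)              # recovered exactly at tau = 10
  expect_false(any(st$ever_confined))
})

test_that("asymptomatic infections are never isolated regardless of eps_I", {
  par <- epi_params(eps_I = 1, beta = 0)
  crv <- infectivity_curve()
  st <- infected_state(2, par, nodes = 1, taus = 0, will_sym = FALSE)
  set.seed(4)
  for (step in 1:120) {
    st <- progression_step(st, par, crv, 1 / 12, step)
    expect_length(st$new_isolations, 0)
  }
  expect_equal(st$status[1], 2L)
})

test_that("symptom onset follows the incremental hazard of s(tau)", {
  par <- epi_params(eps_I = 0, beta = 0)
  crv <- infectivity_curve()
  set.seed(5)
  onsets <- vapply(1:2000, function(i) {
    st <- infected_state(1, par, nodes = 1, taus = 0, will_sym = TRUE)
    for (step in 1:120) {
      st <- progression_step(st, par, crv, 1 / 12, step)
      if (st$symptomatic[1]) return(step / 12)
    }
    NA_real_
  }, 0)
  onsets <- onsets[!is.na(onsets)]
  # marginal onset times follow the log-normal CDF: compare the median
  expect_equal(stats::median(onsets), 5.5, tolerance = 0.15)
})

test_that("tracing quarantines distinct 7-day contacts, not older ones", {
  par <- epi_params(eps_I = 1, eps_T = 1, beta = 0)
  st <- epi_state(6, par)
  st$status[1] <- 1L; st$tau[1] <- 5

  # recent contacts (same day) and a contact 8 days before tracing
  st <- record_contacts(st, cbind(1L, 5L), step = 120L - 8L * 12L)  # 8 days old
  st <- record_contacts(st, cbind(c(1L, 1L, 1L), c(2L, 3L, 4L)), step = 120L)
  st$conf[1] <- 1L
  set.seed(6)
  st2 <- trace_and_quarantine(st, 1L, par, step = 120L)
  expect_equal(which(st2$conf == 2L), c(2L, 3L, 4L))   # eps_T = 1: all three
  expect_equal(st2$conf[5], 0L)                        # too old to trace

  # eps_T = 0 never quarantines
  par0 <- epi_params(eps_I = 1, eps_T = 0)
  expect_equal(trace_and_quarantine(st, 1L, par0, 120L)$conf, st$conf)

  # recovered contacts are exempt
  st$status[2] <- 2L
  st3 <- trace_and_quarantine(st, 1L, par, step = 120L)
  expect_equal(st3$conf[2], 0L)
})

test_that("symptomatic quarantined nodes are promoted to isolation", {
  par <- epi_params(eps_I = 1, beta = 0)
  crv <- infectivity_curve()
  st <- infected_state(2, par, nodes = 1, taus = 5, will_sym = TRUE)
  st$symptomatic[1] <- TRUE
  st$conf[1] <- 2L; st$conf_end[1] <- 500L
  st$ever_confined[1] <- TRUE
  set.seed(7)
  st <- progression_step(st, par, crv, 1 / 12, step = 10L)
  expect_equal(st$conf[1], 1L)               # now isolated
  expect_equal(st$new_isolations, 1L)        # and will trigger its own tracing
})

test_that("isolated nodes recover when isolation ends", {
  par <- epi_params(eps_I = 0, beta = 0, isolation_days = 10)
  crv <- infectivity_curve()
  st <- infected_state(1, par, nodes = 1, taus = 2)
  st$conf[1] <- 1L; st$conf_end[1] <- 130L
  for (step in 100:129) {
    st <- progression_step(st, par, crv, 1 / 12, step)
    expect_equal(st$status[1], 1L)   # still infected while isolated
    expect_equal(st$conf[1], 1L)
  }
  st <- progression_step(st, par, crv, 1 / 12, 130L)
  expect_equal(st$status[1], 2L)     # recovered at release
  expect_equal(st$conf[1], 0L)
})

test_that("offspring counting matches the closed form on a 3-node clique", {
  # complete 3-node graph every step; the index starts at infection age 5 and
  # is infectious (constant probability q per contact) for exactly k steps;
  # later infections only become infectious at age 5, so they never compete.
  q <- 0.12; k <- 12L
  cfg <- network_config(n_nodes = 3, n_bubbles = 1, cluster_sizes = 3,
                        links = 3, p_intra = 1, steps_per_day = 12)
  crv <- infectivity_curve(omega_fn = function(tau) as.numeric(tau >= 5),
                           s_fn = function(tau) 0)
  par <- epi_params(eps_I = 0, eps_T = 0, beta = q,
                    infectious_period_days = 5 + k / 12,
                    seed_tau_min_days = 5, seed_tau_max_days = 5)
  closed_form <- 2 * (1 - (1 - q)^k)
  set.seed(8)
  r0 <- estimate_R0(cfg, par, crv, n_runs = 3000, index_tau0 = NULL)
  expect_lt(abs(as.numeric(r0) - closed_form), 4 * attr(r0, "se"))

  par0 <- epi_params(beta = 0)
  expect_equal(as.numeric(estimate_R0(cfg, par0, crv, n_runs = 20)), 0)
})
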