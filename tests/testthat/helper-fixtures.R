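# Shared fixtures: small network configurations and brute-force oracles.

ref_sizes <- rep(68L, 10L)   # the reference population: 680 nodes, 10 bubbles

# Brute-force pair-type counts by enumerating every node pair.
enumerate_pair_counts <- function(cluster_sizes) {
  memb <- rep.int(seq_along(cluster_sizes), cluster_sizes)
  prs <- utils::combn(sum(cluster_sizes), 2L)
  same <- memb[prs[1, ]] == memb[prs[2, ]]
  c(intra = sum(same), inter = sum(!same))
}

small_config <- function(p = 5, ...) {
  network_config(n_nodes = 120, n_bubbles = 6, links = 90, p = p, ...)
}

# A state with chosen nodes infected at chosen ages (bypassing seeding).
infected_state <- function(n_nodes, params, nodes, taus,
                           will_sym = rep(FALSE, length(nodes)),
                           steps_per_day = 12) {
  st <- epi_state(n_nodes, params, steps_per_day)
  st$status[nodes] <- 1L
  st$tau[nodes] <- taus
  st$will_sym[nodes] <- will_sym
  st$ever_infected[nodes] <- TRUE
  st
}
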