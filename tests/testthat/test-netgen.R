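test_that("expected link counts match brute-force pair enumeration", {
  expect_equal(expected_links(ref_sizes, 0, 0)$total, 0)
  pc <- enumerate_pair_counts(ref_sizes)
  el <- expected_links(ref_sizes, p_intra = 1, p_inter = 0)
  expect_equal(el$l_intra, pc[["intra"]])   # 22780 pairs within 10 bubbles of 68
  expect_equal(el$l_inter, 0)
  # unequal sizes against the same enumeration oracle
  sizes <- c(5L, 9L, 16L)
  pc2 <- enumerate_pair_counts(sizes)
  el2 <- expected_links(sizes, p_intra = 0.3, p_inter = 0.05)
  expect_equal(el2$l_intra, pc2[["intra"]] * 0.3)
  expect_equal(el2$l_inter, pc2[["inter"]] * 0.05)
})

test_that("p_inter solved from the link budget hits the budget exactly", {
  # all links between bubbles
  expect_equal(solve_p_inter(ref_sizes, links = 400, p_intra = 0), 400 / 208080)

  # modularity ratios solved against a brute-force linear system on the
  # enumerated pair-type counts
  pc <- enumerate_pair_counts(ref_sizes)
  for (ratio in c(5, 50, 199)) {
    cfg <- network_config(n_nodes = 680, n_bubbles = 10, links = 400, p = ratio)
    p_inter_oracle <- 400 / (pc[["intra"]] * ratio + pc[["inter"]])
    expect_equal(cfg$p_inter, p_inter_oracle, tolerance = 1e-12)
    expect_equal(cfg$p_intra, ratio * p_inter_oracle, tolerance = 1e-12)
    el <- expected_links(ref_sizes, cfg$p_intra, cfg$p_inter)
    expect_equal(el$total, 400, tolerance = 1e-9)
  }
  cfg199 <- network_config(n_nodes = 680, n_bubbles = 10, links = 400, p = 199)
  expect_equal(cfg199$p_inter, 8.436e-5, tolerance = 1e-4)
  expect_equal(cfg199$p_intra, 1.6788e-2, tolerance = 1e-4)
  cfg5 <- network_config(n_nodes = 680, n_bubbles = 10, links = 400, p = 5)
  expect_equal(cfg5$p_inter, 1.2423e-3, tolerance = 1e-4)
  expect_equal(cfg5$p_intra, 6.2116e-3, tolerance = 1e-4)

  # infeasible budgets are refused
  expect_error(solve_p_inter(ref_sizes, links = 400, p_intra = 1), "p_inter")
})

test_that("generalized budget solution reduces to the equal-size closed form", {
  set.seed(42)
  for (i in 1:10) {
    Nc <- sample(3:12, 1)
    nc <- sample(5:40, 1)
    N <- Nc * nc
    sizes <- rep(nc, Nc)
    # draw budgets for which a p_inter in [0, 1] certainly exists
    L <- round(stats::runif(1, 5, 0.4 * Nc * nc * (N - nc) / 2))
    p_intra_max <- L / (Nc * nc * (nc - 1) / 2)
    p_intra <- stats::runif(1, 0, min(1, p_intra_max))
    closed_form <- 2 * L / (Nc * nc * (N - nc)) - (nc - 1) / (N - nc) * p_intra
    expect_equal(solve_p_inter(sizes, L, p_intra), closed_form,
                 tolerance = 1e-12)
  }
})

test_that("round-robin schedules cover every bubble pair exactly once", {
  sched <- round_robin_schedule(10, d_days = 10, steps_per_day = 12)
  expect_length(sched$rounds, 9)
  expect_equal(sched$round_length_steps, 120)
  expect_true(all(vapply(sched$rounds, nrow, 0L) == 5L))
  all_pairs <- do.call(rbind, sched$rounds)
  expect_equal(nrow(all_pairs), choose(10, 2))
  expect_false(any(duplicated(all_pairs)))
  # within a round every bubble appears exactly once
  for (r in sched$rounds) expect_setequal(as.vector(r), 1:10)

  expect_equal(round_robin_schedule(2, 1)$rounds, list(cbind(1L, 2L)))

  # odd bubble count: a bye sits out once per cycle, all pairs still covered
  s5 <- round_robin_schedule(5, d_days = 5)
  expect_length(s5$rounds, 5)
  expect_true(all(vapply(s5$rounds, nrow, 0L) == 2L))
  p5 <- do.call(rbind, s5$rounds)
  expect_equal(nrow(p5), choose(5, 2))
  expect_false(any(duplicated(p5)))
  byes <- vapply(s5$rounds, function(r) setdiff(1:5, as.vector(r)), 0L)
  expect_setequal(byes, 1:5)
})

test_that("sampled layers respect probabilities, budget and matchings", {
  cfg <- small_config(p = 5)
  zero <- cfg
  zero$p_intra <- 0; zero$p_inter <- 0
  set.seed(1)
  expect_equal(nrow(sample_layer(zero)), 0L)

  # Monte-Carlo link budget on a small configuration
  set.seed(2)
  sizes <- vapply(1:2000, function(i) nrow(sample_layer(cfg)), 0L)
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - cfg$links), 3 * se)

  # with a matching, inter-bubble links occur only between matched bubbles
  matching <- cbind(c(1L, 3L, 5L), c(2L, 4L, 6L))
  memb <- cfg$membership
  set.seed(3)
  for (i in 1:50) {
    lay <- sample_layer(cfg, matching)
    expect_true(all(lay[, 1] < lay[, 2]))
    ca <- memb[lay[, 1]]; cb <- memb[lay[, 2]]
    inter <- ca != cb
    if (any(inter)) {
      keys <- paste(pmin(ca[inter], cb[inter]), pmax(ca[inter], cb[inter]))
      expect_true(all(keys %in% paste(matching[, 1], matching[, 2])))
    }
  }
})

test_that("bubble pairing preserves expected intra and inter link counts", {
  cfg <- small_config(p = 5)
  # analytic expectation: summed boosted block probabilities equal the
  # unmatched inter expectation (brute force over pair types)
  n <- cfg$cluster_sizes; N <- cfg$n_nodes
  matching <- cbind(c(1L, 3L, 5L), c(2L, 4L, 6L))
  p_pair <- function(a, b) cfg$p_inter *
    (n[a] * (N - n[a]) + n[b] * (N - n[b])) / (2 * n[a] * n[b])
  exp_inter_matched <- sum(apply(matching, 1, function(m)
    n[m[1]] * n[m[2]] * p_pair(m[1], m[2])))
  expect_equal(exp_inter_matched,
               expected_links(n, cfg$p_intra, cfg$p_inter)$l_inter,
               tolerance = 1e-12)

  # and by Monte Carlo
  memb <- cfg$membership
  set.seed(4)
  counts <- t(vapply(1:3000, function(i) {
    lay <- sample_layer(cfg, matching)
    if (nrow(lay) == 0) return(c(0, 0))
    same <- memb[lay[, 1]] == memb[lay[, 2]]
    c(sum(same), sum(!same))
  }, c(0, 0)))
  el <- expected_links(n, cfg$p_intra, cfg$p_inter)
  for (k in 1:2) {
    se <- stats::sd(counts[, k]) / sqrt(nrow(counts))
    expect_lt(abs(mean(counts[, k]) - c(el$l_intra, el$l_inter)[k]), 3.5 * se)
  }
})

test_that("temporal networks are deterministic under a fixed seed", {
  cfg <- small_config(p = 5, pairing_period_days = 2)
  set.seed(99); tn1 <- build_temporal_network(cfg, 48)
  set.seed(99); tn2 <- build_temporal_network(cfg, 48)
  expect_identical(tn1$layers, tn2$layers)
  expect_length(build_temporal_network(cfg, 0)$layers, 0)
})

test_that("edge-list round trip preserves the temporal network", {
  cfg <- small_config(p = 5)
  set.seed(5)
  tn <- build_temporal_network(cfg, 10)
  ef <- tempfile(fileext = ".csv"); mf <- tempfile(fileext = ".csv")
  write_temporal_network(tn, ef, mf)
  back <- read_temporal_network(ef, mf, horizon_steps = 10)
  expect_equal(length(back$layers), 10)
  for (s in 1:10) {
    expect_equal(unname(back$layers[[s]]), unname(tn$layers[[s]]))
  }
  expect_equal(back$membership, tn$membership)
  unlink(c(ef, mf))
})
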