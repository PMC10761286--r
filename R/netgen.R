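#' Expected intra- and inter-community link counts of a block-model layer
#'
#' For a stochastic block model with communities ("bubbles") of sizes
#' `cluster_sizes`, a within-bubble connection probability `p_intra` and a
#' between-bubble connection probability `p_inter`, the expected number of
#' links in one layer decomposes as
#' \deqn{l_{intra} = \sum_i \frac{n_i (n_i - 1)}{2} p_{intra}, \qquad
#'       l_{inter} = \sum_i \frac{n_i (N - n_i)}{2} p_{inter},}
#' with \eqn{N = \sum_i n_i}.
#'
#' @param cluster_sizes Integer vector of bubble sizes \eqn{n_i}.
#' @param p_intra Within-bubble connection probability, in `[0, 1]`.
#' @param p_inter Between-bubble connection probability, in `[0, 1]`.
#' @return A list with components `l_intra`, `l_inter` and `total`.
#' @examples
#' expected_links(rep(68, 10), p_intra = 6.2116e-3, p_inter = 1.2423e-3)
#' @export
expected_links <- function(cluster_sizes, p_intra, p_inter) {
  stopifnot(all(cluster_sizes >= 2), p_intra >= 0, p_intra <= 1,
            p_inter >= 0, p_inter <= 1)
  n <- as.numeric(cluster_sizes)
  N <- sum(n)
  l_intra <- sum(n * (n - 1) / 2) * p_intra
  l_inter <- sum(n * (N - n) / 2) * p_inter
  list(l_intra = l_intra, l_inter = l_inter, total = l_intra + l_inter)
}

# Pair-type counts: number of intra-community and inter-community node pairs.
pair_counts <- function(cluster_sizes) {
  n <- as.numeric(cluster_sizes)
  N <- sum(n)
  list(intra = sum(n * (n - 1) / 2), inter = sum(n * (N - n) / 2))
}

#' Solve the between-bubble probability under a fixed expected-link budget
#'
#' Inverts the link-budget constraint
#' \eqn{L = \sum_i [n_i(n_i-1)/2\, p_{intra} + n_i(N-n_i)/2\, p_{inter}]}
#' for `p_inter`, given `p_intra`. With equal bubble sizes
#' \eqn{n_i = n_c} this is
#' \deqn{p_{inter} = \frac{2L}{N_c n_c (N - n_c)} - \frac{n_c - 1}{N - n_c} p_{intra}.}
#'
#' @param cluster_sizes Integer vector of bubble sizes.
#' @param links Expected number of links per layer (the budget `L`).
#' @param p_intra Within-bubble connection probability.
#' @return `p_inter`, guaranteed to lie in `[0, 1]`; errors otherwise.
#' @examples
#' solve_p_inter(rep(68, 10), links = 400, p_intra = 0)   # all links inter
#' @export
solve_p_inter <- function(cluster_sizes, links, p_intra) {
  stopifnot(links > 0, p_intra >= 0, p_intra <= 1)
  pc <- pair_counts(cluster_sizes)
  if (pc$inter == 0) {      # single bubble: the budget must be met by p_intra
    if (abs(pc$intra * p_intra - links) > 1e-9 * max(1, links)) {
      stop("single-bubble configuration: links must equal ",
           "sum(n_i (n_i - 1) / 2) * p_intra")
    }
    return(0)
  }
  p_inter <- (links - pc$intra * p_intra) / pc$inter
  if (p_inter < -1e-12 || p_inter > 1 + 1e-12) {
    stop("no p_inter in [0, 1] satisfies the link budget: p_intra = ",
         p_intra, " gives p_inter = ", signif(p_inter, 6))
  }
  min(max(p_inter, 0), 1)
}

# Solve (p_intra, p_inter) from the modularity ratio p = p_intra / p_inter
# under the budget: S_intra * p_intra + S_inter * p_inter = L.
solve_from_ratio <- function(cluster_sizes, links, ratio) {
  stopifnot(ratio >= 0, links > 0)
  pc <- pair_counts(cluster_sizes)
  p_inter <- links / (pc$intra * ratio + pc$inter)
  p_intra <- ratio * p_inter
  if (p_intra > 1 || p_inter > 1) {
    stop("link budget not attainable with probabilities in [0, 1]")
  }
  list(p_intra = p_intra, p_inter = p_inter)
}

#' Configuration of a modular temporal contact network
#'
#' Bundles the structural parameters of the layered stochastic block model:
#' `n_nodes` nodes partitioned into bubbles of sizes `cluster_sizes`
#' (contiguous blocks: the first \eqn{n_1} nodes form bubble 1, and so on),
#' an expected number of `links` per layer, and the modularity ratio
#' `p = p_intra / p_inter`. Exactly one of `p` or `p_intra` must be supplied;
#' the other probability is solved from the link budget so every generated
#' layer has `links` expected links regardless of modularity.
#'
#' `pairing_period_days > 0` switches on temporal clustering ("temporal social
#' bubbles"): inter-bubble contacts are concentrated between matched bubble
#' pairs which rotate round-robin every `pairing_period_days` days.
#'
#' @param n_nodes Number of nodes `N`.
#' @param n_bubbles Number of bubbles (communities) `N_c`; ignored when
#'   `cluster_sizes` is given.
#' @param cluster_sizes Optional explicit bubble sizes; defaults to an equal
#'   split of `n_nodes` into `n_bubbles`.
#' @param links Expected links per layer (budget `L`).
#' @param p Modularity ratio `p_intra / p_inter` (dimensionless).
#' @param p_intra Alternative to `p`: within-bubble probability, from which
#'   `p_inter` is solved.
#' @param pairing_period_days Days per bubble-pairing round (`0` disables
#'   pairing).
#' @param steps_per_day Network layers (= epidemic updates) per day.
#' @return An object of class `network_config`.
#' @examples
#' cfg <- network_config(n_nodes = 680, n_bubbles = 10, links = 400, p = 5)
#' cfg$p_inter
#' @export
network_config <- function(n_nodes = 680, n_bubbles = 10, cluster_sizes = NULL,
                           links = 400, p = NULL, p_intra = NULL,
                           pairing_period_days = 0, steps_per_day = 12) {
  if (is.null(cluster_sizes)) {
    stopifnot(n_nodes %% n_bubbles == 0)
    cluster_sizes <- rep(n_nodes / n_bubbles, n_bubbles)
  }
  cluster_sizes <- as.integer(cluster_sizes)
  stopifnot(sum(cluster_sizes) == n_nodes, all(cluster_sizes >= 2),
            steps_per_day >= 1, pairing_period_days >= 0)
  n_bubbles <- length(cluster_sizes)
  if (is.null(p) == is.null(p_intra)) {
    stop("supply exactly one of `p` or `p_intra`")
  }
  if (!is.null(p)) {
    pr <- solve_from_ratio(cluster_sizes, links, p)
    p_intra <- pr$p_intra
    p_inter <- pr$p_inter
  } else {
    p_inter <- solve_p_inter(cluster_sizes, links, p_intra)
    p <- if (p_inter > 0) p_intra / p_inter else Inf
  }
  el <- expected_links(cluster_sizes, p_intra, p_inter)
  stopifnot(abs(el$total - links) < 1e-9 * max(1, links))
  structure(
    list(n_nodes = as.integer(n_nodes), n_bubbles = n_bubbles,
         cluster_sizes = cluster_sizes, links = links, p = p,
         p_intra = p_intra, p_inter = p_inter,
         pairing_period_days = as.integer(pairing_period_days),
         steps_per_day = as.integer(steps_per_day),
         membership = rep.int(seq_len(n_bubbles), cluster_sizes)),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>\n")
  cat(sprintf("  %d nodes in %d bubbles (sizes %s)\n", x$n_nodes, x$n_bubbles,
              paste(unique(x$cluster_sizes), collapse = "/")))
  cat(sprintf("  expected links/layer: %g   modularity p = %.4g\n",
              x$links, x$p))
  cat(sprintf("  p_intra = %.4g, p_inter = %.4g\n", x$p_intra, x$p_inter))
  cat(sprintf("  steps/day: %d   pairing period: %s\n", x$steps_per_day,
              if (x$pairing_period_days > 0)
                paste0(x$pairing_period_days, " days") else "off"))
  invisible(x)
}

#' Round-robin bubble-pairing schedule
#'
#' Builds the temporal-clustering tournament: in each round every bubble is
#' matched with exactly one other bubble, and over a full cycle every
#' unordered bubble pair meets exactly once (circle method; `N_c - 1` rounds
#' for even `N_c`). For odd `N_c` a bye is inserted: each round one bubble
#' sits out and has no inter-bubble contacts. If a simulation outlasts one
#' tournament the schedule cycles.
#'
#' @param n_bubbles Number of bubbles (`>= 2`).
#' @param d_days Days per round (the pairing period `d`).
#' @param steps_per_day Epidemic steps per day.
#' @return An object of class `pairing_schedule`: list with `rounds` (a list
#'   of two-column matrices of bubble indices) and `round_length_steps`.
#' @examples
#' sched <- round_robin_schedule(10, d_days = 10, steps_per_day = 12)
#' length(sched$rounds)            # 9 rounds
#' sched$round_length_steps        # 120
#' @export
round_robin_schedule <- function(n_bubbles, d_days, steps_per_day = 12) {
  stopifnot(n_bubbles >= 2, d_days >= 1, steps_per_day >= 1)
  m <- if (n_bubbles %% 2 == 1) n_bubbles + 1L else as.integer(n_bubbles)
  bye <- if (m > n_bubbles) m else NA_integer_
  rounds <- vector("list", m - 1L)
  others <- seq(2L, m)
  for (r in seq_len(m - 1L)) {
    # circle method: fix team 1, rotate the rest
    rot <- c(others[r:length(others)], others[seq_len(r - 1L)])
    arrangement <- c(1L, rot)
    a <- arrangement[seq_len(m / 2L)]
    b <- rev(arrangement)[seq_len(m / 2L)]
    pairs <- cbind(pmin(a, b), pmax(a, b))
    if (!is.na(bye)) pairs <- pairs[pairs[, 1] != bye & pairs[, 2] != bye, , drop = FALSE]
    rounds[[r]] <- unname(pairs)
  }
  structure(list(rounds = rounds,
                 round_length_steps = as.integer(d_days * steps_per_day),
                 n_bubbles = as.integer(n_bubbles)),
            class = "pairing_schedule")
}

#' @export
print.pairing_schedule <- function(x, ...) {
  cat(sprintf("<pairing_schedule> %d bubbles, %d rounds, %d steps/round\n",
              x$n_bubbles, length(x$rounds), x$round_length_steps))
  invisible(x)
}

# Matching active at a given 1-based step index (NULL when pairing is off).
active_matching <- function(schedule, step) {
  if (is.null(schedule)) return(NULL)
  round_idx <- ((step - 1L) %/% schedule$round_length_steps) %% length(schedule$rounds) + 1L
  schedule$rounds[[round_idx]]
}

# Precompute pair-enumeration tables so layers can be sampled by drawing a
# binomial count and uniformly sampling row indices.  `intra` enumerates all
# within-bubble pairs; `inter` all between-bubble pairs, with `inter_block`
# giving, for each unordered bubble pair, the row range of its block.
layer_tables <- function(config) {
  memb <- config$membership
  n <- config$cluster_sizes
  N <- config$n_nodes
  offsets <- c(0L, cumsum(n))
  intra <- do.call(rbind, lapply(seq_along(n), function(ci) {
    idx <- (offsets[ci] + 1L):offsets[ci + 1L]
    t(utils::combn(idx, 2L))
  }))
  nb <- config$n_bubbles
  blocks <- list()
  inter_list <- list()
  row0 <- 0L
  for (a in seq_len(nb - 1L)) {
    for (b in seq((a + 1L), nb)) {
      ia <- (offsets[a] + 1L):offsets[a + 1L]
      ib <- (offsets[b] + 1L):offsets[b + 1L]
      block <- cbind(rep(ia, times = length(ib)), rep(ib, each = length(ia)))
      inter_list[[length(inter_list) + 1L]] <- block
      blocks[[paste(a, b)]] <- c(row0 + 1L, row0 + nrow(block), a, b)
      row0 <- row0 + nrow(block)
    }
  }
  inter <- if (length(inter_list)) do.call(rbind, inter_list)
           else matrix(integer(0), ncol = 2)
  # boosted probability for a matched bubble pair, preserving its expected
  # inter-link total (reduces to p_inter * (N - n_c) / n_c for equal sizes)
  p_pair <- function(a, b) {
    config$p_inter * (n[a] * (N - n[a]) + n[b] * (N - n[b])) / (2 * n[a] * n[b])
  }
  list(intra = intra, inter = inter, blocks = blocks, p_pair = p_pair)
}

sample_layer_tbl <- function(config, tables, matching = NULL) {
  m_intra <- nrow(tables$intra)
  k <- stats::rbinom(1L, m_intra, config$p_intra)
  rows <- if (k > 0) tables$intra[sample.int(m_intra, k), , drop = FALSE] else NULL
  if (is.null(matching)) {
    m_inter <- nrow(tables$inter)
    k2 <- if (m_inter > 0 && config$p_inter > 0)
      stats::rbinom(1L, m_inter, config$p_inter) else 0L
    if (k2 > 0) rows <- rbind(rows, tables$inter[sample.int(m_inter, k2), , drop = FALSE])
  } else {
    for (r in seq_len(nrow(matching))) {
      a <- matching[r, 1]; b <- matching[r, 2]
      blk <- tables$blocks[[paste(a, b)]]
      pp <- tables$p_pair(a, b)
      if (pp > 1) stop("matched-pair probability exceeds 1 (p_pair = ",
                       signif(pp, 4), "); lower p_inter or enlarge bubbles")
      nblk <- blk[2] - blk[1] + 1L
      k2 <- stats::rbinom(1L, nblk, pp)
      if (k2 > 0) {
        rows <- rbind(rows, tables$inter[blk[1] - 1L + sample.int(nblk, k2), ,
                                         drop = FALSE])
      }
    }
  }
  if (is.null(rows)) matrix(integer(0), ncol = 2) else rows
}

#' Sample one contact layer from the block model
#'
#' Draws a single static contact network: every within-bubble node pair is a
#' link independently with probability `p_intra`; without a matching, every
#' between-bubble pair with probability `p_inter`. When a `matching` (a
#' two-column matrix of bubble-index pairs, one row per matched pair) is
#' supplied, inter-bubble links occur only between matched bubbles, with a
#' boosted probability chosen so the expected inter-bubble link count is
#' unchanged.
#'
#' @param config A [network_config()].
#' @param matching Optional perfect matching of bubbles (two-column matrix).
#' @return Integer matrix with two columns `i < j`, one row per undirected
#'   contact; node indices are 1-based.
#' @examples
#' cfg <- network_config(n_nodes = 40, n_bubbles = 4, links = 30, p = 5)
#' set.seed(1); nrow(sample_layer(cfg))
#' @export
sample_layer <- function(config, matching = NULL) {
  sample_layer_tbl(config, layer_tables(config), matching)
}

#' Generate a temporal contact network
#'
#' Samples one independent contact layer per epidemic step. When
#' `pairing_period_days > 0` in the configuration, the bubble matching active
#' at each step follows the round-robin [round_robin_schedule()].
#'
#' @param config A [network_config()].
#' @param horizon_steps Number of layers (epidemic steps) to generate.
#' @return An object of class `temporal_network`: list with `layers` (list of
#'   two-column contact matrices), `membership` (node to bubble index) and the
#'   `config`.
#' @examples
#' cfg <- network_config(n_nodes = 40, n_bubbles = 4, links = 30, p = 5)
#' set.seed(1); tn <- build_temporal_network(cfg, horizon_steps = 24)
#' length(tn$layers)
#' @export
build_temporal_network <- function(config, horizon_steps) {
  stopifnot(horizon_steps >= 0)
  tables <- layer_tables(config)
  schedule <- if (config$pairing_period_days > 0) {
    round_robin_schedule(config$n_bubbles, config$pairing_period_days,
                         config$steps_per_day)
  } else NULL
  layers <- vector("list", horizon_steps)
  for (s in seq_len(horizon_steps)) {
    layers[[s]] <- sample_layer_tbl(config, tables, active_matching(schedule, s))
  }
  structure(list(layers = layers, membership = config$membership,
                 config = config),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  nl <- length(x$layers)
  mean_links <- if (nl > 0) mean(vapply(x$layers, nrow, 0L)) else NA_real_
  cat(sprintf("<temporal_network> %d layers, %d nodes, mean %.1f links/layer\n",
              nl, x$config$n_nodes, mean_links))
  invisible(x)
}

#' Write / read a temporal network as timestamped edge lists
#'
#' The edge file is a plain CSV with header `step,i,j` (one row per contact
#' per layer, 1-based node ids); the optional membership sidecar has header
#' `node,cluster`. Layers with no contacts are preserved via the
#' `horizon_steps` attribute column-free convention: `read_temporal_network`
#' takes the horizon from the maximum step unless given explicitly.
#'
#' @param tn A `temporal_network`.
#' @param edge_file Path of the edge-list CSV.
#' @param membership_file Optional path of the membership CSV.
#' @return `write_temporal_network` returns `edge_file` invisibly;
#'   `read_temporal_network` returns a `temporal_network`-like list with
#'   `layers` and `membership` (and `config = NULL`).
#' @export
write_temporal_network <- function(tn, edge_file, membership_file = NULL) {
  steps <- rep.int(seq_along(tn$layers), vapply(tn$layers, nrow, 0L))
  edges <- do.call(rbind, tn$layers)
  df <- data.frame(step = steps,
                   i = if (is.null(edges)) integer(0) else edges[, 1],
                   j = if (is.null(edges)) integer(0) else edges[, 2])
  utils::write.csv(df, edge_file, row.names = FALSE, quote = FALSE)
  if (!is.null(membership_file)) {
    utils::write.csv(data.frame(node = seq_along(tn$membership),
                                cluster = tn$membership),
                     membership_file, row.names = FALSE, quote = FALSE)
  }
  invisible(edge_file)
}

#' @rdname write_temporal_network
#' @param horizon_steps Number of layers to materialize on read (defaults to
#'   the maximum step present).
#' @export
read_temporal_network <- function(edge_file, membership_file = NULL,
                                  horizon_steps = NULL) {
  df <- utils::read.csv(edge_file)
  stopifnot(all(c("step", "i", "j") %in% names(df)))
  if (is.null(horizon_steps)) horizon_steps <- if (nrow(df)) max(df$step) else 0L
  layers <- vector("list", horizon_steps)
  split_rows <- split(seq_len(nrow(df)), factor(df$step, levels = seq_len(horizon_steps)))
  for (s in seq_len(horizon_steps)) {
    rows <- split_rows[[s]]
    layers[[s]] <- if (length(rows)) {
      cbind(pmin(df$i[rows], df$j[rows]), pmax(df$i[rows], df$j[rows]))
    } else matrix(integer(0), ncol = 2)
  }
  membership <- NULL
  if (!is.null(membership_file)) {
    md <- utils::read.csv(membership_file)
    membership <- md$cluster[order(md$node)]
  }
  structure(list(layers = layers, membership = membership, config = NULL),
            class = "temporal_network")
}
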