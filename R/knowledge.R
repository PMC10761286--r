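#' Knowledge-contagion parameters
#'
#' The knowledge process is a multi-strain SI complex contagion: `n_pieces`
#' independent pieces of knowledge circulate, and a node acquires a piece only
#' after `K` contacts with nodes that already hold it (threshold rule with
#' memory: exposures accumulate across the whole simulation and are never
#' forgotten).
#'
#' @param n_pieces Number of distinct knowledge pieces (20).
#' @param K Exposure threshold: contacts with holders needed to acquire a
#'   piece. The default is calibrated so that, in the strong-bubbles scenario
#'   (`p = 199`, no quarantine), the population-mean knowledge reaches one
#'   bubble's initial endowment on the reported day-43 timescale; see the
#'   package vignette.
#' @return Object of class `knowledge_params`.
#' @export
knowledge_params <- function(n_pieces = 20, K = 10) {
  stopifnot(n_pieces >= 0, K >= 1)
  structure(list(n_pieces = as.integer(n_pieces), K = as.integer(K)),
            class = "knowledge_params")
}

#' Fresh knowledge state
#'
#' Exposure counters and acquisition flags for every node and piece.
#' `acquired` is the up-to-date acquisition matrix (including acquisitions
#' pending activation); `active` is the snapshot taken at the last daily
#' update, which governs who can transmit each piece: acquisitions made
#' during a day only start spreading after the next 24-hour update.
#'
#' @param n_nodes Number of nodes.
#' @param params A [knowledge_params()].
#' @return Object of class `knowledge_state` with integer matrix `exposures`
#'   and logical matrices `acquired` and `active` (nodes in rows, pieces in
#'   columns).
#' @export
knowledge_state <- function(n_nodes, params) {
  P <- params$n_pieces
  structure(list(
    n_nodes = as.integer(n_nodes),
    K = params$K,
    exposures = matrix(0L, n_nodes, P),
    acquired = matrix(FALSE, n_nodes, P),
    active = matrix(FALSE, n_nodes, P)
  ), class = "knowledge_state")
}

#' @export
print.knowledge_state <- function(x, ...) {
  cat(sprintf("<knowledge_state> N=%d pieces=%d mean knowledge=%.3f\n",
              x$n_nodes, ncol(x$acquired), mean_knowledge(x)))
  invisible(x)
}

#' Seed one holder per knowledge piece
#'
#' Each piece is initially possessed by one uniformly chosen node (pieces are
#' seeded independently, so one node can by chance hold several). Seeded
#' pieces are immediately active, i.e. spread from day 0.
#'
#' @param state A fresh [knowledge_state()].
#' @param params A [knowledge_params()].
#' @return The updated state.
#' @export
seed_knowledge <- function(state, params) {
  P <- params$n_pieces
  if (P == 0) return(state)
  holders <- sample.int(state$n_nodes, P, replace = TRUE)
  idx <- cbind(holders, seq_len(P))
  state$acquired[idx] <- TRUE
  state$active[idx] <- TRUE
  state
}

#' Accumulate knowledge exposures over one contact layer
#'
#' For every contact `(i, j)` with neither node confined (the layer is
#' expected to be confinement-stripped already) and every piece held by `j`
#' as of the last daily update but not yet acquired by `i`, the exposure
#' counter of `(i, piece)` increases by one (and symmetrically for `j`).
#' Counters reaching the threshold `K` mark the piece as acquired, but the
#' new holder only starts transmitting after the next [daily_update()].
#'
#' @param state A [knowledge_state()].
#' @param layer Two-column contact matrix.
#' @param confined Optional logical mask of confined (isolated or
#'   quarantined) nodes; contacts touching a confined node are dropped. The
#'   simulation engine passes pre-stripped layers instead.
#' @return The updated state.
#' @export
exposure_step <- function(state, layer, confined = NULL) {
  if (!is.null(confined) && nrow(layer)) {
    layer <- layer[!confined[layer[, 1]] & !confined[layer[, 2]], , drop = FALSE]
  }
  if (nrow(layer) == 0 || ncol(state$acquired) == 0) return(state)
  i <- c(layer[, 1], layer[, 2])
  j <- c(layer[, 2], layer[, 1])
  src <- state$active[j, , drop = FALSE]
  keep <- rowSums(src) > 0
  if (!any(keep)) return(state)
  i <- i[keep]
  inc <- rowsum(src[keep, , drop = FALSE] + 0L, group = i)
  ids <- as.integer(rownames(inc))
  open <- !state$acquired[ids, , drop = FALSE]
  # counters freeze at the threshold: beyond K the count carries no meaning
  expo <- pmin(state$exposures[ids, , drop = FALSE] + inc * open, state$K)
  state$exposures[ids, ] <- expo
  newly <- open & expo >= state$K
  if (any(newly)) {
    acq <- state$acquired[ids, , drop = FALSE]
    acq[newly] <- TRUE
    state$acquired[ids, ] <- acq
  }
  state
}

#' Activate pending acquisitions (24-hour knowledge update)
#'
#' Epidemic variables update every two hours, knowledge eligibility only once
#' a day: this refreshes the transmission snapshot so that pieces acquired
#' during the past day start spreading.
#'
#' @param state A [knowledge_state()].
#' @return The updated state.
#' @export
daily_update <- function(state) {
  state$active <- state$acquired
  state
}

#' Population-mean number of acquired knowledge pieces
#'
#' @param state A [knowledge_state()].
#' @return `sum(acquired) / n_nodes`, a value in `[0, n_pieces]`.
#' @export
mean_knowledge <- function(state) {
  sum(state$acquired) / state$n_nodes
}
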