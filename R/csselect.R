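#' Empirical neighbour model
#'
#' Each agent observes its neighbours' actions every round and keeps, per
#' ordered neighbour pair `(i, k)`, a count table over joint actions
#' `(a_i, a_k)`. Conditional action frequencies are Laplace-smoothed:
#' `P_k(a_k | a_i) = (count(a_i, a_k) + lambda) /
#' (sum_a' count(a_i, a') + lambda * m)`, so the distribution is uniform
#' before any observation and always well defined.
#'
#' @param network a [cg_network].
#' @param n_actions action-space size.
#' @param smoothing Laplace constant `lambda` (default 1).
#' @return an object of class `cg_neighbor_model`.
#' @export
neighbor_model <- function(network, n_actions, smoothing = 1) {
  stopifnot(smoothing > 0)
  counts <- list()
  for (i in seq_len(network$n_nodes) - 1L) {
    for (k in network$adjacency[[i + 1L]]) {
      counts[[nm_key(i, k)]] <- matrix(0L, n_actions, n_actions)
    }
  }
  structure(list(counts = counts, n_actions = n_actions,
                 smoothing = smoothing),
            class = "cg_neighbor_model")
}

nm_key <- function(i, k) paste0(i, ":", k)

#' @rdname neighbor_model
#' @param nm a `cg_neighbor_model`.
#' @param i observing agent (0-based).
#' @param k observed neighbour (0-based, must be adjacent to `i`).
#' @param a_i,a_k the jointly observed 1-based actions.
#' @return `nm_observe()`: the updated model; `nm_prob()`: the vector
#'   `P_k(. | a_i)` over `k`'s actions (sums to 1).
#' @export
nm_observe <- function(nm, i, k, a_i, a_k) {
  key <- nm_key(i, k)
  if (is.null(nm$counts[[key]])) {
    stop(sprintf("agent %d is not a neighbour of agent %d", k, i))
  }
  nm$counts[[key]][a_i, a_k] <- nm$counts[[key]][a_i, a_k] + 1L
  nm
}

#' @rdname neighbor_model
#' @export
nm_prob <- function(nm, i, k, a_i) {
  key <- nm_key(i, k)
  if (is.null(nm$counts[[key]])) {
    stop(sprintf("agent %d is not a neighbour of agent %d", k, i))
  }
  row <- nm$counts[[key]][a_i, ] + nm$smoothing
  row / sum(row)
}

#' Potential value of an action under a coordination set
#'
#' The expected utility agent `i` attributes to playing `a_i` when it
#' coordinates with `CS(i)` and merely predicts the rest:
#' `PV_i(a_i, CS) = sum_{j in CS} max_{a_j} Q_ij(a_i, a_j) +
#' sum_{k in NC} sum_{a_k} P_k(a_k | a_i) Q_ik(a_i, a_k)`,
#' with `NC = tau(i) \ CS`. Coordinated neighbours are credited with the
#' best response (they are assumed to coordinate perfectly); non-coordinated
#' neighbours contribute their predicted average. Since a maximum dominates
#' any average, `PV` is monotone non-decreasing in `CS`.
#'
#' @param i 0-based agent.
#' @param a_i 1-based action.
#' @param cs integer vector of 0-based neighbour ids, a subset of `tau(i)`.
#' @param network a [cg_network].
#' @param edgeq edge Q-tables ([edge_q_tables]).
#' @param nm a [neighbor_model].
#' @return scalar potential value.
#' @export
potential_value <- function(i, a_i, cs, network, edgeq, nm) {
  tau <- network$adjacency[[i + 1L]]
  if (length(setdiff(cs, tau))) stop("cs must be a subset of tau(i)")
  nc <- setdiff(tau, cs)
  pv <- 0
  for (j in cs) {
    pv <- pv + max(q_oriented(edgeq, network, i, j)[a_i, ])
  }
  for (k in nc) {
    pv <- pv + sum(nm_prob(nm, i, k, a_i) *
                     q_oriented(edgeq, network, i, k)[a_i, ])
  }
  pv
}

#' Potential loss of dropping a neighbour set
#'
#' The utility agent `i` forgoes by not coordinating with `NC(i)`:
#' `PL_i(NC) = max_{a_i} PV_i(a_i, tau(i)) - max_{a_i} PV_i(a_i,
#' tau(i) \ NC)`. It satisfies `PL(emptyset) = 0`, monotonicity under set
#' inclusion, and `0 <= PL(NC) <= PL(tau(i))`.
#'
#' @param nc integer vector of 0-based neighbour ids to drop (subset of
#'   `tau(i)`).
#' @inheritParams potential_value
#' @return scalar potential loss (non-negative).
#' @export
potential_loss <- function(i, nc, network, edgeq, nm) {
  tau <- network$adjacency[[i + 1L]]
  if (length(setdiff(nc, tau))) stop("nc must be a subset of tau(i)")
  m <- nm$n_actions
  pv_full <- vapply(seq_len(m), function(a)
    potential_value(i, a, tau, network, edgeq, nm), numeric(1))
  cs <- setdiff(tau, nc)
  pv_cs <- vapply(seq_len(m), function(a)
    potential_value(i, a, cs, network, edgeq, nm), numeric(1))
  max(pv_full) - max(pv_cs)
}

#' Random coordination-set selection
#'
#' Each neighbour is kept independently with probability `delta` (a keep
#' fraction: `delta = 1` keeps the whole neighbourhood, `delta = 0` keeps
#' nobody). The decayed variant draws with the current `delta` and then
#' shrinks it by `decay` down to `floor`, so communication fades over the
#' course of learning.
#'
#' @param tau integer vector of 0-based neighbour ids.
#' @param delta keep probability in `[0, 1]`.
#' @return `select_cs_random()`: the selected subset of `tau`.
#' @export
select_cs_random <- function(tau, delta) {
  stopifnot(delta >= 0, delta <= 1)
  if (!length(tau)) return(integer(0))
  tau[runif(length(tau)) < delta]
}

#' @rdname select_cs_random
#' @param state list with elements `delta`, `decay`, `floor`.
#' @return `select_cs_decay()`: list with `cs` (the selected subset) and
#'   `state` (the decayed state to carry to the next round).
#' @export
select_cs_decay <- function(tau, state) {
  stopifnot(state$floor >= 0, state$decay >= 0)
  cs <- select_cs_random(tau, state$delta)
  state$delta <- max(state$floor, state$delta - state$decay)
  list(cs = cs, state = state)
}

#' Loss-rate coordination-set selection
#'
#' Greedy shrinking of the coordination set under a potential-loss budget:
#' starting from `NC = emptyset`, repeatedly add the neighbour whose removal
#' costs the least potential loss, as long as the resulting
#' `PL_i(NC)` stays within `delta * PL_i(tau(i))`. Here `delta` is an
#' allowed *loss* fraction — `delta = 0` keeps every neighbour whenever
#' dropping any would lose utility, and `delta = 1` unconditionally drops
#' them all. Monotonicity of `PL` under set inclusion makes the greedy
#' order admissible.
#'
#' @param delta allowed loss fraction in `[0, 1]`.
#' @inheritParams potential_value
#' @return integer vector: the coordination set `CS(i) = tau(i) \ NC`.
#' @export
select_cs_lossrate <- function(i, delta, network, edgeq, nm) {
  stopifnot(delta >= 0, delta <= 1)
  tau <- network$adjacency[[i + 1L]]
  if (!length(tau)) return(integer(0))
  if (delta >= 1) return(integer(0))
  pl_full <- potential_loss(i, tau, network, edgeq, nm)
  if (delta == 0 && pl_full > 0) return(tau)
  budget <- delta * pl_full
  nc <- integer(0)
  remaining <- tau
  while (length(remaining)) {
    pls <- vapply(remaining, function(k)
      potential_loss(i, c(nc, k), network, edgeq, nm), numeric(1))
    best <- which.min(pls)
    if (pls[best] <= budget + 1e-12) {
      nc <- c(nc, remaining[best])
      remaining <- remaining[-best]
    } else {
      break
    }
  }
  setdiff(tau, nc)
}
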