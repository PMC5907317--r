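#' Linear decay schedules
#'
#' Learning-rate and exploration-rate schedules decay linearly per round and
#' clamp at a floor: `value(t) = max(floor, init - t * delta)`. The default
#' experiment settings use a learning rate starting at 1.0, decaying by
#' 0.0005 per round with floor 0.6, and an exploration rate starting at 1.0,
#' decaying by a few thousandths per round with floor 0.
#'
#' @param init starting value at round 0.
#' @param delta decrement per round (non-negative).
#' @param floor lower clamp.
#' @param s a schedule.
#' @param t 0-based round index (non-negative).
#' @return `schedule()` returns a `cg_schedule` object; `step_schedule()`
#'   the schedule value at round `t`.
#' @examples
#' step_schedule(schedule(1.0, 0.0005, 0.6), 800)   # 0.6: floor reached
#' @export
schedule <- function(init, delta, floor = 0) {
  stopifnot(is.finite(init), is.finite(delta), delta >= 0, floor <= init)
  structure(list(init = init, delta = delta, floor = floor),
            class = "cg_schedule")
}

#' @rdname schedule
#' @export
step_schedule <- function(s, t) {
  if (any(t < 0)) stop("round index must be non-negative")
  pmax(s$floor, s$init - t * s$delta)
}

#' Edge-factored cooperative Q-update
#'
#' The per-edge temporal-difference update
#' `Q_ij(a_i, a_j) <- (1 - alpha) Q_ij(a_i, a_j) +
#' alpha * (r + gamma * Q_ij(a_i*, a_j*))`, where `(a_i*, a_j*)` is the
#' jointly selected (max-plus) next action restricted to this edge. In the
#' single-state game the "next state" is the same state, so the future term
#' is the same table evaluated at the coordinated action. Each undirected
#' edge owns one shared table, written once per round.
#'
#' @param edgeq edge Q-tables ([edge_q_tables]).
#' @param network a [cg_network].
#' @param i,j 0-based endpoints of the edge.
#' @param a_i,a_j executed actions (1-based), `a_i` being agent `i`'s.
#' @param r observed edge reward.
#' @param a_i_star,a_j_star coordinated next actions for `i` and `j`.
#' @param alpha learning rate in `[0, 1]`.
#' @param gamma discount factor in `[0, 1]`.
#' @return the updated edge Q-table list.
#' @export
update_edge_q <- function(edgeq, network, i, j, a_i, a_j, r,
                          a_i_star, a_j_star, alpha, gamma) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1)
  e <- edge_index(network, i, j)
  if (is.na(e)) stop(sprintf("no edge between agents %d and %d", i, j))
  # canonical table rows belong to the lower-id endpoint
  if (i > j) {
    tmp <- a_i; a_i <- a_j; a_j <- tmp
    tmp <- a_i_star; a_i_star <- a_j_star; a_j_star <- tmp
  }
  q <- edgeq[[e]]
  q[a_i, a_j] <- (1 - alpha) * q[a_i, a_j] +
    alpha * (r + gamma * q[a_i_star, a_j_star])
  edgeq[[e]] <- q
  edgeq
}

#' Epsilon-greedy exploration
#'
#' With probability `eps` pick a uniformly random action, otherwise keep the
#' coordinated choice `a_star`.
#'
#' @param a_star 1-based coordinated action.
#' @param eps exploration probability in `[0, 1]`.
#' @param m action-space size.
#' @return 1-based action.
#' @export
epsilon_greedy <- function(a_star, eps, m) {
  stopifnot(eps >= 0, eps <= 1)
  if (runif(1) < eps) sample.int(m, 1L) else as.integer(a_star)
}

#' Independent Q-learning baseline (IL)
#'
#' Each agent keeps a private action-value vector and learns only from its
#' own action and reward: `Q_i(a) <- Q_i(a) + alpha * (r + gamma * max_a'
#' Q_i(a') - Q_i(a))`. No communication is involved — the zero-message
#' baseline the coordinated learner is compared against.
#'
#' @param localq numeric action-value vector.
#' @param a executed action (1-based).
#' @param r observed reward.
#' @param alpha,gamma learning rate and discount in `[0, 1]`.
#' @param eps exploration probability.
#' @return `il_update()`: the updated vector; `il_select()`: a 1-based
#'   action, epsilon-greedy on `localq` with random tie-breaking.
#' @export
il_update <- function(localq, a, r, alpha, gamma) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1)
  localq[a] <- localq[a] + alpha * (r + gamma * max(localq) - localq[a])
  localq
}

#' @rdname il_update
#' @export
il_select <- function(localq, eps) {
  if (runif(1) < eps) {
    sample.int(length(localq), 1L)
  } else {
    argmax_random_tie(localq)
  }
}

#' Distributed value function baseline (DVF)
#'
#' Each agent mixes its neighbours' value functions into its own update with
#' contribution weights `f(i, j) = 1 / |tau(i)|` for every
#' `j in {i} union tau(i)`:
#' `Q_i(a) <- Q_i(a) + alpha * (r + gamma * sum_j f(i,j) max_a' Q_j(a') -
#' Q_i(a))`. In the stateless game, action selection uses the weighted sum
#' of own and neighbour Q-vectors, `argmax_a sum_j f(i,j) Q_j(a)`, so
#' neighbours' preferences steer the choice. Each round costs one Q-vector
#' exchange per directed neighbour pair.
#'
#' @param localq agent `i`'s action-value vector.
#' @param neighbor_qs list of the neighbours' action-value vectors (possibly
#'   empty, in which case DVF degenerates to IL).
#' @inheritParams il_update
#' @return `dvf_update()`: the updated vector; `dvf_select()`: a 1-based
#'   action.
#' @export
dvf_update <- function(localq, neighbor_qs, a, r, alpha, gamma) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1)
  if (!length(neighbor_qs)) return(il_update(localq, a, r, alpha, gamma))
  f <- 1 / length(neighbor_qs)
  future <- f * max(localq) + sum(vapply(neighbor_qs, max, numeric(1))) * f
  localq[a] <- localq[a] + alpha * (r + gamma * future - localq[a])
  localq
}

#' @rdname dvf_update
#' @export
dvf_select <- function(localq, neighbor_qs, eps = 0) {
  if (eps > 0 && runif(1) < eps) return(sample.int(length(localq), 1L))
  if (!length(neighbor_qs)) return(argmax_random_tie(localq))
  f <- 1 / length(neighbor_qs)
  score <- f * localq
  for (q in neighbor_qs) score <- score + f * q
  argmax_random_tie(score)
}
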