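#' Pairwise coordination games on a network
#'
#' A game specification couples a [cg_network] with one payoff table per
#' edge. Each pair of adjacent agents plays a two-player normal-form game on
#' their shared edge; the global reward of a joint action is the sum of the
#' edge payoffs. Agents are stateless (a single-state repeated game): there
#' are no state transitions, only repeated joint decisions.
#'
#' @param network a [cg_network].
#' @param n_actions size of the (common) action space.
#' @param payoff either a single `n_actions x n_actions` matrix shared by all
#'   edges, or a list with one matrix per edge in the order of
#'   `network$edges`. Entry `[a_i, a_j]` of the table on edge `(i, j)`
#'   (canonical orientation `i < j`) is the reward both endpoints receive.
#' @return an object of class `cg_game`: list with `network`, `n_actions`,
#'   `payoff` (always a list, one matrix per edge).
#' @examples
#' net <- make_regular(6, 2)
#' g <- game_spec(net, 2)
#' global_reward(g, rep(1, 6))   # everyone matched: one +1 per edge
#' @export
game_spec <- function(network, n_actions,
                      payoff = default_coordination_table(n_actions)) {
  stopifnot(inherits(network, "cg_network"))
  n_actions <- as.integer(n_actions)
  e <- n_edges(network)
  if (is.matrix(payoff)) {
    stopifnot(nrow(payoff) == n_actions, ncol(payoff) == n_actions)
    payoff <- rep(list(payoff), e)
  } else {
    stopifnot(is.list(payoff), length(payoff) == e)
    for (tab in payoff) {
      stopifnot(is.matrix(tab), nrow(tab) == n_actions, ncol(tab) == n_actions)
    }
  }
  structure(list(network = network, n_actions = n_actions, payoff = payoff),
            class = "cg_game")
}

#' @export
print.cg_game <- function(x, ...) {
  cat(sprintf("<cg_game: %d agents, %d actions, %d edges>\n",
              x$network$n_nodes, x$n_actions, n_edges(x$network)))
  invisible(x)
}

#' Default pairwise coordination payoff table
#'
#' The canonical pure-coordination game: both agents receive `+1` when they
#' choose the same action and `-1` otherwise. With `m` actions the game has
#' `m` equivalent optimal equilibria (the `m` uniform joint actions), which
#' is what makes the emerging convention a genuine social norm rather than a
#' payoff-forced outcome.
#'
#' @param m number of actions (at least 2).
#' @return an `m x m` numeric matrix with `+1` on the diagonal, `-1` off it.
#' @examples
#' default_coordination_table(2)
#' @export
default_coordination_table <- function(m) {
  m <- as.integer(m)
  if (m < 2L) stop("a coordination game needs at least 2 actions")
  tab <- matrix(-1, m, m)
  diag(tab) <- 1
  tab
}

#' Global reward of a joint action
#'
#' The global reward is the sum over edges of the pairwise payoff,
#' `R(a) = sum_{(i,j) in E} r(a_i, a_j)` — the additive decomposition of the
#' global utility over the coordination graph.
#'
#' @param spec a [game_spec].
#' @param a integer vector of length `n_nodes`: 1-based action index chosen
#'   by each agent (element `i + 1` is agent `i`'s action).
#' @return `global_reward()`: the summed edge payoff. `average_edge_payoff()`:
#'   the same divided by the number of edges; for the default coordination
#'   table it lies in `[-1, 1]` and equals 1 exactly when every adjacent pair
#'   is matched.
#' @examples
#' g <- sensor_fixture()
#' global_reward(g, c(1, 1, 3, 3))   # optimal coverage: 70
#' @export
global_reward <- function(spec, a) {
  net <- spec$network
  if (length(a) != net$n_nodes || anyNA(a)) {
    stop("joint action must assign one action to every agent")
  }
  a <- as.integer(a)
  if (any(a < 1L) || any(a > spec$n_actions)) stop("action index out of range")
  total <- 0
  for (e in seq_len(n_edges(net))) {
    i <- net$edges[e, 1L]; j <- net$edges[e, 2L]
    total <- total + spec$payoff[[e]][a[i + 1L], a[j + 1L]]
  }
  total
}

#' @rdname global_reward
#' @export
average_edge_payoff <- function(spec, a) {
  e <- n_edges(spec$network)
  if (e == 0L) stop("average edge payoff is undefined on an empty edge set")
  global_reward(spec, a) / e
}

#' The 4-sensor / 3-location coverage fixture
#'
#' A small sensor-network coordination problem used as a worked example and
#' test oracle: four sensors on a path, each able to watch one of three
#' target locations, and a location only counts as covered when the two
#' sensors flanking it both watch it. Location rewards are 30, 50, 40.
#' Greedy independent learners are drawn to the single best location
#' (reward 50), while the optimal joint policy covers locations 1 and 3
#' simultaneously for a global reward of 70 — the classic gap between
#' independent and coordinated decisions.
#'
#' @return a [game_spec] on the path `0-1-2-3` with 3 actions and per-edge
#'   payoff tables: edge (0,1) pays 30 iff both choose action 1, edge (1,2)
#'   pays 50 iff both choose action 2, edge (2,3) pays 40 iff both choose
#'   action 3; 0 otherwise.
#' @examples
#' g <- sensor_fixture()
#' global_reward(g, c(2, 2, 2, 2))   # everyone crowds location 2: 50
#' @export
sensor_fixture <- function() {
  net <- cg_network(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
  tab <- function(action, reward) {
    m <- matrix(0, 3, 3)
    m[action, action] <- reward
    m
  }
  game_spec(net, 3, payoff = list(tab(1, 30), tab(2, 50), tab(3, 40)))
}

#' Exhaustive joint-action optimum of a game
#'
#' Enumerates the full joint-action space and returns the maximising joint
#' action and its global reward. Exponential in the number of agents — meant
#' as a ground-truth oracle on small instances, guarded at `m^n <= 1e6`.
#'
#' @param spec a [game_spec].
#' @return list with `action` (1-based integer vector) and `value`.
#' @examples
#' brute_force_optimum(sensor_fixture())$value   # 70
#' @export
brute_force_optimum <- function(spec) {
  res <- enumerate_joint_max(spec$network, spec$payoff, spec$n_actions)
  list(action = res$action, value = res$value)
}

# Shared exhaustive maximiser over a sum of per-edge tables (canonical
# orientation). Used by both the game optimum and the max-plus test oracle.
enumerate_joint_max <- function(network, tables, m) {
  n <- network$n_nodes
  total <- m^n
  if (total > 1e6) {
    stop(sprintf("joint action space too large for enumeration: %d^%d = %g",
                 m, n, total))
  }
  # all joint actions as an (m^n) x n matrix of 1-based action indices
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  value <- numeric(total)
  for (e in seq_len(n_edges(network))) {
    i <- network$edges[e, 1L] + 1L
    j <- network$edges[e, 2L] + 1L
    value <- value + tables[[e]][cbind(grid[, i], grid[, j])]
  }
  best <- which.max(value)
  list(action = as.integer(grid[best, ]), value = value[best])
}
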