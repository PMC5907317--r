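#' Edge Q-tables on a coordination graph
#'
#' Cooperative Q-learning factors the global action value over the edges of
#' the coordination graph: one table `Q_ij(a_i, a_j)` per undirected edge,
#' shared by both endpoints. Tables are stored in the network's canonical
#' edge order with rows indexed by the lower-id endpoint's action; the
#' reversed orientation is just the transpose (`Q_ji(a_j, a_i) =
#' Q_ij(a_i, a_j)`).
#'
#' @param network a [cg_network].
#' @param n_actions action-space size.
#' @param fill initial value for every entry (default 0).
#' @return list of `n_actions x n_actions` matrices, one per edge, in
#'   `network$edges` order.
#' @export
edge_q_tables <- function(network, n_actions, fill = 0) {
  rep(list(matrix(fill, n_actions, n_actions)), n_edges(network))
}

# Index of the canonical edge (min(i,j), max(i,j)), or NA if absent.
edge_index <- function(network, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  hit <- which(network$edges[, 1L] == lo & network$edges[, 2L] == hi)
  if (length(hit)) hit[1L] else NA_integer_
}

# Q table oriented so rows are agent i's actions and columns agent j's.
q_oriented <- function(edgeq, network, i, j) {
  e <- edge_index(network, i, j)
  if (is.na(e)) stop(sprintf("no edge between agents %d and %d", i, j))
  if (i < j) edgeq[[e]] else t(edgeq[[e]])
}

#' Active edges induced by per-agent coordination sets
#'
#' Each agent `i` picks a coordination set `CS(i)` among its neighbours
#' `tau(i)`; the edge `(i, j)` is active — max-plus messages flow on it in
#' both directions — when at least one endpoint selected the other
#' (`j in CS(i)` or `i in CS(j)`), so one-sided selections still activate
#' the edge and the active set is symmetric by construction.
#'
#' @param network a [cg_network].
#' @param cs_list list of length `n_nodes`; element `i + 1` is an integer
#'   vector of 0-based neighbour ids forming `CS(i)` (must be a subset of
#'   `tau(i)`).
#' @return logical vector over `network$edges` rows: is the edge active?
#' @export
active_edges <- function(network, cs_list) {
  stopifnot(length(cs_list) == network$n_nodes)
  for (i in seq_along(cs_list)) {
    extra <- setdiff(cs_list[[i]], network$adjacency[[i]])
    if (length(extra)) {
      stop(sprintf("CS(%d) contains non-neighbours: %s", i - 1L,
                   paste(extra, collapse = ", ")))
    }
  }
  active <- logical(n_edges(network))
  for (e in seq_len(n_edges(network))) {
    i <- network$edges[e, 1L]; j <- network$edges[e, 2L]
    active[e] <- (j %in% cs_list[[i + 1L]]) || (i %in% cs_list[[j + 1L]])
  }
  active
}

# Active neighbours of agent i (0-based) under an active-edge indicator.
active_neighbours <- function(network, active, i) {
  nb <- network$adjacency[[i + 1L]]
  if (!length(nb)) return(integer(0))
  keep <- vapply(nb, function(k) active[edge_index(network, i, k)], logical(1))
  nb[keep]
}

# Row index of the directed message i -> j in the message matrix:
# edge e = (lo, hi) owns rows 2e-1 (lo -> hi) and 2e (hi -> lo).
message_row <- function(network, i, j) {
  e <- edge_index(network, i, j)
  if (i < j) 2L * e - 1L else 2L * e
}

# Empty (zero) message set for a network with m actions.
empty_messages <- function(network, m) {
  list(mu = matrix(0, 2L * n_edges(network), m),
       iterations = 0L, converged = FALSE, messages_sent = 0L)
}

#' One max-plus message
#'
#' The message from agent `i` to an active neighbour `j` about `j`'s action:
#' `mu_ij(a_j) = max_{a_i} ( Q_ij(a_i, a_j) + sum_{k in ACS(i) \ j}
#' mu_ki(a_i) )`, where `ACS(i)` are `i`'s active neighbours. A
#' normalisation constant is then absorbed by mean-centring the vector
#' (subtracting its mean over `a_j`), which bounds message drift on loopy
#' graphs without ever changing any argmax.
#'
#' @param i,j 0-based sender and receiver; the edge `(i, j)` must be active.
#' @param edgeq edge Q-tables ([edge_q_tables]).
#' @param msgs a message set as returned by [run_maxplus] / `empty` start.
#' @param network a [cg_network].
#' @param active logical active-edge indicator ([active_edges]).
#' @return numeric vector over `a_j` with mean zero.
#' @export
compute_message <- function(i, j, edgeq, msgs, network, active) {
  e <- edge_index(network, i, j)
  if (is.na(e) || !active[e]) {
    stop(sprintf("edge (%d, %d) is not active", i, j))
  }
  q <- q_oriented(edgeq, network, i, j)   # rows a_i, cols a_j
  m <- ncol(q)
  incoming <- numeric(nrow(q))
  for (k in setdiff(active_neighbours(network, active, i), j)) {
    incoming <- incoming + msgs$mu[message_row(network, k, i), ]
  }
  mu <- vapply(seq_len(m), function(aj) max(q[, aj] + incoming), numeric(1))
  mu - mean(mu)
}

#' Run max-plus message passing on the active subgraph
#'
#' Iterates the messages of [compute_message] until the largest absolute
#' message change falls below `tol` or `deadline` iterations have run,
#' whichever comes first — an anytime contract mirroring a communication
#' budget. Two sweep schedules are provided:
#'
#' * `"sequential"` (default): Gauss-Seidel sweeps — each iteration visits
#'   every directed message once, in a fresh random order drawn from the
#'   run's RNG, and each message is computed from the *latest* incoming
#'   messages. Information crosses the whole graph within few sweeps and
#'   the random orders act as a stochastic relaxation on loopy graphs.
#' * `"synchronous"`: Jacobi sweeps — all directed messages are recomputed
#'   from the previous iteration's messages. Fully deterministic given the
#'   Q-tables, convenient for analysis.
#'
#' On tree-structured active graphs both schedules reach the exact fixed
#' point and the selected joint action maximises the summed edge Q-values;
#' on loopy graphs max-plus is a heuristic.
#'
#' @inheritParams compute_message
#' @param deadline maximum number of sweeps (at least 1).
#' @param tol convergence threshold on the max absolute message change.
#' @param schedule `"sequential"` or `"synchronous"`.
#' @return list with `mu` (matrix `2E x m`; row `2e-1` is the message
#'   `lo -> hi` of edge `e`, row `2e` the reverse), `iterations`,
#'   `converged`, and `messages_sent` (directed messages:
#'   `2 * |active| * iterations`).
#' @export
run_maxplus <- function(edgeq, network, active, deadline = 5L, tol = 1e-5,
                        schedule = c("sequential", "synchronous")) {
  stopifnot(deadline >= 1L, tol > 0)
  schedule <- match.arg(schedule)
  if (n_edges(network) == 0L || !any(active)) {
    m0 <- if (length(edgeq)) ncol(edgeq[[1]]) else 1L
    return(empty_messages(network, m0))
  }
  m <- ncol(edgeq[[1]])
  msgs <- empty_messages(network, m)
  act_idx <- which(active)
  sent <- 0L
  iters <- 0L
  converged <- FALSE
  if (schedule == "sequential") {
    # directed message rows of the active edges, in canonical order
    rows0 <- as.vector(rbind(2L * act_idx - 1L, 2L * act_idx))
    ends <- cbind(as.vector(t(network$edges[act_idx, c(1, 2), drop = FALSE])),
                  as.vector(t(network$edges[act_idx, c(2, 1), drop = FALSE])))
    ord <- seq_along(rows0)
    for (it in seq_len(deadline)) {
      ord <- fisher_yates(ord)  # keeps shuffling the previous order
      delta <- 0
      for (x in ord) {
        new_mu <- compute_message(ends[x, 1L], ends[x, 2L], edgeq, msgs,
                                  network, active)
        delta <- max(delta, max(abs(new_mu - msgs$mu[rows0[x], ])))
        msgs$mu[rows0[x], ] <- new_mu
      }
      sent <- sent + 2L * length(act_idx)
      iters <- it
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  } else {
    for (it in seq_len(deadline)) {
      new_mu <- msgs$mu
      for (e in act_idx) {
        i <- network$edges[e, 1L]; j <- network$edges[e, 2L]
        new_mu[2L * e - 1L, ] <- compute_message(i, j, edgeq, msgs, network,
                                                 active)
        new_mu[2L * e, ] <- compute_message(j, i, edgeq, msgs, network, active)
      }
      delta <- max(abs(new_mu - msgs$mu))
      msgs$mu <- new_mu
      sent <- sent + 2L * length(act_idx)
      iters <- it
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  msgs$iterations <- iters
  msgs$converged <- converged
  msgs$messages_sent <- sent
  msgs
}

# Fisher-Yates shuffle drawing one uniform per swap (high index down),
# mirroring the engine's shuffle so R and C++ sweeps visit messages in the
# same order under the same RNG state.
fisher_yates <- function(x) {
  for (i in seq(length(x), 2L)) {
    j <- min(floor(runif(1) * i) + 1L, i)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select an agent's action from converged messages
#'
#' `a_i* = argmax_{a_i} sum_{k in ACS(i)} mu_ki(a_i)` over the agent's
#' active neighbours, ties broken uniformly at random with the run's RNG.
#' An agent with no active edges falls back to the greedy action under its
#' empirical neighbour model — the action maximising the expected Q-value
#' summed over all neighbours, `argmax_a sum_{k in tau(i)} sum_{a_k}
#' P_k(a_k | a) Q_ik(a, a_k)` — or, without a model, to a uniform random
#' action.
#'
#' @inheritParams compute_message
#' @param n_actions action-space size.
#' @param nm optional [neighbor_model] for the isolated-agent fallback.
#' @return 1-based action index.
#' @export
select_action <- function(i, msgs, network, active, n_actions,
                          edgeq = NULL, nm = NULL) {
  acs <- active_neighbours(network, active, i)
  if (length(acs)) {
    score <- numeric(n_actions)
    for (k in acs) score <- score + msgs$mu[message_row(network, k, i), ]
  } else if (!is.null(nm) && !is.null(edgeq) &&
             length(network$adjacency[[i + 1L]])) {
    score <- expected_neighbour_value(i, network, edgeq, nm, n_actions)
  } else {
    score <- numeric(n_actions)   # uniform tie-break = uniform random
  }
  argmax_random_tie(score)
}

# sum_{k in tau(i)} E_{a_k ~ P_k(.|a_i)} Q_ik(a_i, a_k) for every a_i.
expected_neighbour_value <- function(i, network, edgeq, nm, n_actions) {
  score <- numeric(n_actions)
  for (k in network$adjacency[[i + 1L]]) {
    q <- q_oriented(edgeq, network, i, k)
    for (ai in seq_len(n_actions)) {
      score[ai] <- score[ai] + sum(nm_prob(nm, i, k, ai) * q[ai, ])
    }
  }
  score
}

# argmax with uniform random tie-breaking (uses the ambient RNG).
argmax_random_tie <- function(score, tol = 1e-12) {
  best <- which(score >= max(score) - tol)
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' Joint action from one max-plus run
#'
#' Convenience wrapper applying [select_action] to every agent.
#'
#' @inheritParams select_action
#' @return integer vector of 1-based actions, one per agent.
#' @export
select_joint_action <- function(msgs, network, active, n_actions,
                                edgeq = NULL, nm = NULL) {
  vapply(seq_len(network$n_nodes) - 1L,
         function(i) select_action(i, msgs, network, active, n_actions,
                                   edgeq = edgeq, nm = nm),
         integer(1))
}

#' Exhaustive joint argmax of the edge-factored value
#'
#' Enumerates all `m^n` joint actions and maximises the summed edge
#' Q-values — the exact ground truth max-plus approximates. Guarded at
#' `m^n <= 1e6`; intended as a test oracle on small instances.
#'
#' @param edgeq edge Q-tables ([edge_q_tables]).
#' @param network a [cg_network].
#' @return list with `action` (1-based) and `value`.
#' @export
brute_force_joint_argmax <- function(edgeq, network) {
  m <- ncol(edgeq[[1]])
  enumerate_joint_max(network, edgeq, m)
}
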