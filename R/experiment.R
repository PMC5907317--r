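#' Experiment configuration
#'
#' Assembles and validates the configuration for one simulation run. The
#' defaults reproduce the standard large single-state setting: a population
#' on a small-world network of mean degree 6 playing the pure coordination
#' game, learning rate decaying 1.0 -> 0.6 at 0.0005/round, exploration
#' decaying from 1.0 at 0.004/round to 0, max-plus with a 5-iteration
#' deadline and message tolerance 1e-5.
#'
#' @param topology list: `kind` one of `"regular"`, `"er"`, `"small_world"`,
#'   `"scale_free"`, `"file"`; plus its parameters (`n`, `k`, `p`, `d`,
#'   `beta`, `m`, `path`).
#' @param game list: `n_actions`, and `payoff` either `"coordination"`
#'   (default) or `"sensor_fixture"`.
#' @param learning list: `alpha` and `epsilon` schedules (each
#'   `list(init, delta, floor)`), `gamma`, and `algorithm` one of
#'   `"coordinated"`, `"IL"`, `"DVF"`.
#' @param csselect list: `strategy` one of `"all"`, `"random"`,
#'   `"decayed_random"`, `"loss_rate"`; `delta`, `decay`, `floor`,
#'   `smoothing`.
#' @param maxplus list: `deadline`, `tol`, `schedule` (`"sequential"`
#'   random-order Gauss-Seidel sweeps, the default, or `"synchronous"`
#'   Jacobi sweeps), `warm_start` (carry messages across rounds instead of
#'   zero-initialising them; default `FALSE`).
#' @param rounds number of learning rounds (>= 1).
#' @param window consecutive greedy-optimal evaluations required to declare
#'   norm emergence.
#' @param early_stop stop once convergence is confirmed.
#' @param seed integer RNG seed for the run.
#' @return an object of class `cg_config`.
#' @export
experiment_config <- function(topology = list(kind = "small_world", n = 100,
                                              k = 6, beta = 0.1),
                              game = list(n_actions = 10),
                              learning = list(),
                              csselect = list(strategy = "all"),
                              maxplus = list(),
                              rounds = 2000, window = 10,
                              early_stop = TRUE, seed = 1) {
  defaults <- list(
    alpha = list(init = 1.0, delta = 5e-4, floor = 0.6),
    epsilon = list(init = 1.0, delta = 0.004, floor = 0),
    gamma = 0, algorithm = "coordinated")
  learning <- utils::modifyList(defaults, learning)
  csselect <- utils::modifyList(
    list(strategy = "all", delta = 1, decay = 0, floor = 0, smoothing = 1),
    csselect)
  maxplus <- utils::modifyList(
    list(deadline = 5L, tol = 1e-5, schedule = "sequential",
         warm_start = FALSE),
    maxplus)

  stopifnot(rounds >= 1, window >= 1,
            learning$gamma >= 0, learning$gamma <= 1,
            maxplus$deadline >= 1, maxplus$tol > 0,
            csselect$delta >= 0, csselect$delta <= 1)
  if (!learning$algorithm %in% c("coordinated", "IL", "DVF")) {
    stop("algorithm must be one of 'coordinated', 'IL', 'DVF'")
  }
  if (!csselect$strategy %in% c("all", "random", "decayed_random",
                                "loss_rate")) {
    stop("unknown coordination-set strategy: ", csselect$strategy)
  }
  structure(list(topology = topology, game = game, learning = learning,
                 csselect = csselect, maxplus = maxplus,
                 rounds = as.integer(rounds), window = as.integer(window),
                 early_stop = isTRUE(early_stop), seed = as.integer(seed)),
            class = "cg_config")
}

# Build the network described by a topology config (uses the ambient RNG).
build_topology <- function(topology) {
  kind <- topology$kind %||% "small_world"
  switch(kind,
    regular = make_regular(topology$n, topology$k),
    er = if (!is.null(topology$p)) make_er(topology$n, topology$p)
         else make_er_degree(topology$n, topology$d),
    small_world = make_small_world(topology$n, topology$k,
                                   topology$beta %||% 0.1),
    scale_free = make_scale_free(topology$n, topology$m %||% 3L),
    file = read_edgelist(topology$path, n_nodes = topology$n),
    stop("unknown topology kind: ", kind))
}

build_game <- function(cfg, network) {
  payoff <- cfg$game$payoff %||% "coordination"
  if (identical(payoff, "sensor_fixture")) return(sensor_fixture())
  game_spec(network, cfg$game$n_actions)
}

#' Run one learning experiment
#'
#' Executes the full learning loop: each round every agent (re)selects its
#' coordination set, max-plus runs on the active subgraph to propose a
#' coordinated joint action, agents act epsilon-greedily, every edge pays
#' out, edge Q-tables take a temporal-difference update towards the observed
#' reward plus the discounted value of the coordinated action, neighbour
#' observations accumulate, and the schedules tick. The `IL` and `DVF`
#' algorithms replace the coordinated machinery with their per-agent value
#' vectors (IL exchanges no messages at all; DVF exchanges one Q-vector per
#' directed neighbour pair per round).
#'
#' Metrics are recorded every round. The greedy-policy evaluation column
#' (`greedy_payoff`) scores the coordinated/greedy action *before*
#' exploration noise, so norm emergence ("average payoff 1") is observable
#' while exploration is still ongoing; a run is `converged` once the greedy
#' evaluation sits at the optimal average edge payoff for `window`
#' consecutive rounds.
#'
#' @param cfg a [experiment_config].
#' @return a `data.frame` with one row per executed round and columns
#'   `round`, `avg_payoff` (training actions), `greedy_payoff`,
#'   `adoption_fraction`, `active_edges`, `maxplus_iterations`,
#'   `messages_round`, `messages_cum`, `converged`; attributes
#'   `converged_round` (NA when the norm never emerged),
#'   `total_messages`, `network`, and `final_greedy_action`.
#' @examples
#' cfg <- experiment_config(topology = list(kind = "regular", n = 10, k = 2),
#'                          game = list(n_actions = 2), rounds = 200,
#'                          seed = 42)
#' res <- run_experiment(cfg)
#' attr(res, "converged_round")
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "cg_config"))
  set.seed(cfg$seed)
  network <- build_topology(cfg$topology)
  spec <- build_game(cfg, network)
  if (cfg$learning$algorithm == "coordinated") {
    run_coordinated(cfg, spec)
  } else {
    run_local_baseline(cfg, spec)
  }
}

strategy_code <- function(strategy) {
  match(strategy, c("all", "random", "decayed_random", "loss_rate")) - 1L
}

run_coordinated <- function(cfg, spec) {
  network <- spec$network
  if (n_edges(network) == 0L) stop("the network has no edges to learn on")
  shared <- spec$payoff[[1]]
  for (tab in spec$payoff) {
    if (!isTRUE(all.equal(tab, shared))) {
      stop("the experiment engine requires a shared per-edge payoff table")
    }
  }
  out <- cpp_run_coordinated(
    n = network$n_nodes, m = spec$n_actions,
    edges = network$edges, payoff = shared,
    alpha_init = cfg$learning$alpha$init,
    alpha_delta = cfg$learning$alpha$delta,
    alpha_floor = cfg$learning$alpha$floor,
    eps_init = cfg$learning$epsilon$init,
    eps_delta = cfg$learning$epsilon$delta,
    eps_floor = cfg$learning$epsilon$floor,
    gamma = cfg$learning$gamma,
    deadline = cfg$maxplus$deadline, tol = cfg$maxplus$tol,
    sequential = identical(cfg$maxplus$schedule, "sequential"),
    warm_start = isTRUE(cfg$maxplus$warm_start),
    strategy = strategy_code(cfg$csselect$strategy),
    cs_delta = cfg$csselect$delta, cs_decay = cfg$csselect$decay,
    cs_floor = cfg$csselect$floor, smoothing = cfg$csselect$smoothing,
    rounds = cfg$rounds, window = cfg$window,
    early_stop = cfg$early_stop)
  met <- as.data.frame(out$metrics)
  names(met) <- c("round", "avg_payoff", "greedy_payoff", "adoption_fraction",
                  "active_edges", "maxplus_iterations", "messages_round",
                  "messages_cum")
  met$converged <- !is.na(out$converged_round) &
    met$round >= out$converged_round
  structure(met,
            converged_round = out$converged_round,
            total_messages = out$total_messages,
            final_greedy_action = out$final_greedy_action,
            network = network)
}

run_local_baseline <- function(cfg, spec) {
  network <- spec$network
  n <- network$n_nodes
  m <- spec$n_actions
  e_cnt <- n_edges(network)
  if (e_cnt == 0L) stop("the network has no edges to learn on")
  algo <- cfg$learning$algorithm
  gamma <- cfg$learning$gamma
  localq <- rep(list(numeric(m)), n)
  rows <- vector("list", cfg$rounds)
  msgs_cum <- 0
  streak <- 0L
  converged_round <- NA_integer_
  target <- max(unlist(spec$payoff))
  incident <- lapply(seq_len(n) - 1L, function(i)
    which(network$edges[, 1L] == i | network$edges[, 2L] == i))
  rounds_run <- 0L
  for (t in seq_len(cfg$rounds) - 1L) {
    alpha <- step_schedule(do.call(schedule, cfg$learning$alpha), t)
    eps <- step_schedule(do.call(schedule, cfg$learning$epsilon), t)
    greedy <- vapply(seq_len(n), function(i) {
      if (algo == "IL") argmax_random_tie(localq[[i]])
      else dvf_select(localq[[i]], localq[network$adjacency[[i]] + 1L])
    }, integer(1))
    a_exec <- vapply(greedy, function(a) epsilon_greedy(a, eps, m), integer(1))
    edge_pay <- function(a) vapply(seq_len(e_cnt), function(e) {
      spec$payoff[[e]][a[network$edges[e, 1L] + 1L],
                       a[network$edges[e, 2L] + 1L]]
    }, numeric(1))
    pay_greedy <- edge_pay(greedy)
    pay_exec <- edge_pay(a_exec)
    # each agent's reward: mean payoff over its incident edges
    for (i in seq_len(n)) {
      inc <- incident[[i]]
      if (!length(inc)) next
      r <- mean(pay_exec[inc])
      if (algo == "IL") {
        localq[[i]] <- il_update(localq[[i]], a_exec[i], r, alpha, gamma)
      } else {
        localq[[i]] <- dvf_update(localq[[i]],
                                  localq[network$adjacency[[i]] + 1L],
                                  a_exec[i], r, alpha, gamma)
      }
    }
    msgs_round <- if (algo == "DVF") 2L * e_cnt else 0L
    msgs_cum <- msgs_cum + msgs_round
    greedy_pay <- mean(pay_greedy)
    streak <- if (greedy_pay >= target - 1e-9) streak + 1L else 0L
    if (streak >= cfg$window && is.na(converged_round)) {
      converged_round <- t - cfg$window + 2L
    }
    tally <- tabulate(greedy, m)
    rows[[t + 1L]] <- data.frame(
      round = t + 1L, avg_payoff = mean(pay_exec), greedy_payoff = greedy_pay,
      adoption_fraction = max(tally) / n, active_edges = 0L,
      maxplus_iterations = 0L, messages_round = msgs_round,
      messages_cum = msgs_cum)
    rounds_run <- t + 1L
    if (cfg$early_stop && !is.na(converged_round) && streak >= cfg$window) {
      break
    }
  }
  met <- do.call(rbind, rows[seq_len(rounds_run)])
  met$converged <- !is.na(converged_round) & met$round >= converged_round
  structure(met,
            converged_round = converged_round,
            total_messages = msgs_cum,
            final_greedy_action = greedy,
            network = network)
}

#' Detect norm emergence in a greedy-evaluation history
#'
#' `TRUE` once the greedy-policy average edge payoff sits at the optimum for
#' `window` consecutive evaluations.
#'
#' @param history numeric vector of greedy average-edge-payoff evaluations.
#' @param window required run length (>= 1).
#' @param target the optimal average edge payoff (1 for the default game).
#' @return logical flag.
#' @export
detect_convergence <- function(history, window, target = 1) {
  stopifnot(window >= 1)
  if (length(history) < window) return(FALSE)
  at <- history >= target - 1e-9
  any(vapply(seq_len(length(at) - window + 1),
             function(s) all(at[s:(s + window - 1)]), logical(1)))
}

#' Total messages sent over a run
#'
#' The coordinated learner counts directed max-plus messages: every
#' iteration of every round sends two messages per active edge. DVF counts
#' one Q-vector exchange per directed neighbour pair per round; IL sends
#' nothing.
#'
#' @param records metrics data frame from [run_experiment].
#' @return total directed message count.
#' @export
count_messages <- function(records) {
  if (!nrow(records)) return(0)
  records$messages_cum[nrow(records)]
}

#' Write / read experiment artifacts
#'
#' Metrics go to CSV with a fixed header; configs load from YAML or JSON
#' (by file extension).
#'
#' @param records metrics data frame from [run_experiment].
#' @param path output/input file path.
#' @return `write_metrics()`: `path`, invisibly. `load_config()`: a
#'   [experiment_config].
#' @export
write_metrics <- function(records, path) {
  cols <- c("round", "avg_payoff", "adoption_fraction", "messages_cum",
            "converged")
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be a .yaml/.yml or .json file"))
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; restore it
  if (is.list(raw$topology) && "FALSE" %in% names(raw$topology) &&
      !"n" %in% names(raw$topology)) {
    names(raw$topology)[names(raw$topology) == "FALSE"] <- "n"
  }
  args <- raw[intersect(names(raw),
                        c("topology", "game", "learning", "csselect",
                          "maxplus", "rounds", "window", "early_stop",
                          "seed"))]
  do.call(experiment_config, args)
}
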