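small_cfg <- function(...) {
  experiment_config(
    topology = list(kind = "regular", n = 12, k = 4),
    game = list(n_actions = 2),
    rounds = 300, seed = 5, ...)
}

test_that("experiment runs are deterministic given config and seed", {
  cfg <- small_cfg(csselect = list(strategy = "random", delta = 0.5))
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "converged_round"), attr(r2, "converged_round"))
})

test_that("invalid configurations are rejected before running", {
  expect_error(experiment_config(rounds = 0))
  expect_error(experiment_config(learning = list(algorithm = "bogus")),
               "algorithm")
  expect_error(experiment_config(csselect = list(strategy = "sometimes")),
               "strategy")
  expect_error(experiment_config(csselect = list(strategy = "random",
                                                 delta = 2)))
})

test_that("metric records have the promised shape and invariants", {
  res <- run_experiment(small_cfg())
  expect_true(all(c("round", "avg_payoff", "greedy_payoff",
                    "adoption_fraction", "messages_cum", "converged")
                  %in% names(res)))
  expect_true(all(diff(res$messages_cum) >= 0))
  expect_true(all(res$avg_payoff >= -1 & res$avg_payoff <= 1))
  expect_true(all(res$adoption_fraction > 0 & res$adoption_fraction <= 1))
  # message accounting identity: per-round counts match the analytic form
  expect_equal(res$messages_round,
               2 * res$active_edges * res$maxplus_iterations)
  expect_equal(res$messages_cum, cumsum(res$messages_round))
  expect_equal(count_messages(res), attr(res, "total_messages"))
})

test_that("norm emergence on the standard 50-agent 2-action setting", {
  converged <- 0L
  for (s in 1:20) {
    cfg <- experiment_config(
      topology = list(kind = "small_world", n = 50, k = 6, beta = 0.1),
      game = list(n_actions = 2),
      rounds = 500, seed = 1000 + s)
    res <- run_experiment(cfg)
    cr <- attr(res, "converged_round")
    if (!is.na(cr) && cr <= 500) converged <- converged + 1L
  }
  expect_gte(converged, 18L)
})

test_that("converged runs have full adoption and stay converged", {
  cfg <- experiment_config(
    topology = list(kind = "small_world", n = 30, k = 4, beta = 0.1),
    game = list(n_actions = 3), rounds = 600, seed = 11,
    early_stop = FALSE)
  res <- run_experiment(cfg)
  cr <- attr(res, "converged_round")
  expect_false(is.na(cr))
  after <- res[res$round >= cr, ]
  expect_true(all(after$greedy_payoff == 1))
  expect_true(all(after$adoption_fraction == 1))
})

test_that("IL exchanges no messages; DVF one per directed neighbour pair", {
  cfg_il <- small_cfg(learning = list(algorithm = "IL",
                                      epsilon = list(init = 1, delta = 0.04,
                                                     floor = 0)))
  res_il <- run_experiment(cfg_il)
  expect_equal(attr(res_il, "total_messages"), 0)
  expect_true(all(res_il$messages_cum == 0))

  cfg_dvf <- small_cfg(learning = list(algorithm = "DVF"))
  res_dvf <- run_experiment(cfg_dvf)
  e <- n_edges(attr(res_dvf, "network"))
  expect_equal(res_dvf$messages_cum, 2 * e * seq_len(nrow(res_dvf)))
})

test_that("DVF improves the average payoff on a random network", {
  cfg <- experiment_config(
    topology = list(kind = "er", n = 50, d = 6),
    game = list(n_actions = 2),
    learning = list(algorithm = "DVF"),
    rounds = 800, seed = 3, early_stop = FALSE)
  res <- run_experiment(cfg)
  early <- mean(res$greedy_payoff[1:50])
  late <- mean(res$greedy_payoff[(nrow(res) - 49):nrow(res)])
  expect_gt(late, early)
  expect_gt(late, 0.5)
})

test_that("cumulative messages scale proportionally with population size", {
  msgs <- vapply(c(100, 200, 500), function(n) {
    per_seed <- vapply(1:10, function(s) {
      cfg <- experiment_config(
        topology = list(kind = "small_world", n = n, k = 6, beta = 0.1),
        game = list(n_actions = 4),
        csselect = list(strategy = "random", delta = 0.5),
        rounds = 100, seed = 2000 + s, early_stop = FALSE)
      attr(run_experiment(cfg), "total_messages")
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  per_agent <- msgs / c(100, 200, 500)
  expect_lt(max(per_agent) / min(per_agent), 1.15)
})

test_that("decayed random selection makes communication fade over rounds", {
  cfg <- experiment_config(
    topology = list(kind = "regular", n = 30, k = 4),
    game = list(n_actions = 3),
    csselect = list(strategy = "decayed_random", delta = 1, decay = 0.01,
                    floor = 0),
    rounds = 120, seed = 6, early_stop = FALSE)
  res <- run_experiment(cfg)
  first <- mean(res$messages_round[1:20])
  last <- mean(res$messages_round[101:120])
  expect_lt(last, first / 2)
  expect_equal(res$messages_round[1], 2 * n_edges(attr(res, "network")) *
                 res$maxplus_iterations[1])
})

test_that("convergence detection requires a sustained optimal window", {
  expect_true(detect_convergence(rep(1, 10), window = 5))
  expect_false(detect_convergence(rep(c(1, 0.5), 10), window = 2))
  expect_false(detect_convergence(c(0.9, 1, 1, 1), window = 4))
  expect_true(detect_convergence(c(0.2, 1, 1, 1), window = 3))
  expect_error(detect_convergence(1, window = 0))
})

test_that("metrics CSV and config files round-trip", {
  res <- run_experiment(small_cfg())
  p <- withr::local_tempfile(fileext = ".csv")
  write_metrics(res, p)
  back <- utils::read.csv(p)
  expect_equal(names(back), c("round", "avg_payoff", "adoption_fraction",
                              "messages_cum", "converged"))
  expect_equal(back$messages_cum, res$messages_cum)

  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("topology:", "  kind: regular", "  n: 10", "  k: 2",
               "game:", "  n_actions: 2", "rounds: 50", "seed: 9"), y)
  cfg <- load_config(y)
  expect_s3_class(cfg, "cg_config")
  expect_equal(cfg$rounds, 50L)
  expect_equal(cfg$topology$n, 10)
})

test_that("the command-line interface simulates, sweeps and reports the oracle", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("topology:", "  kind: [unclosed"), y)
  expect_equal(suppressMessages(cn_cli(c("simulate", "--config", y))), 1L)

  writeLines(c("topology:", "  kind: regular", "  n: 10", "  k: 2",
               "game:", "  n_actions: 2", "rounds: 40", "seed: 9"), y)
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  expect_equal(cn_cli(c("simulate", "--config", y, "--seed", "7",
                        "--out", out1)), 0L)
  expect_equal(cn_cli(c("simulate", "--config", y, "--seed", "7",
                        "--out", out2)), 0L)
  expect_identical(readLines(out1), readLines(out2))

  msg <- capture.output(code <- cn_cli(c("oracle", "--fixture", "sensor")))
  expect_equal(code, 0L)
  expect_true(any(grepl("70", msg)))

  sweep_yaml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("topology:", "  kind: regular", "  \"n\": 12", "  k: 4",
               "game:", "  n_actions: 2", "rounds: 40", "seed: 1",
               "csselect:", "  strategy: random", "  delta: 1.0",
               "sweep:", "  seeds: [1, 2]", "  params:",
               "    csselect.delta: [0.5, 1.0]"), sweep_yaml)
  sweep_dir <- withr::local_tempdir()
  out <- capture.output(code <- cn_cli(c("sweep", "--config", sweep_yaml,
                                         "--out-dir", sweep_dir)))
  expect_equal(code, 0L)
  expect_length(list.files(sweep_dir, pattern = "\\.csv$"), 4L)

  expect_equal(suppressMessages(cn_cli(c("unknown-cmd"))), 1L)
  expect_equal(suppressMessages(cn_cli(character(0))), 1L)
})
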