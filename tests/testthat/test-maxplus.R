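test_that("a single message is the incoming-augmented column maximum, centred", {
  net <- cg_network(2, rbind(c(0, 1)))
  eq <- list(matrix(c(1, -1, -1, 1), 2, 2))
  msgs <- run_maxplus(eq, net, TRUE, deadline = 1)
  # pre-centring column maxima are (1, 1); centred to (0, 0)
  mu <- compute_message(0, 1, eq, list(mu = matrix(0, 2, 2)), net, TRUE)
  expect_equal(mu, c(0, 0))
  expect_equal(as.vector(msgs$mu), rep(0, 4))

  eq0 <- list(matrix(0, 3, 3))
  expect_equal(compute_message(0, 1, eq0, list(mu = matrix(0, 2, 3)),
                               net, TRUE), rep(0, 3))
  expect_error(compute_message(0, 1, eq, list(mu = matrix(0, 2, 2)),
                               net, FALSE), "not active")
})

test_that("messages on a path match direct evaluation of the recursion", {
  # 3-node path 0-1-2 with fixed tables; message 1 -> 2 after messages from 0
  q01 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)   # rows a0, cols a1
  q12 <- matrix(c(0.4, -0.6, -0.1, 0.8), 2, 2)  # rows a1, cols a2
  net <- cg_network(3, rbind(c(0, 1), c(1, 2)))
  eq <- list(q01, q12)
  msgs <- run_maxplus(eq, net, c(TRUE, TRUE), deadline = 10, tol = 1e-12,
                      schedule = "synchronous")
  # hand evaluation: mu_01(a1) = max_a0 q01[a0, a1], centred
  mu01 <- apply(q01, 2, max); mu01 <- mu01 - mean(mu01)
  # mu_12(a2) = max_a1 (q12[a1, a2] + mu01[a1]), centred
  mu12 <- apply(q12 + mu01, 2, max); mu12 <- mu12 - mean(mu12)
  expect_equal(msgs$mu[1, ], mu01)
  expect_equal(msgs$mu[3, ], mu12)
})

test_that("iteration stops at the deadline or on convergence", {
  set.seed(3)
  net <- make_small_world(20, 4, 0.2)
  eq <- random_edgeq(net, 3)
  act <- rep(TRUE, n_edges(net))
  msgs <- run_maxplus(eq, net, act, deadline = 5, tol = 1e-12)
  expect_lte(msgs$iterations, 5L)
  expect_equal(msgs$messages_sent, 2L * n_edges(net) * msgs$iterations)

  none <- run_maxplus(eq, net, rep(FALSE, n_edges(net)))
  expect_equal(none$messages_sent, 0L)
  expect_equal(none$iterations, 0L)
})

test_that("both sweep schedules agree with the compiled kernel", {
  set.seed(17)
  for (rep in 1:5) {
    net <- random_network(10, 0.35)
    m <- sample(2:4, 1)
    eq <- random_edgeq(net, m)
    act <- runif(n_edges(net)) < 0.8
    if (!any(act)) act[1] <- TRUE
    q <- flatten_edgeq(eq)
    seed <- 100 + rep
    set.seed(seed)
    r_seq <- run_maxplus(eq, net, act, deadline = 4, tol = 1e-9)
    set.seed(seed)
    c_seq <- coordnorm:::cpp_maxplus(net$n_nodes, m, net$edges, act, q,
                                     4L, 1e-9, TRUE)
    expect_equal(r_seq$mu, c_seq$mu, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(r_seq$iterations, c_seq$iterations)
    r_sync <- run_maxplus(eq, net, act, deadline = 4, tol = 1e-9,
                          schedule = "synchronous")
    c_sync <- coordnorm:::cpp_maxplus(net$n_nodes, m, net$edges, act, q,
                                      4L, 1e-9, FALSE)
    expect_equal(r_sync$mu, c_sync$mu, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("max-plus is exact on random trees", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    m <- sample(2:4, 1)
    net <- random_tree(n)
    eq <- random_edgeq(net, m)
    act <- rep(TRUE, n_edges(net))
    schedule <- if (rep %% 2) "sequential" else "synchronous"
    msgs <- run_maxplus(eq, net, act, deadline = 2 * n, tol = 1e-10,
                        schedule = schedule)
    a <- select_joint_action(msgs, net, act, m)
    val <- sum(vapply(seq_len(n_edges(net)), function(e)
      eq[[e]][a[net$edges[e, 1] + 1], a[net$edges[e, 2] + 1]], numeric(1)))
    oracle <- brute_force_joint_argmax(eq, net)
    expect_equal(val, oracle$value, tolerance = 1e-9)
  }
})

test_that("shifting all tables by a constant never changes the selection", {
  set.seed(9)
  for (rep in 1:20) {
    net <- random_tree(sample(3:7, 1))
    m <- 3
    eq <- random_edgeq(net, m)
    eq_shift <- lapply(eq, function(x) x + 57.3)
    act <- rep(TRUE, n_edges(net))
    m1 <- run_maxplus(eq, net, act, deadline = 20, tol = 1e-10,
                      schedule = "synchronous")
    m2 <- run_maxplus(eq_shift, net, act, deadline = 20, tol = 1e-10,
                      schedule = "synchronous")
    set.seed(rep); a1 <- select_joint_action(m1, net, act, m)
    set.seed(rep); a2 <- select_joint_action(m2, net, act, m)
    expect_identical(a1, a2)
  }
})

test_that("select_action follows the strongest message and breaks ties uniformly", {
  net <- cg_network(2, rbind(c(0, 1)))
  msgs <- list(mu = rbind(c(0, 0), c(0.3, 0.9)))  # row 2 = agent 1 -> 0
  expect_equal(select_action(0, msgs, net, TRUE, 2), 2L)

  zero <- list(mu = matrix(0, 2, 3))
  set.seed(8)
  draws <- vapply(1:3000, function(r) select_action(0, zero, net, TRUE, 3),
                  integer(1))
  expect_gt(suppressWarnings(chisq.test(tabulate(draws, 3)))$p.value, 1e-4)
})

test_that("with true payoff tables max-plus finds the optimal sensor coverage", {
  spec <- sensor_fixture()
  net <- spec$network
  act <- rep(TRUE, 3)
  msgs <- run_maxplus(spec$payoff, net, act, deadline = 10, tol = 1e-10)
  set.seed(1)
  a <- select_joint_action(msgs, net, act, 3)
  expect_equal(global_reward(spec, a), 70)
})

test_that("isolated agents fall back to the neighbour-model greedy action", {
  net <- cg_network(3, rbind(c(0, 1), c(1, 2)))
  m <- 2
  eq <- list(matrix(c(5, 0, 0, 1), 2, 2), matrix(0, 2, 2))
  nm <- neighbor_model(net, m)
  for (r in 1:50) nm <- nm_observe(nm, 0, 1, 1, 1)   # neighbour plays 1
  msgs <- run_maxplus(eq, net, c(FALSE, FALSE), deadline = 1)
  a <- select_action(0, msgs, net, c(FALSE, FALSE), m, edgeq = eq, nm = nm)
  expect_equal(a, 1L)  # expected Q favours the observed convention
})

test_that("the exhaustive joint argmax refuses oversized instances", {
  net <- make_regular(25, 2)
  eq <- edge_q_tables(net, 4)
  expect_error(brute_force_joint_argmax(eq, net), "too large")
  one <- cg_network(2, rbind(c(0, 1)))
  tab <- matrix(c(0, 3, -1, 2), 2, 2)
  res <- brute_force_joint_argmax(list(tab), one)
  expect_equal(res$value, 3)
  expect_equal(res$action, c(2L, 1L))
})

test_that("active edges are the symmetric union of one-sided selections", {
  net <- cg_network(3, rbind(c(0, 1), c(1, 2)))
  expect_equal(active_edges(net, list(1L, c(0L, 2L), 1L)), c(TRUE, TRUE))
  expect_equal(active_edges(net, list(integer(0), integer(0), integer(0))),
               c(FALSE, FALSE))
  expect_equal(active_edges(net, list(1L, integer(0), integer(0))),
               c(TRUE, FALSE))
  expect_error(active_edges(net, list(2L, integer(0), integer(0))),
               "non-neighbours")
})
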