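make_toy <- function() {
  # N = 10: a 5-cycle of pairs on 1..5, two triangles, one 4-edge
  hypergraph(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1),
                  c(1, 6, 7), c(3, 8, 9), c(6, 7, 8, 10)),
             n = 10, labels = 1:10, quiet = TRUE)
}

test_that("simulation is reproducible by seed and seed-sensitive", {
  H <- make_toy()
  p <- dynamics_params(lambda = 0.8, theta_star = 0.5)
  t1 <- simulate_contagion(H, p, init = 0.5, t_max = 20, seed = 4)
  t2 <- simulate_contagion(H, p, init = 0.5, t_max = 20, seed = 4)
  t3 <- simulate_contagion(H, p, init = 0.5, t_max = 20, seed = 5)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$flip_node, t2$flip_node)
  expect_false(identical(t1$times, t3$times))
})

test_that("event log is self-consistent", {
  H <- make_toy()
  p <- dynamics_params(lambda = 1.2, theta_star = 0.5)
  tr <- simulate_contagion(H, p, init = 1.0, t_max = 30, seed = 11)
  expect_true(all(diff(tr$times) >= 0))
  expect_true(all(tr$kind %in% c("deactivation", "pairwise", "hyperedge")))
  # replay the flips: active counts must match the logged trace
  state <- tr$init_state
  for (ev in seq_along(tr$times)) {
    idx <- tr$flip_node[seq.int(tr$flip_off[ev] + 1L, tr$flip_off[ev + 1L])]
    state[idx] <- 1L - state[idx]
    expect_identical(sum(state), as.integer(tr$n_active[ev]))
  }
  expect_identical(as.integer(state), as.integer(tr$final_state))
  # deactivations flip exactly one node off; activations only turn nodes on
  for (ev in seq_along(tr$times)) {
    k <- tr$flip_off[ev + 1L] - tr$flip_off[ev]
    if (tr$kind[ev] == "deactivation") expect_identical(k, 1L)
    if (tr$kind[ev] == "hyperedge") expect_gte(k, 1L)
  }
})

test_that("absorption time of a lone active node is Exp(delta)", {
  H <- hypergraph(list(c(1, 2)), quiet = TRUE)
  p <- dynamics_params(lambda = 0, delta = 2)
  times <- vapply(1:400, function(r) {
    tr <- simulate_contagion(H, p, init = c(1L, 0L), t_max = 100, seed = r)
    expect_identical(tr$status, "absorbed")
    tr$times[length(tr$times)]
  }, 0)
  # mean 1/delta = 0.5, se = 0.5/sqrt(400)
  expect_lt(abs(mean(times) - 0.5), 3 * 0.5 / sqrt(400))
})

test_that("hyperedge fires only at critical mass and activates all members", {
  # single 4-edge, threshold 2; start with 2 active and no deactivation
  H <- hypergraph(list(1:4), quiet = TRUE)
  p <- dynamics_params(lambda = 5, delta = 0, theta_star = 0.5)
  tr <- simulate_contagion(H, p, init = c(1, 2), t_max = 50, seed = 2)
  expect_identical(length(tr$times), 1L)
  expect_identical(tr$kind[1L], "hyperedge")
  expect_identical(sort(tr$flip_node), c(3L, 4L))
  expect_identical(as.integer(tr$final_state), rep(1L, 4))
  # below critical mass nothing ever happens
  tr0 <- simulate_contagion(H, p, init = c(1L, 0L, 0L, 0L), t_max = 50, seed = 2)
  expect_identical(length(tr0$times), 0L)
  expect_identical(tr0$status, "t_max")
})

test_that("cardinality-2 hyperedges behave as directed SIS infections", {
  # isolated pair with delta = 0: node 1 infects node 2 at rate lambda,
  # first firing time Exp(lambda)
  H <- hypergraph(list(c(1, 2)), quiet = TRUE)
  p <- dynamics_params(lambda = 4, delta = 0)
  times <- vapply(1:400, function(r) {
    tr <- simulate_contagion(H, p, init = c(1L, 0L), t_max = 100, seed = r)
    tr$times[1L]
  }, 0)
  expect_lt(abs(mean(times) - 0.25), 3 * 0.25 / sqrt(400))
})

test_that("next-reaction and direct schedulers sample the same law", {
  H <- make_toy()
  p <- dynamics_params(lambda = 0.35, theta_star = 0.5)
  si <- hypercontagion:::sim_inputs(H, p)
  init <- rep(1L, 10)
  # subcritical-ish: compare absorption times across 250 runs per scheduler
  t_nr <- vapply(1:250, function(r) {
    res <- hypercontagion:::cpp_simulate(si$n, si$ememb, si$eoff, si$theta,
                                         si$rate, p$delta, init, 500, r, 0L, 1e6)
    res$t_end
  }, 0)
  t_dm <- vapply(1:250, function(r) {
    res <- hypercontagion:::cpp_simulate_direct(si$n, si$ememb, si$eoff,
                                                si$theta, si$rate, p$delta,
                                                init, 500, 10000 + r, 1e6)
    res$t_end
  }, 0)
  ks <- suppressWarnings(stats::ks.test(t_nr, t_dm))
  expect_gt(ks$p.value, 0.001)
})

test_that("node_activity replay matches the engine's time accounting", {
  H <- make_toy()
  p <- dynamics_params(lambda = 0.9, theta_star = 0.5)
  tr <- simulate_contagion(H, p, init = 0.5, t_max = 25, seed = 7)
  a <- node_activity(tr)
  expect_equal(a * tr$t_end, tr$active_time, tolerance = 1e-10)
  # windowed version on a hand-checkable sub-interval
  aw <- node_activity(tr, window = c(0.2, 0.8) * tr$t_end)
  expect_true(all(aw >= 0 & aw <= 1))
  expect_error(node_activity(tr, window = c(10, 10)), "empty")
  expect_error(node_activity(tr, window = c(0, 1e6)), "outside")
})

test_that("snapshots are taken at the stride and match replay", {
  H <- make_toy()
  p <- dynamics_params(lambda = 1, theta_star = 0.5)
  tr <- simulate_contagion(H, p, init = 1.0, t_max = 10, seed = 3,
                           snapshot_stride = 50L)
  expect_false(is.null(tr$snapshots))
  expect_identical(ncol(tr$snapshots), 10L)
  state <- tr$init_state
  for (ev in seq_along(tr$times)) {
    idx <- tr$flip_node[seq.int(tr$flip_off[ev] + 1L, tr$flip_off[ev + 1L])]
    state[idx] <- 1L - state[idx]
    if (ev %% 50L == 0L) {
      expect_identical(as.integer(tr$snapshots[ev %/% 50L, ]),
                       as.integer(state))
    }
  }
})

test_that("initial conditions resolve as documented", {
  expect_identical(local_seed <- hypercontagion:::resolve_init(c(2, 4), 5),
                   c(0L, 1L, 0L, 1L, 0L))
  expect_identical(hypercontagion:::resolve_init(c(1, 0, 1, 0, 0), 5),
                   c(1L, 0L, 1L, 0L, 0L))
  set.seed(1)
  y <- hypercontagion:::resolve_init(0.4, 10)
  expect_identical(sum(y), 4L)
  expect_error(hypercontagion:::resolve_init(c(0, 7), 5), "invalid")
})
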