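test_that("qs_summary matches hand-computed moments", {
  p <- numeric(101)
  p[11] <- 0.5; p[21] <- 0.5            # half mass at n = 10, half at n = 20
  s <- qs_summary(p, N = 100)
  expect_equal(s$rho, 15 / 100)
  expect_equal(s$chi, (250 - 225) / 15)
  # unnormalized input is normalized internally
  s2 <- qs_summary(10 * p, N = 100)
  expect_equal(s2, s)
  expect_error(qs_summary(c(1, numeric(10)), N = 10), "zero mean")
})

test_that("find_peaks recovers planted unimodal and bimodal profiles", {
  N <- 100
  n <- 1:N
  uni <- c(0, exp(-(n - 60)^2 / 50))
  expect_equal(find_peaks(uni / sum(uni), w = 1L), 0.6)
  bi <- c(0, exp(-(n - 20)^2 / 40) + 0.8 * exp(-(n - 70)^2 / 40))
  pk <- find_peaks(bi / sum(bi), w = 3L)
  expect_length(pk, 2L)
  expect_equal(pk, c(0.2, 0.7), tolerance = 0.02)
  # a secondary bump below the prominence threshold is dropped
  weak <- c(0, exp(-(n - 20)^2 / 40) + 0.005 * exp(-(n - 70)^2 / 40))
  expect_length(find_peaks(weak / sum(weak), w = 3L, prominence = 0.05), 1L)
})

test_that("QS distribution assigns no mass to the absorbing state", {
  H <- make_hyperblob(40, 4, seed = 2)
  params <- dynamics_params(lambda = 0.4, theta_star = 0.2)
  d <- run_qs(H, params, init = 0.5, seed = 9,
              qs = qs_config(t_r = 50, t_s = 50, c_max = 5))
  expect_s3_class(d, "qs_dist")
  expect_equal(unname(d$prob[1]), 0)
  expect_equal(sum(d$prob), 1)
  expect_true(all(d$node_activity >= 0 & d$node_activity <= 1))
  # per-node activity integrates to the same mean occupancy as the
  # state distribution (two independent accumulators in the engine)
  s <- qs_summary(d)
  expect_equal(mean(d$node_activity), s$rho, tolerance = 1e-8)
})

test_that("with lambda = 0 the QS process is pinned at n = 1", {
  H <- make_hyperblob(30, 4, seed = 3)
  params <- dynamics_params(lambda = 0, theta_star = 0.5)
  d <- run_qs(H, params, init = c(5L), seed = 4,
              qs = qs_config(t_r = 20, t_s = 20, c_max = 3))
  expect_equal(unname(d$prob[2]), 1)    # all mass at n = 1
  expect_equal(qs_summary(d)$rho, 1 / 30)
})

test_that("QS runs are reproducible and converge by the chi criterion", {
  H <- make_hyperblob(50, 4, seed = 5)
  params <- dynamics_params(lambda = 1.2, theta_star = 0.2)
  qs <- qs_config(t_r = 100, t_s = 100, c_max = 50)
  d1 <- run_qs(H, params, init = 1.0, seed = 21, qs = qs)
  d2 <- run_qs(H, params, init = 1.0, seed = 21, qs = qs)
  expect_identical(d1$freq, d2$freq)
  expect_identical(d1$windows, d2$windows)
  expect_true(d1$status %in% c("converged", "c_max"))
  if (d1$status == "converged") {
    ct <- d1$chi_trace
    expect_lt(abs(ct[length(ct)] - ct[length(ct) - 1L]), qs$eps)
  }
  expect_error(run_qs(H, params, init = numeric(0), seed = 1, qs = qs),
               "at least one active")
})

test_that("QS estimates are insensitive to M and p_r", {
  H <- make_hyperblob(60, 4, seed = 6)
  params <- dynamics_params(lambda = 1.5, theta_star = 0.2)
  base <- qs_config(t_r = 200, t_s = 200, c_max = 20)
  r1 <- qs_summary(run_qs(H, params, 1.0, seed = 31, qs = base))
  alt <- qs_config(M = 20L, p_r = 0.2, t_r = 200, t_s = 200, c_max = 20)
  r2 <- qs_summary(run_qs(H, params, 1.0, seed = 32, qs = alt))
  # supercritical regime: both estimates sit on the same active branch
  expect_lt(abs(r1$rho - r2$rho), 0.05)
})

test_that("cluster_branches separates and merges as documented", {
  cb <- hypercontagion:::cluster_branches
  expect_identical(cb(c(0.10, 0.11, 0.50, 0.52), N = 100),
                   c(1L, 1L, 2L, 2L))
  expect_identical(cb(0.4, N = 100), 1L)
  # clusters closer than 3 pooled SEs get re-merged
  rho <- c(0.100, 0.102, 0.104, 0.180, 0.182, 0.184)
  expect_identical(length(unique(cb(rho, N = 20))), 1L)
})

test_that("lambda_sweep produces a labelled branch diagram", {
  H <- make_hyperblob(40, 4, seed = 8)
  qs <- qs_config(t_r = 50, t_s = 50, c_max = 5)
  bd <- lambda_sweep(H, lambdas = c(0.5, 1.5),
                     inits = list(low = c(1L, 2L), high = 1.0),
                     replicas = 2L, seed = 100, theta_star = 0.2, qs = qs)
  expect_s3_class(bd, "branch_diagram")
  expect_equal(nrow(bd), 2 * 2 * 2)
  expect_true(all(c("lambda", "init", "replica", "rho", "chi",
                    "n_peaks", "branch") %in% names(bd)))
  expect_true(all(bd$branch >= 1L))
  expect_true(all(vapply(bd$peaks, is.numeric, TRUE)))
  # deterministic in the base seed
  bd2 <- lambda_sweep(H, lambdas = c(0.5, 1.5),
                      inits = list(low = c(1L, 2L), high = 1.0),
                      replicas = 2L, seed = 100, theta_star = 0.2, qs = qs)
  expect_equal(bd$rho, bd2$rho)
})
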