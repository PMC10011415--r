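test_that("generator entries match the chain rates by hand", {
  # N = 5, lam_k = 2, lam_star = 3, delta = 1, theta = 3, no QS constraint
  p <- blob_params(N = 5, lam_k = 2, lam_star = 3, delta = 1, theta = 3,
                   qs = FALSE)
  Q <- as.matrix(blob_generator(p))
  # state n lives in row/column n + 1
  expect_equal(Q[4, 3], 3)               # death 3 -> 2: delta * 3
  expect_equal(Q[2, 1], 1)               # death 1 -> 0 present without QS
  expect_equal(Q[3, 4], 2 * 2 * 3 / 5)   # birth 2 -> 3
  expect_equal(Q[4, 6], 3)               # jump 3 -> 5 at lam_star
  expect_equal(Q[5, 6], 2 * 4 * 1 / 5 + 3) # birth 4 -> 5 plus jump share a cell
  expect_equal(Q[1, 2], 0)               # state 0 is absorbing
  expect_equal(as.numeric(Matrix::rowSums(Q)), rep(0, 6), tolerance = 1e-12)
})

test_that("the QS constraint removes only the 1 -> 0 transition", {
  p <- blob_params(N = 5, lam_k = 2, lam_star = 3, delta = 1, theta = 3)
  Q <- as.matrix(blob_generator(p))
  expect_equal(Q[2, 1], 0)
  p0 <- blob_params(N = 5, lam_k = 2, lam_star = 3, delta = 1, theta = 3,
                    qs = FALSE)
  Q0 <- as.matrix(blob_generator(p0))
  D <- Q - Q0
  D[2, 1:2] <- 0                         # the zeroed rate and its diagonal
  expect_equal(max(abs(D)), 0)
})

test_that("transient evolution conserves probability and relaxes to pi", {
  p <- blob_params(N = 60, lam_k = 1.5, lam_star = 1, delta = 1,
                   theta_star = 0.2)
  P0 <- numeric(61); P0[2] <- 1          # all mass at n = 1
  out <- blob_evolve(p, P0, times = c(0.5, 5, 1000))
  expect_equal(rowSums(out), rep(1, 3), tolerance = 1e-10)
  expect_true(all(out >= -1e-12))
  pi <- blob_stationary(p)$pi
  expect_lt(max(abs(out[3, ] - pi)), 1e-6)
})

test_that("evolution validates its initial distribution", {
  p <- blob_params(N = 10, lam_k = 1, lam_star = 1, theta = 3)
  expect_error(blob_evolve(p, rep(0.5, 11), times = 1), "normalized")
  expect_error(blob_evolve(p, c(1, numeric(5)), times = 1), "dimension")
  bad <- c(1.5, -0.5, numeric(9))
  expect_error(blob_evolve(p, bad, times = 1), "nonnegative")
})

test_that("without the QS constraint a subcritical chain is absorbed", {
  expect_error(blob_params(N = 30, lam_k = 0.5, lam_star = 0, theta = 31),
               "theta")
  p <- blob_params(N = 30, lam_k = 0.5, lam_star = 0, delta = 1,
                   theta = 30, qs = FALSE)
  P0 <- numeric(31); P0[6] <- 1          # start at n = 5
  out <- blob_evolve(p, P0, times = 200)
  expect_gt(out[1, 1], 1 - 1e-8)
})

test_that("flux recursion agrees with the null-space oracle", {
  p <- blob_params(N = 80, lam_k = 0.8, lam_star = 2, delta = 1,
                   theta_star = 0.25)
  a <- blob_stationary(p)
  b <- blob_nullspace(p)
  expect_lt(max(abs(a$pi - b$pi)), 1e-10)
  expect_lt(a$residual, 1e-8)
})

test_that("with lam_star = 0 the QS chain obeys detailed balance", {
  # pure birth-death: pi_{n+1}/pi_n = beta_n / (delta (n+1))
  p <- blob_params(N = 40, lam_k = 1.2, lam_star = 0, delta = 0.7,
                   theta = 40)
  pi <- blob_stationary(p)$pi
  n <- 1:40
  w <- numeric(40); w[1] <- 1
  for (m in 1:39) {
    beta <- 1.2 * m * (40 - m) / 40
    w[m + 1] <- w[m] * beta / (0.7 * (m + 1))
  }
  w <- w / sum(w)
  expect_equal(unname(pi[-1]), w, tolerance = 1e-12)
  expect_equal(unname(pi[1]), 0)
})

test_that("chain summaries match a hand-computed distribution", {
  p <- blob_params(N = 4, lam_k = 1, lam_star = 1, theta = 3)
  s <- chain_summary(c(0, 0.5, 0, 0, 0.5), p = p)
  expect_equal(s$rho, 2.5 / 4)
  expect_equal(s$chi, (8.5 - 2.5^2) / 2.5)
  expect_equal(s$P_lower, 0.5)
  expect_equal(s$P_upper, 0.5)
  expect_equal(s$rho_lower, 1 / 4)
  expect_equal(s$rho_upper, 1)
  expect_equal(s$chi_lower, 0)
  expect_equal(s$chi_upper, 0)
  # an empty region reports NA
  s2 <- chain_summary(c(0, 1, 0, 0, 0), p = p)
  expect_equal(s2$P_upper, 0)
  expect_true(is.na(s2$rho_upper))
})

test_that("scaling fit recovers a planted power law", {
  Ns <- c(100, 200, 400, 800, 1600)
  fit <- suppressWarnings(fit_scaling_exponent(Ns, 3 * Ns^-0.62))
  expect_equal(fit$mu, 0.62, tolerance = 1e-10)
  expect_lt(fit$se, 1e-10)
  expect_error(fit_scaling_exponent(c(100, 200), c(NA, 0.1)), "at least two")
})

test_that("scaling analysis locates a resolvable window", {
  sc <- scaling_analysis(Ns = c(100, 200, 400, 800),
                         lam_k_grid = seq(0.4, 1.3, by = 0.01),
                         lam_star = 10, theta_star = 0.2)
  expect_s3_class(sc, "blob_scaling")
  expect_equal(nrow(sc$widths), 4L)
  expect_true(all(sc$widths$resolved))
  expect_true(all(sc$widths$width_rho > 0))
  # the window shrinks with system size
  expect_true(all(diff(sc$widths$width_rho) < 0))
  expect_false(is.null(sc$mu_rho))
})

test_that("the annealed chain approximates a sparse hyperblob", {
  # for a sparse k-regular pairwise layer the chain's n(N-n)/N drive is an
  # annealed approximation: agreement is close but not exact, so the
  # tolerance here is deliberately loose (the exact correspondence for the
  # complete layer is checked elsewhere)
  p <- blob_params(N = 50, lam_k = 2, lam_star = 5, delta = 1,
                   theta_star = 0.2)
  chain <- chain_summary(blob_stationary(p))
  H <- make_hyperblob(50, 6, seed = 23)
  d <- run_qs(H, blob_dynamics(p, k = 6), init = 1.0, seed = 91,
              qs = qs_config(t_r = 500, t_s = 500, c_max = 40))
  s <- qs_summary(d)
  expect_lt(abs(s$rho - chain$rho), 0.05)
  expect_lt(abs(s$chi - chain$chi), 0.2)
})

test_that("blob_dynamics maps chain rates onto simulator parameters", {
  p <- blob_params(N = 50, lam_k = 2, lam_star = 5, delta = 1.3,
                   theta_star = 0.2)
  dp <- blob_dynamics(p, k = 4)
  expect_equal(dp$lambda, 0.5)
  expect_equal(dp$delta, 1.3)
  # a pairwise edge carries rate lambda; the global hyperedge rate lam_star
  expect_equal(hyperedge_rate(2L, dp), 0.5)
  expect_equal(hyperedge_rate(50L, dp), 5)
  # threshold on the global hyperedge reproduces the integer critical mass
  expect_equal(hyperedge_threshold(50L, dp$theta_star), p$theta)
})
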