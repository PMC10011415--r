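write_cfg <- function(...) {
  path <- tempfile(fileext = ".cfg")
  writeLines(c(...), path)
  path
}

test_that("read_config parses the flat key-value dialect", {
  cfg <- read_config(write_cfg(
    "# a comment",
    "method = run-qs",
    "lambda = 0.5   # trailing comment",
    "m_in = 200, 100",
    "quiet = true",
    "generator=communities"
  ))
  expect_identical(cfg$method, "run-qs")
  expect_identical(cfg$lambda, 0.5)
  expect_identical(cfg$m_in, c(200, 100))
  expect_identical(cfg$quiet, TRUE)
  expect_identical(cfg$generator, "communities")
  expect_error(read_config(write_cfg("oops no equals")), "cannot parse")
})

test_that("parse_grid expands colon specs and passes vectors through", {
  pg <- hypercontagion:::parse_grid
  expect_equal(pg("0.1:0.3:0.1"), c(0.1, 0.2, 0.3))
  expect_equal(pg(c(1, 2, 5)), c(1, 2, 5))
  expect_error(pg("0.1:0.3"), "bad grid")
})

test_that("experiments are byte-identical for the same config and seed", {
  base <- list(method = "simulate", generator = "hyperblob", n = 40, k = 4,
               lambda = 0.8, theta_star = 0.2, t_max = 20, seed = 5)
  d1 <- file.path(tempdir(), "exp-a"); d2 <- file.path(tempdir(), "exp-b")
  run_experiment(c(base, list(out = d1)))
  run_experiment(c(base, list(out = d2)))
  for (f in c("events.tsv", "summary.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed produces a different event log
  d3 <- file.path(tempdir(), "exp-c")
  base$seed <- 6
  run_experiment(c(base, list(out = d3)))
  expect_false(identical(readLines(file.path(d1, "events.tsv")),
                         readLines(file.path(d3, "events.tsv"))))
})

test_that("stochastic methods demand a seed unless overridden", {
  cfg <- list(method = "simulate", generator = "hyperblob", n = 20, k = 4,
              lambda = 0.5, out = file.path(tempdir(), "exp-noseed"))
  expect_error(run_experiment(cfg), "without seed")
  expect_error(run_experiment(list(method = "frobnicate", out = tempdir())),
               "unknown method")
})

test_that("generate writes the hypergraph and community table", {
  out <- file.path(tempdir(), "exp-gen")
  files <- run_experiment(list(method = "generate", generator = "communities",
                               n = 60, nc = 2, m_in = c(10, 8), m_out = 4,
                               mu = 4, seed = 3, out = out))
  expect_true(file.exists(file.path(out, "hypergraph.tsv")))
  expect_true(file.exists(file.path(out, "communities.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # round trip keeps every hyperedge; isolated nodes are not encoded in
  # the edge-list format, so the node count may shrink
  H <- load_hypergraph(file.path(out, "hypergraph.tsv"), quiet = TRUE)
  expect_length(H$edges, 22L)
  expect_lte(H$n, 60L)
  comm <- utils::read.delim(file.path(out, "communities.tsv"))
  expect_equal(nrow(comm), 60L)
  expect_equal(sort(unique(comm$block)), 1:2)
})

test_that("blob-exact emits a normalized stationary distribution", {
  out <- file.path(tempdir(), "exp-blob")
  run_experiment(list(method = "blob-exact", n = 100, lam_k = 1, lam_star = 5,
                      theta_star = 0.2, out = out))
  pi <- utils::read.delim(file.path(out, "pi.tsv"))
  expect_equal(nrow(pi), 101L)
  expect_equal(sum(pi$pi), 1, tolerance = 1e-12)
  expect_equal(pi$pi[1], 0)            # QS chain: no mass at n = 0
  s <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_true(all(c("rho", "chi", "P_lower", "P_upper") %in% names(s)))
  expect_true(s$rho > 0 && s$rho <= 1)
})

test_that("run-ode writes a continuation trace", {
  out <- file.path(tempdir(), "exp-ode")
  run_experiment(list(method = "run-ode", generator = "hyperblob", n = 30,
                      k = 4, seed = 2, lambda_grid = "0.3:0.5:0.2",
                      theta_star = 0.2, seed_state = "one", out = out))
  tr <- utils::read.delim(file.path(out, "trace.tsv"))
  expect_equal(tr$lambda, c(0.3, 0.5))
  expect_true(all(tr$converged))
  expect_true(all(tr$rho >= 0 & tr$rho <= 1))
})

test_that("sweep produces a branch diagram table", {
  out <- file.path(tempdir(), "exp-sweep")
  run_experiment(list(method = "sweep", generator = "communities", n = 200,
                      nc = 2, m_in = c(200, 100), m_out = 120, mu = 8,
                      seed = 7, lambda_grid = c(0.05, 0.08),
                      rho0 = c(0.5, 1), theta_star = 0.5,
                      t_relax = 50, t_window = 50, c_max = 5, out = out))
  dg <- utils::read.delim(file.path(out, "diagram.tsv"))
  expect_equal(nrow(dg), 4L)
  expect_true(all(c("lambda", "branch", "init", "replica", "rho", "chi",
                    "n_peaks") %in% names(dg)))
  expect_true(all(dg$branch >= 1))
})

test_that("the command-line interface runs end to end", {
  cli <- system.file("cli", "hypercontagion.R", package = "hypercontagion")
  expect_true(nzchar(cli))
  out <- file.path(tempdir(), "exp-cli")
  cfg <- write_cfg("n = 200", "nc = 2", "m_in = 200, 100", "m_out = 40",
                   "mu = 8", "generator = communities",
                   "lambda_grid = 0.05:0.08:0.03", "theta_star = 0.5",
                   "t_relax = 50", "t_window = 50", "c_max = 5")
  res <- system2("Rscript", c(cli, "sweep", "--config", shQuote(cfg),
                              "--seed", "11", "--out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  dg <- utils::read.delim(file.path(out, "diagram.tsv"))
  expect_equal(nrow(dg), 4L)           # 2 lambdas x 2 default seedings
  expect_true(all(is.finite(dg$rho)))
})

test_that("CLI key=value overrides beat the config file", {
  cli <- system.file("cli", "hypercontagion.R", package = "hypercontagion")
  out <- file.path(tempdir(), "exp-cli-ovr")
  cfg <- write_cfg("n = 100", "lam_k = 1", "lam_star = 5",
                   "theta_star = 0.2")
  res <- system2("Rscript", c(cli, "blob-exact", "--config", shQuote(cfg),
                              "--out", shQuote(out), "n=50"),
                 stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  pi <- utils::read.delim(file.path(out, "pi.tsv"))
  expect_equal(nrow(pi), 51L)          # override n = 50 won
  # a broken config exits with a nonzero status and an error line
  res2 <- suppressWarnings(
    system2("Rscript", c(cli, "blob-exact", "--out", shQuote(out)),
            stdout = TRUE, stderr = TRUE))
  expect_identical(attr(res2, "status"), 1L)
  expect_true(any(grepl("^error:", res2)))
})
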