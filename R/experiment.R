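# Leveled logging: "quiet" < "progress" (per grid point) < "debug" (per QS
# window). Controlled by options(hypercontagion.log_level = ...).
hc_log <- function(level, fmt, ...) {
  rank <- c(quiet = 0L, progress = 1L, debug = 2L)
  lv <- getOption("hypercontagion.log_level", "quiet")
  if (!lv %in% names(rank)) lv <- "quiet"
  if (rank[[lv]] >= rank[[level]]) message(sprintf(fmt, ...))
}

#' Read a flat key-value experiment configuration
#'
#' Minimal TOML-style dialect: one `key = value` per line, `#` comments,
#' values parsed as numbers when possible, comma-separated values become
#' vectors, `true`/`false` become logicals. Keys mirror the command-line
#' flags of the bundled CLI script.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("config error: cannot parse line: ", ln)
    key <- kv[2L]; val <- trimws(kv[3L])
    parts <- trimws(strsplit(val, ",")[[1L]])
    parsed <- suppressWarnings(as.numeric(parts))
    if (!anyNA(parsed)) {
      out[[key]] <- parsed
    } else if (length(parts) == 1L && tolower(parts) %in% c("true", "false")) {
      out[[key]] <- tolower(parts) == "true"
    } else {
      out[[key]] <- if (length(parts) == 1L) parts else parts
    }
  }
  out
}

# "a:b:step" -> numeric grid; numeric vectors pass through
parse_grid <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- as.numeric(strsplit(x, ":")[[1L]])
  if (length(parts) != 3L || anyNA(parts)) stop("config error: bad grid spec: ", x)
  seq(parts[1L], parts[2L], by = parts[3L])
}

config_field <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) stop("config error: missing required key: ", key)
  default
}

resolve_structure <- function(config) {
  if (!is.null(config$graph)) {
    if (!file.exists(config$graph)) stop("missing input file: ", config$graph)
    return(load_hypergraph(config$graph, quiet = TRUE))
  }
  gen <- config_field(config, "generator", required = TRUE)
  seed <- config_field(config, "seed", required = TRUE)
  switch(gen,
    hyperblob = make_hyperblob(config_field(config, "n", required = TRUE),
                               config_field(config, "k", required = TRUE),
                               seed = seed),
    communities = make_community_hypergraph(
      N = config_field(config, "n", required = TRUE),
      n_c = config_field(config, "nc", required = TRUE),
      m_in = config_field(config, "m_in", required = TRUE),
      m_out = config_field(config, "m_out", 0),
      mu = config_field(config, "mu", 8),
      seed = seed),
    stop("config error: unknown generator: ", gen))
}

resolve_dynamics <- function(config) {
  mod_name <- config_field(config, "modulation", "log2")
  mod <- switch(mod_name,
                log2 = modulation_log2,
                const = modulation_constant(config_field(config, "const_value", 1)),
                stop("config error: unknown modulation: ", mod_name))
  dynamics_params(lambda = config_field(config, "lambda", required = TRUE),
                  delta = config_field(config, "delta", 1),
                  theta_star = config_field(config, "theta_star", 0.5),
                  modulation = mod)
}

resolve_qs <- function(config) {
  qs_config(M = config_field(config, "qs_m", 100L),
            p_r = config_field(config, "qs_pr", 0.02),
            t_r = config_field(config, "t_relax", 1e4),
            t_s = config_field(config, "t_window", 1e3),
            eps = config_field(config, "eps", 1e-3),
            c_max = config_field(config, "c_max", 500L))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run a configured experiment
#'
#' Deterministic mapping from a configuration (structure source, dynamics,
#' method, method options and seed) to a result bundle on disk: a
#' `manifest.json` echoing the resolved configuration and package version,
#' plus method-specific TSV/JSON outputs. Methods: `generate`, `simulate`,
#' `run-qs`, `sweep`, `run-ode`, `blob-exact`.
#'
#' @param config named list (see [read_config()]) with at least `method`,
#'   `out` and -- for stochastic methods -- `seed`.
#' @return invisible list of written file paths.
#' @export
run_experiment <- function(config) {
  method <- config_field(config, "method", required = TRUE)
  out_dir <- config_field(config, "out", required = TRUE)
  if (!method %in% c("generate", "simulate", "run-qs", "sweep", "run-ode",
                     "blob-exact")) {
    stop("config error: unknown method: ", method)
  }
  stochastic <- method %in% c("generate", "simulate", "run-qs", "sweep")
  if (stochastic && is.null(config$seed) && !isTRUE(config$no_seed)) {
    stop("config error: stochastic method without seed (set no_seed = true to override)")
  }
  seed <- config_field(config, "seed", 1L)
  log_level <- config_field(config, "log_level", "quiet")
  old_opt <- options(hypercontagion.log_level = log_level)
  on.exit(options(old_opt), add = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    fp <- file.path(out_dir, name)
    files <<- c(files, fp)
    fp
  }
  manifest <- list(package = "hypercontagion",
                   version = as.character(utils::packageVersion("hypercontagion")),
                   method = method,
                   config = config[order(names(config))])
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (method == "generate") {
    H <- resolve_structure(config)
    write_hypergraph(H, emit("hypergraph.tsv"))
    comm <- attr(H, "community")
    if (!is.null(comm)) {
      write_tsv(data.frame(node = seq_len(H$n), block = comm),
                emit("communities.tsv"))
    }
  } else if (method == "blob-exact") {
    p <- blob_params(N = config_field(config, "n", required = TRUE),
                     lam_k = config_field(config, "lam_k", required = TRUE),
                     lam_star = config_field(config, "lam_star", required = TRUE),
                     delta = config_field(config, "delta", 1),
                     theta_star = config_field(config, "theta_star", 0.5),
                     qs = TRUE)
    st <- blob_stationary(p)
    write_tsv(data.frame(n = 0:p$N, pi = as.numeric(st$pi)), emit("pi.tsv"))
    jsonlite::write_json(chain_summary(st), emit("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (method == "simulate") {
    H <- resolve_structure(config)
    params <- resolve_dynamics(config)
    traj <- simulate_contagion(H, params,
                               init = config_field(config, "init", 0.5),
                               t_max = config_field(config, "t_max", 100),
                               seed = seed,
                               snapshot_stride = config_field(config, "snapshot_stride", 0L))
    write_tsv(data.frame(time = traj$times, kind = traj$kind,
                         edge = traj$edge, n_active = traj$n_active),
              emit("events.tsv"))
    jsonlite::write_json(list(t_end = traj$t_end, status = traj$status,
                              final_active = sum(traj$final_state)),
                         emit("summary.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (method == "run-qs") {
    H <- resolve_structure(config)
    params <- resolve_dynamics(config)
    d <- run_qs(H, params, init = config_field(config, "init", 1),
                seed = seed, qs = resolve_qs(config))
    write_tsv(data.frame(n = 0:H$n, probability = as.numeric(d$prob)),
              emit("distribution.tsv"))
    s <- qs_summary(d)
    jsonlite::write_json(list(rho = s$rho, chi = s$chi,
                              peaks = find_peaks(d), windows = d$windows,
                              status = d$status),
                         emit("summary.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (method == "sweep") {
    H <- resolve_structure(config)
    grid <- parse_grid(config_field(config, "lambda_grid", required = TRUE))
    rho0 <- config_field(config, "rho0", c(0.5, 1))
    inits <- as.list(rho0)
    names(inits) <- paste0("rho0=", rho0)
    bd <- lambda_sweep(H, grid, inits,
                       replicas = config_field(config, "replicas", 1L),
                       seed = seed,
                       delta = config_field(config, "delta", 1),
                       theta_star = config_field(config, "theta_star", 0.5),
                       qs = resolve_qs(config))
    write_tsv(data.frame(lambda = bd$lambda, branch = bd$branch,
                         init = bd$init, replica = bd$replica,
                         rho = bd$rho, chi = bd$chi, n_peaks = bd$n_peaks),
              emit("diagram.tsv"))
  } else if (method == "run-ode") {
    H <- resolve_structure(config)
    grid <- parse_grid(config_field(config, "lambda_grid", required = TRUE))
    seed_spec <- config_field(config, "seed_state", "one")
    y0 <- if (identical(seed_spec, "zero")) rep(0, H$n)
          else if (identical(seed_spec, "one")) rep(1, H$n)
          else if (is.numeric(seed_spec) && length(seed_spec) == 1L) rep(seed_spec, H$n)
          else stop("config error: bad seed_state")
    tr <- branch_continuation(H, grid, list(seed = y0),
                              seed_lambda = config_field(config, "seed_lambda", grid[1L]),
                              delta = config_field(config, "delta", 1),
                              theta_star = config_field(config, "theta_star", 0.5),
                              residual_tol = config_field(config, "residual_tol", 1e-8))
    path <- tr[[1L]]$path
    write_tsv(data.frame(lambda = path$lambda, rho = path$rho,
                         converged = path$converged),
              emit("trace.tsv"))
  }
  invisible(files)
}
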