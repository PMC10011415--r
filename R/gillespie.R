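# Flatten a hypergraph plus dynamics parameters into the 0-based CSR form
# consumed by the C++ engine.
sim_inputs <- function(H, params) {
  validate_hypergraph(H)
  if (!length(H$edges)) stop("empty hypergraph: no hyperedges to simulate")
  stopifnot(inherits(params, "dynamics_params"))
  ed <- edge_dynamics(H, params)
  list(
    n = H$n,
    ememb = as.integer(unlist(H$edges) - 1L),
    eoff = as.integer(c(0L, cumsum(ed$card))),
    theta = as.integer(ed$theta),
    rate = as.numeric(ed$rate)
  )
}

# Resolve an initial-condition spec into a binary vector of length N.
#  - a single numeric in [0, 1]: fraction of active nodes, placed uniformly
#    at random (uses the current RNG stream);
#  - a logical or 0/1 numeric vector of length N: the explicit state;
#  - any other integer vector: the set of active node indices.
resolve_init <- function(init, N) {
  if (is.numeric(init) && length(init) == 1L && init >= 0 && init <= 1) {
    k <- round(init * N)
    y <- integer(N)
    if (k > 0L) y[sample.int(N, k)] <- 1L
    return(y)
  }
  if (is.logical(init)) init <- as.integer(init)
  if (length(init) == N && all(init %in% c(0L, 1L))) {
    return(as.integer(init))
  }
  init <- as.integer(init)
  if (any(init < 1L) || any(init > N)) stop("invalid initial condition")
  y <- integer(N)
  y[init] <- 1L
  y
}

#' Simulate the critical-mass contagion process
#'
#' Statistically exact continuous-time simulation of the Markov chain: each
#' active node deactivates at rate `delta`; each hyperedge whose active
#' count has reached its critical mass `Theta_j` carries a Poisson process
#' at rate `lambda_j` whose firing activates all its inactive members
#' simultaneously (the process is destroyed if deactivations bring the
#' count back below threshold); cardinality-2 hyperedges are simulated as
#' two directed node-to-node infection processes, recovering the SIS model
#' on graphs. The scheduler is the next-reaction method: an indexed
#' priority queue of exponentially distributed firing times, resampled
#' lazily only when a process is (re)created.
#'
#' @param H a `hypergraph`.
#' @param params a [dynamics_params()] object.
#' @param init initial condition: a fraction in (0, 1), an explicit binary
#'   vector of length `n`, or a vector of active node indices.
#' @param t_max simulation horizon.
#' @param seed integer RNG seed (mandatory: one PCG32 stream per run).
#' @param snapshot_stride record a full node-state snapshot every this many
#'   events (0 = none).
#' @param max_events hard cap on logged events.
#' @return an object of class `contagion_trajectory`: event log (`times`,
#'   `kind`, `edge`, flipped nodes), active counts, per-node cumulative
#'   active time, initial/final states and a termination `status`
#'   (`"absorbed"`, `"t_max"` or `"max_events"`).
#' @export
simulate_contagion <- function(H, params, init, t_max, seed,
                               snapshot_stride = 0L, max_events = 1e7) {
  if (t_max <= 0) stop("t_max must be positive")
  si <- sim_inputs(H, params)
  y0 <- local_seed(seed, resolve_init(init, H$n))
  res <- cpp_simulate(si$n, si$ememb, si$eoff, si$theta, si$rate,
                      params$delta, y0, t_max, as.numeric(seed),
                      as.integer(snapshot_stride), max_events)
  snaps <- NULL
  if (snapshot_stride > 0L && length(res$snapshots)) {
    snaps <- matrix(res$snapshots, ncol = H$n, byrow = TRUE)
  }
  structure(list(
    times = res$times,
    kind = c("deactivation", "pairwise", "hyperedge")[res$kind + 1L],
    edge = res$edge,
    flip_node = res$flip_node,
    flip_off = res$flip_off,
    n_active = res$n_active,
    init_state = y0,
    final_state = res$final_state,
    active_time = res$active_time,
    snapshot_times = res$snapshot_times,
    snapshots = snaps,
    t_end = res$t_end,
    n = H$n,
    status = res$status
  ), class = "contagion_trajectory")
}

#' @export
print.contagion_trajectory <- function(x, ...) {
  cat(sprintf("Contagion trajectory: %d events over t in [0, %g], %d/%d active at end (%s)\n",
              length(x$times), x$t_end, sum(x$final_state), x$n, x$status))
  invisible(x)
}

#' Per-node activity fraction over a time window
#'
#' Computes, exactly from the event log, the fraction of the window each
#' node spent active (time-weighted).
#'
#' @param traj a `contagion_trajectory`.
#' @param window numeric length-2 interval within `[0, t_end]`.
#' @return numeric vector of length `n` with values in \[0, 1\].
#' @export
node_activity <- function(traj, window = c(0, traj$t_end)) {
  stopifnot(inherits(traj, "contagion_trajectory"))
  a <- window[1L]; b <- window[2L]
  if (!(b > a)) stop("empty window")
  if (a < 0 || b > traj$t_end + 1e-12) stop("window outside trajectory span")
  state <- as.integer(traj$init_state)
  last <- rep(0, traj$n)
  acc <- rep(0, traj$n)
  overlap <- function(t0, t1) max(0, min(t1, b) - max(t0, a))
  nev <- length(traj$times)
  for (ev in seq_len(nev)) {
    t1 <- traj$times[ev]
    idx <- if (traj$flip_off[ev] < traj$flip_off[ev + 1L]) {
      traj$flip_node[(traj$flip_off[ev] + 1L):traj$flip_off[ev + 1L]]
    } else integer(0)
    for (i in idx) {
      if (state[i] == 1L) acc[i] <- acc[i] + overlap(last[i], t1)
      state[i] <- 1L - state[i]
      last[i] <- t1
    }
  }
  on_idx <- which(state == 1L)
  for (i in on_idx) acc[i] <- acc[i] + overlap(last[i], traj$t_end)
  acc / (b - a)
}
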