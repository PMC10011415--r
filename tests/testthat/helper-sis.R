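# Independent quasi-stationary SIS reference implementation, used to check
# that the contagion dynamics restricted to cardinality-2 hyperedges
# reduces to the standard SIS model on a graph. Deliberately shares
# nothing with the package engine: plain R, R's own RNG, direct (rate-sum)
# Gillespie scheduling instead of the next-reaction queue.
#
# adj: list of integer neighbour vectors (1-based). Returns the
# time-weighted mean infected fraction over the sampling period.
qs_sis_reference <- function(adj, lambda, delta, init_frac, t_relax,
                             t_sample, M = 50L, p_r = 0.02, seed = 1L) {
  set.seed(seed)
  N <- length(adj)
  state <- integer(N)
  state[sample.int(N, max(1L, round(init_frac * N)))] <- 1L
  # ni[i]: number of infected neighbours of i (kept incrementally)
  ni <- vapply(seq_len(N), function(i) sum(state[adj[[i]]]), 1L)
  store <- replicate(M, which(state == 1L), simplify = FALSE)
  t <- 0
  t_end <- t_relax + t_sample
  wsum <- 0   # time-weighted sum of infected counts over the sample period
  wtot <- 0
  set_state <- function(infected) {
    state <<- integer(N)
    state[infected] <<- 1L
    ni <<- vapply(seq_len(N), function(i) sum(state[adj[[i]]]), 1L)
  }
  repeat {
    n_inf <- sum(state)
    sus <- which(state == 0L)
    w_inf <- ni[sus]                       # infection pressure per S node
    rate_rec <- delta * n_inf
    rate_inf <- lambda * sum(w_inf)
    R <- rate_rec + rate_inf
    dt <- stats::rexp(1L, R)
    t_next <- min(t + dt, t_end)
    if (t_next > t_relax) {
      span <- t_next - max(t, t_relax)
      wsum <- wsum + n_inf * span
      wtot <- wtot + span
    }
    t <- t + dt
    if (t >= t_end) break
    # stored-state updates happen as a Poisson process of rate p_r
    if (stats::runif(1L) < p_r * dt) {
      store[[sample.int(M, 1L)]] <- which(state == 1L)
    }
    if (stats::runif(1L) < rate_rec / R) {
      i <- sample(which(state == 1L), 1L)
      state[i] <- 0L
      ni[adj[[i]]] <- ni[adj[[i]]] - 1L
      if (n_inf == 1L) {
        # absorbing state hit: restart from a stored configuration
        set_state(store[[sample.int(M, 1L)]])
      }
    } else {
      i <- sus[sample.int(length(sus), 1L, prob = w_inf)]
      state[i] <- 1L
      ni[adj[[i]]] <- ni[adj[[i]]] + 1L
    }
  }
  wsum / wtot / N
}

# Random regular graph as a neighbour list, built independently of the
# package generator (igraph's degree-sequence sampler).
rrg_adjacency <- function(N, k, seed) {
  set.seed(seed)
  g <- igraph::sample_degseq(rep(k, N), method = "configuration")
  g <- igraph::simplify(g)
  while (any(igraph::degree(g) != k)) {
    g <- igraph::simplify(igraph::sample_degseq(rep(k, N),
                                                method = "configuration"))
  }
  lapply(igraph::as_adj_list(g), as.integer)
}
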