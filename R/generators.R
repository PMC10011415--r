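# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Generate a hyperblob
#'
#' A hyperblob is a simple random k-regular graph on `N` nodes (every node
#' has exactly `k` pairwise neighbours) plus one hyperedge of cardinality
#' `N` containing every node. Its node-permutation symmetry collapses the
#' contagion dynamics onto a one-dimensional occupancy chain, which is what
#' makes an exact analysis possible (see [blob_stationary()]).
#'
#' The regular graph is built with the pairing (configuration) model with
#' full restart whenever a self-loop or multi-edge appears, so the result
#' is uniform over simple k-regular graphs.
#'
#' @param N number of nodes.
#' @param k pairwise degree; `k*N` must be even and `k < N`.
#' @param seed integer RNG seed.
#' @param max_restarts cap on pairing-model restarts.
#' @return a `hypergraph` with `N*k/2 + 1` hyperedges.
#' @export
make_hyperblob <- function(N, k, seed, max_restarts = 100000L) {
  N <- as.integer(N); k <- as.integer(k)
  if (k >= N) stop("degree k must be smaller than N")
  if ((k * N) %% 2L != 0L) stop("k * N must be even")
  if (k == N - 1L) {
    # the complete graph is the unique (N-1)-regular simple graph; the
    # pairing model would essentially never hit it by rejection
    pr <- utils::combn(N, 2L)
    edges <- lapply(seq_len(ncol(pr)), function(j) pr[, j])
    edges[[length(edges) + 1L]] <- seq_len(N)
    return(hypergraph(edges, n = N, labels = seq_len(N), quiet = TRUE))
  }
  local_seed(seed, {
    edges <- NULL
    for (attempt in seq_len(max_restarts)) {
      stubs <- sample(rep.int(seq_len(N), k))
      a <- stubs[seq(1L, length(stubs), by = 2L)]
      b <- stubs[seq(2L, length(stubs), by = 2L)]
      if (any(a == b)) next
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- (lo - 1) * N + hi
      if (anyDuplicated(key)) next
      o <- order(key)
      edges <- mapply(function(x, y) c(x, y), lo[o], hi[o], SIMPLIFY = FALSE)
      break
    }
    if (is.null(edges)) stop("pairing model failed to produce a simple graph")
    edges[[length(edges) + 1L]] <- seq_len(N)
    hypergraph(edges, n = N, labels = seq_len(N), quiet = TRUE)
  })
}

# Draw one hyperedge cardinality: exponential with mean mu, discretised by
# ceiling and clamped into [2, cmax].
draw_cardinality <- function(mu, cmax) {
  x <- as.integer(ceiling(stats::rexp(1L, rate = 1 / mu)))
  min(max(x, 2L), as.integer(cmax))
}

#' Generate a community-structured hypergraph
#'
#' Nodes are split into `n_c` equal-sized blocks. Each community `c`
#' receives `m_in[c]` hyperedges drawn entirely inside its block, and
#' `m_out` bridge hyperedges each span exactly two (uniformly chosen)
#' distinct communities: for a bridge of cardinality `|e|`, a uniform
#' `ell` in `1..(|e|-1)` members come from one community and the rest from
#' the other. Cardinalities are drawn from an exponential distribution with
#' mean `mu`, discretised by ceiling and clamped into `[2, N/n_c]`.
#' Duplicate hyperedges are resampled.
#'
#' @param N number of nodes; must be divisible by `n_c`.
#' @param n_c number of communities.
#' @param m_in integer vector of length `n_c`: in-community hyperedge counts.
#' @param m_out bridge hyperedge count.
#' @param mu mean of the cardinality distribution.
#' @param seed integer RNG seed.
#' @return a `hypergraph` with attribute `community` giving each node's
#'   block (integer vector of length `N`).
#' @export
make_community_hypergraph <- function(N, n_c, m_in, m_out, mu = 8, seed) {
  N <- as.integer(N); n_c <- as.integer(n_c)
  if (N %% n_c != 0L) stop("N must be divisible by n_c")
  if (length(m_in) != n_c) stop("m_in must have one entry per community")
  if (any(m_in < 0) || m_out < 0) stop("hyperedge counts must be >= 0")
  bs <- N %/% n_c
  if (bs < 2L) stop("blocks too small: cardinality window [2, N/n_c] is empty")
  blocks <- split(seq_len(N), rep(seq_len(n_c), each = bs))
  local_seed(seed, {
    edges <- vector("list", sum(m_in) + m_out)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    pos <- 0L
    add_edge <- function(draw) {
      # resample until the drawn hyperedge is new
      repeat {
        e <- sort(draw())
        key <- paste(e, collapse = " ")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          pos <<- pos + 1L
          edges[[pos]] <<- e
          return(invisible(NULL))
        }
      }
    }
    for (c in seq_len(n_c)) {
      for (i in seq_len(m_in[c])) {
        add_edge(function() sample(blocks[[c]], draw_cardinality(mu, bs)))
      }
    }
    for (i in seq_len(m_out)) {
      add_edge(function() {
        ab <- sample(n_c, 2L)
        card <- draw_cardinality(mu, bs)
        ell <- sample.int(card - 1L, 1L)
        c(sample(blocks[[ab[1L]]], ell), sample(blocks[[ab[2L]]], card - ell))
      })
    }
    H <- hypergraph(edges, n = N, labels = seq_len(N), quiet = TRUE)
    attr(H, "community") <- rep(seq_len(n_c), each = bs)
    H
  })
}

#' Configuration-model rewiring of a hypergraph
#'
#' Performs `n_swaps` pairwise-shuffle steps of the vertex-labeled
#' hypergraph configuration model: at each step two hyperedges are chosen
#' uniformly, their members pooled (with multiplicity) and randomly
#' repartitioned into two hyperedges of the original cardinalities. A
#' proposal is rejected -- leaving both hyperedges unchanged but still
#' counting the step -- if a part would repeat a node or duplicate an
#' existing hyperedge. The node membership-count sequence and the
#' cardinality multiset are invariant.
#'
#' @param H a `hypergraph`.
#' @param n_swaps number of attempted shuffle steps.
#' @param seed integer RNG seed.
#' @return the rewired `hypergraph` with attribute `accepted` counting
#'   accepted swaps.
#' @export
rewire_configuration_model <- function(H, n_swaps, seed) {
  validate_hypergraph(H)
  if (n_swaps < 0) stop("n_swaps must be >= 0")
  m <- length(H$edges)
  if (m < 2L) {
    warning("fewer than 2 hyperedges: rewiring is a no-op")
    return(H)
  }
  edges <- H$edges
  local_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    keyof <- function(e) paste(e, collapse = " ")
    for (e in edges) seen[[keyof(e)]] <- TRUE
    accepted <- 0L
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(m, 2L)
      e1 <- edges[[ij[1L]]]; e2 <- edges[[ij[2L]]]
      pool <- sample(c(e1, e2))
      f1 <- sort(pool[seq_len(length(e1))])
      f2 <- sort(pool[-seq_len(length(e1))])
      if (anyDuplicated(f1) || anyDuplicated(f2)) next
      k1 <- keyof(f1); k2 <- keyof(f2)
      if (k1 == k2) next
      ko1 <- keyof(e1); ko2 <- keyof(e2)
      # duplicate check against all hyperedges except the two being replaced
      clash <- function(k) !is.null(seen[[k]]) && k != ko1 && k != ko2
      if (clash(k1) || clash(k2)) next
      rm(list = c(ko1, ko2), envir = seen)
      seen[[k1]] <- TRUE; seen[[k2]] <- TRUE
      edges[[ij[1L]]] <- f1; edges[[ij[2L]]] <- f2
      accepted <- accepted + 1L
    }
    out <- structure(list(n = H$n, edges = edges, labels = H$labels),
                     class = "hypergraph")
    attr(out, "community") <- attr(H, "community")
    attr(out, "accepted") <- accepted
    out
  })
}
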