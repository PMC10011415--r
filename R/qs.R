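#' Quasi-stationary sampling configuration
#'
#' The quasi-stationary (QS) method conditions an absorbing-state process
#' on survival: the simulation keeps a list of `M` previously visited
#' active states, overwriting a uniformly random slot with the current
#' state at rate `p_r` per unit time, and whenever the absorbing state is
#' hit the state is replaced by a uniform draw from the list. After a
#' relaxation time `t_r`, the time-weighted occupancy of each active count
#' `n` is accumulated in windows of length `t_s`; sampling stops when the
#' susceptibility changes by less than `eps` between consecutive windows,
#' or after `c_max` windows.
#'
#' Defaults: `M = 100`, `p_r = 0.02` (standard QS practice; the estimates
#' are insensitive to both over a decade of values), `t_r = 1e4`,
#' `t_s = 1e3` (scale these down for small systems), `eps = 1e-3`,
#' `c_max = 500`.
#'
#' @param M stored-state list size (>= 1).
#' @param p_r state-recording rate per unit time.
#' @param t_r relaxation time before sampling starts.
#' @param t_s adaptive sampling sub-window length.
#' @param eps tolerance on the between-window susceptibility change.
#' @param c_max maximum number of sampling windows.
#' @return an object of class `qs_config`.
#' @export
qs_config <- function(M = 100L, p_r = 0.02, t_r = 1e4, t_s = 1e3,
                      eps = 1e-3, c_max = 500L) {
  stopifnot(M >= 1L, p_r >= 0, t_r >= 0, t_s > 0, eps > 0, c_max >= 1L)
  structure(list(M = as.integer(M), p_r = p_r, t_r = t_r, t_s = t_s,
                 eps = eps, c_max = as.integer(c_max)),
            class = "qs_config")
}

#' Quasi-stationary Monte-Carlo run
#'
#' Runs the contagion process under the stored-states QS method and
#' returns the time-weighted distribution of the number of active nodes
#' together with per-node activity estimates. The distribution assigns
#' zero mass to `n = 0` by construction.
#'
#' @param H a `hypergraph`.
#' @param params a [dynamics_params()] object.
#' @param init initial condition (see [simulate_contagion()]); must have at
#'   least one active node.
#' @param seed integer RNG seed.
#' @param qs a [qs_config()].
#' @return an object of class `qs_dist` with fields `prob` (probability
#'   over `n = 0..N`, named), `freq` (raw time weights), `sample_time`,
#'   `windows`, `chi_trace`, `node_activity` (per-node active fraction of
#'   the sampling period), `final_state` and `status` (`"converged"` or
#'   `"c_max"`).
#' @export
run_qs <- function(H, params, init, seed, qs = qs_config()) {
  stopifnot(inherits(qs, "qs_config"))
  si <- sim_inputs(H, params)
  y0 <- local_seed(seed, resolve_init(init, H$n))
  if (sum(y0) == 0L) stop("QS initial condition must have at least one active node")
  res <- cpp_qs_run(si$n, si$ememb, si$eoff, si$theta, si$rate,
                    params$delta, y0, qs$M, qs$p_r, qs$t_r, qs$t_s,
                    qs$eps, qs$c_max, as.numeric(seed))
  freq <- res$freq
  names(freq) <- 0:H$n
  prob <- freq / sum(freq)
  for (w in seq_along(res$chi_trace)) {
    hc_log("debug", "QS window %d/%d: chi = %.5f", w, res$windows,
           res$chi_trace[w])
  }
  structure(list(
    freq = freq, prob = prob,
    sample_time = res$sample_time, windows = res$windows,
    chi_trace = res$chi_trace,
    node_activity = res$node_active_time / res$sample_time,
    final_state = res$final_state,
    n = H$n, status = res$status
  ), class = "qs_dist")
}

#' @export
print.qs_dist <- function(x, ...) {
  s <- qs_summary(x)
  cat(sprintf("QS state distribution over N = %d nodes: rho = %.4f, chi = %.3f (%d windows, %s)\n",
              x$n, s$rho, s$chi, x$windows, x$status))
  invisible(x)
}

#' Order parameter and susceptibility of a state distribution
#'
#' `rho = <n>/N` is the expected active fraction and
#' `chi = (<n^2> - <n>^2)/<n>` the variance-to-mean ratio of the active
#' count, both under the time-weighted distribution. Peaks or divergences
#' of `chi` mark phase transitions.
#'
#' @param dist a `qs_dist`, or a bare probability vector over `n = 0..N`.
#' @param N node count (only needed for a bare vector).
#' @return list with elements `rho` and `chi`.
#' @export
qs_summary <- function(dist, N = NULL) {
  if (inherits(dist, "qs_dist")) {
    p <- dist$prob; N <- dist$n
  } else {
    p <- dist / sum(dist)
    if (is.null(N)) N <- length(p) - 1L
  }
  if (!length(p) || any(!is.finite(p))) stop("empty or invalid distribution")
  n <- seq_along(p) - 1
  m1 <- sum(n * p)
  if (m1 <= 0) stop("distribution has zero mean occupancy")
  m2 <- sum(n^2 * p)
  list(rho = m1 / N, chi = (m2 - m1^2) / m1)
}

#' @export
summary.qs_dist <- function(object, ...) qs_summary(object)

#' Peaks of a state distribution
#'
#' Smooths the occupancy profile over active counts `n = 1..N` with a
#' moving average and returns the local maxima whose prominence (height
#' above the higher of the two flanking saddles) exceeds a fraction of the
#' maximum occupancy, as positions `n/N` in increasing order.
#'
#' @param dist a `qs_dist` or a probability vector over `n = 0..N`.
#' @param w moving-average window (consecutive `n` bins).
#' @param prominence minimal prominence as a fraction of the profile
#'   maximum.
#' @param N node count (only for a bare vector).
#' @return numeric vector of peak positions `n/N` (possibly empty).
#' @export
find_peaks <- function(dist, w = 5L, prominence = 0.02, N = NULL) {
  if (inherits(dist, "qs_dist")) {
    p <- dist$prob; N <- dist$n
  } else {
    p <- dist / sum(dist)
    if (is.null(N)) N <- length(p) - 1L
  }
  prof <- p[-1L]                       # n = 1..N; QS puts no mass at 0
  if (w > 1L) {
    kern <- rep(1 / w, w)
    sm <- stats::filter(prof, kern, sides = 2L)
    # shrink the window at the boundaries instead of dropping them
    na <- which(is.na(sm))
    for (i in na) {
      lo <- max(1L, i - (w %/% 2L)); hi <- min(length(prof), i + (w %/% 2L))
      sm[i] <- mean(prof[lo:hi])
    }
    prof <- as.numeric(sm)
  }
  L <- length(prof)
  if (L < 3L || max(prof) <= 0) return(numeric(0))
  thr <- prominence * max(prof)
  peaks <- numeric(0)
  for (i in seq_len(L)) {
    left <- if (i > 1L) prof[i - 1L] else -Inf
    right <- if (i < L) prof[i + 1L] else -Inf
    if (!(prof[i] > left && prof[i] >= right)) next
    # prominence: walk out on each side until a higher point; track minima
    saddle <- function(dir) {
      jmin <- prof[i]
      j <- i + dir
      while (j >= 1L && j <= L && prof[j] <= prof[i]) {
        jmin <- min(jmin, prof[j]); j <- j + dir
      }
      jmin
    }
    prom <- prof[i] - max(saddle(-1L), saddle(1L))
    # the global maximum has no higher point on either side: measure from
    # the lower of the two side minima instead
    if (prof[i] == max(prof)) prom <- prof[i] - min(saddle(-1L), saddle(1L))
    if (prom >= thr) peaks <- c(peaks, i / N)
  }
  peaks
}

#' Sweep the spreading rate and label branches
#'
#' Runs [run_qs()] on a grid of spreading rates `lambda` for each supplied
#' initial-condition spec and replica, then labels branches per `lambda` by
#' single-linkage clustering of the order parameter: runs are split where
#' consecutive sorted `rho` values gap by more than `5/N`, and clusters
#' whose means are closer than 3 pooled standard errors are re-merged.
#' Branch labels are ordinal in mean `rho` (1 = lowest); they are per-`lambda`
#' and not matched across the grid.
#'
#' @param H a `hypergraph`.
#' @param lambdas numeric grid of spreading rates (sorted internally).
#' @param inits named list of initial-condition specs (fractions, binary
#'   vectors or node sets, see [simulate_contagion()]).
#' @param replicas QS runs per (lambda, init).
#' @param seed integer base seed; each run derives its own stream.
#' @param delta,theta_star,modulation dynamics template passed to
#'   [dynamics_params()].
#' @param qs a [qs_config()].
#' @param peak_w,peak_prominence passed to [find_peaks()].
#' @return an object of class `branch_diagram`: a data frame with columns
#'   `lambda`, `init`, `replica`, `rho`, `chi`, `n_peaks`, `branch`, plus a
#'   `peaks` list-column.
#' @export
lambda_sweep <- function(H, lambdas, inits, replicas = 1L, seed,
                         delta = 1, theta_star = 0.5,
                         modulation = modulation_log2, qs = qs_config(),
                         peak_w = 5L, peak_prominence = 0.02) {
  stopifnot(length(lambdas) >= 1L)
  lambdas <- sort(lambdas)
  if (is.null(names(inits))) names(inits) <- paste0("init", seq_along(inits))
  rows <- list()
  counter <- 0L
  for (lam in lambdas) {
    params <- dynamics_params(lambda = lam, delta = delta,
                              theta_star = theta_star,
                              modulation = modulation)
    for (nm in names(inits)) {
      for (r in seq_len(replicas)) {
        counter <- counter + 1L
        run_seed <- (as.integer(seed) + 7919L * counter) %% 2147483629L
        d <- run_qs(H, params, inits[[nm]], seed = run_seed, qs = qs)
        s <- qs_summary(d)
        pk <- find_peaks(d, w = peak_w, prominence = peak_prominence)
        hc_log("progress",
               "sweep lambda = %g init = %s replica = %d: rho = %.4f chi = %.3f (%d windows)",
               lam, nm, r, s$rho, s$chi, d$windows)
        rows[[counter]] <- data.frame(
          lambda = lam, init = nm, replica = r,
          rho = s$rho, chi = s$chi, n_peaks = length(pk),
          stringsAsFactors = FALSE)
        rows[[counter]]$peaks <- list(pk)
      }
    }
  }
  df <- do.call(rbind, rows)
  df$branch <- NA_integer_
  for (lam in lambdas) {
    sel <- which(df$lambda == lam)
    df$branch[sel] <- cluster_branches(df$rho[sel], H$n)
  }
  structure(df, class = c("branch_diagram", class(df)))
}

# Single-linkage clustering of rho values: split at gaps > 5/N, then merge
# clusters whose means differ by < 3 pooled standard errors.
cluster_branches <- function(rho, N) {
  k <- length(rho)
  if (k == 1L) return(1L)
  o <- order(rho)
  gaps <- diff(rho[o])
  cl_sorted <- cumsum(c(1, as.integer(gaps > 5 / N)))
  cl <- integer(k)
  cl[o] <- cl_sorted
  # merge statistically indistinguishable clusters
  repeat {
    ids <- sort(unique(cl))
    if (length(ids) == 1L) break
    means <- vapply(ids, function(g) mean(rho[cl == g]), 0)
    vars <- vapply(ids, function(g) {
      x <- rho[cl == g]
      if (length(x) > 1L) stats::var(x) / length(x) else 0
    }, 0)
    merged <- FALSE
    for (q in seq_len(length(ids) - 1L)) {
      se <- sqrt(vars[q] + vars[q + 1L])
      if (se > 0 && abs(means[q + 1L] - means[q]) < 3 * se) {
        cl[cl == ids[q + 1L]] <- ids[q]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  match(cl, sort(unique(cl)))
}
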