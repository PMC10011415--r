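#' Parameters of the hyperblob occupancy chain
#'
#' In a hyperblob (random k-regular graph plus one hyperedge containing
#' every node) all nodes are statistically equivalent, so the contagion
#' collapses onto a birth-death chain over the number of active nodes `n`
#' with one extra "jump" transition: pairwise spreading drives
#' `beta_n = lam_k * n * (N - n) / N` (with `lam_k` the lumped product of
#' the free spreading rate and the degree, `lambda <k>`), deactivation
#' drives `delta_n = delta * n`, and once `n >= theta` the global hyperedge
#' fires at bare rate `lam_star`, sending the chain straight to `n = N`.
#' With `qs = TRUE` the transition from `n = 1` to the absorbing state is
#' removed, conditioning the chain on survival.
#'
#' @param N node count.
#' @param lam_k lumped pairwise drive `lambda * <k>` (>= 0).
#' @param lam_star bare rate of the global hyperedge (>= 0).
#' @param delta deactivation rate (> 0).
#' @param theta integer critical mass on the global hyperedge; defaults to
#'   `ceiling(theta_star * N)`.
#' @param theta_star critical-mass fraction used when `theta` is missing.
#' @param qs apply the quasi-stationary constraint.
#' @return an object of class `blob_params`.
#' @export
blob_params <- function(N, lam_k, lam_star, delta = 1, theta = NULL,
                        theta_star = NULL, qs = TRUE) {
  if (is.null(theta)) {
    if (is.null(theta_star)) stop("give theta or theta_star")
    theta <- as.integer(ceiling(theta_star * N))
  }
  theta <- as.integer(theta)
  if (theta < 1L || theta > N) stop("theta must lie in [1, N]")
  if (lam_k < 0 || lam_star < 0 || delta <= 0) stop("invalid rates")
  structure(list(N = as.integer(N), lam_k = lam_k, lam_star = lam_star,
                 delta = delta, theta = theta, qs = isTRUE(qs)),
            class = "blob_params")
}

# birth and death rates of the occupancy chain, n = 0..N
blob_rates <- function(p) {
  n <- 0:p$N
  list(beta = p$lam_k * n * (p$N - n) / p$N,   # n -> n+1 (0 at n = N)
       death = p$delta * n)                    # n -> n-1
}

#' Simulator dynamics matching a hyperblob chain
#'
#' Maps the lumped chain parameters onto [dynamics_params()] for a
#' hyperblob generated with [make_hyperblob()] at degree `k`: the free
#' spreading rate is `lam_k / k` (so each of the `k` incident pairwise
#' processes carries rate `lam_k / k` and the node-level pairwise drive is
#' `lam_k` per active-inactive contact fraction), and the modulation maps
#' cardinality 2 to 1 and any larger cardinality (the single global
#' hyperedge) to `lam_star / lambda`, giving the hyperedge the bare rate
#' `lam_star`. The critical-mass fraction is `theta / N`, whose ceiling on
#' the global hyperedge recovers the integer threshold `theta` exactly
#' (the threshold is irrelevant for pairwise interactions).
#'
#' Note that the chain's pairwise drive `lam_k * n * (N - n) / N` is an
#' annealed description of the k-regular layer, so this mapping is
#' approximate for sparse degrees; the chain is exact for the complete
#' pairwise layer (`k = N - 1`) simulated with free rate `lam_k / N`.
#'
#' @param p a [blob_params()] object.
#' @param k pairwise degree of the simulated hyperblob.
#' @return a [dynamics_params()] object.
#' @export
blob_dynamics <- function(p, k) {
  stopifnot(inherits(p, "blob_params"))
  if (p$lam_k <= 0) stop("blob_dynamics requires lam_k > 0")
  lambda <- p$lam_k / k
  ratio <- p$lam_star / lambda
  dynamics_params(
    lambda = lambda, delta = p$delta, theta_star = p$theta / p$N,
    modulation = function(cardinality) ifelse(cardinality == 2L, 1, ratio))
}

#' Generator matrix of the hyperblob chain
#'
#' Builds the (N+1) x (N+1) rate matrix over occupancy states `0..N`:
#' `Q[n, n-1] = delta * n`, `Q[n, n+1] = lam_k * n * (N-n)/N`, and the jump
#' `Q[n, N] = lam_star` for `theta <= n <= N-1` (added on top of the birth
#' rate at `n = N-1`; parallel transitions sum in a generator). Under the
#' QS constraint the entry from state 1 to state 0 is zeroed before the
#' diagonal (negative row sum) is formed.
#'
#' @param p a [blob_params()] object.
#' @return a sparse `Matrix` generator with zero row sums.
#' @export
blob_generator <- function(p) {
  N <- p$N
  r <- blob_rates(p)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  # deaths (1-based matrix indices: state n is row n+1)
  from <- 1:N
  death <- r$death[from + 1L]
  if (p$qs) death[1L] <- 0          # Q[1, 0] = 0
  keep <- death > 0
  i <- c(i, from[keep] + 1L); j <- c(j, from[keep]); x <- c(x, death[keep])
  # births
  from <- 0:(N - 1L)
  birth <- r$beta[from + 1L]
  keep <- birth > 0
  i <- c(i, from[keep] + 1L); j <- c(j, from[keep] + 2L); x <- c(x, birth[keep])
  # jump to N
  if (p$lam_star > 0 && p$theta <= N - 1L) {
    from <- p$theta:(N - 1L)
    i <- c(i, from + 1L); j <- c(j, rep(N + 1L, length(from)))
    x <- c(x, rep(p$lam_star, length(from)))
  }
  Q <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(N + 1L, N + 1L))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  Q
}

#' Transient evolution of the occupancy distribution
#'
#' Solves `dP/dt = Q^T P` from `P0`, either with the matrix exponential
#' (dense, for chains up to a few hundred states) or by stiff ODE
#' integration for larger chains. Each returned distribution is
#' renormalized; a normalization drift above 1e-8 raises a warning.
#'
#' @param p a [blob_params()] object (or a generator from
#'   [blob_generator()]).
#' @param P0 initial distribution over `0..N` (must sum to 1).
#' @param times nonnegative times at which to report `P(t)`.
#' @return matrix with one row per time, columns `0..N`.
#' @export
blob_evolve <- function(p, P0, times) {
  Q <- if (inherits(p, "blob_params")) blob_generator(p) else p
  np <- nrow(Q)
  if (length(P0) != np) stop("P0 dimension mismatch")
  if (abs(sum(P0) - 1) > 1e-8) stop("P0 must be normalized")
  if (any(P0 < 0)) stop("P0 must be nonnegative")
  Qt <- Matrix::t(Q)
  out <- matrix(NA_real_, nrow = length(times), ncol = np,
                dimnames = list(NULL, 0:(np - 1L)))
  if (np <= 600L) {
    for (q in seq_along(times)) {
      Pt <- as.numeric(Matrix::expm(Qt * times[q]) %*% P0)
      out[q, ] <- Pt
    }
  } else {
    rhs <- function(t, P, parms) list(as.numeric(Qt %*% P))
    sol <- deSolve::lsoda(y = as.numeric(P0), times = sort(unique(c(0, times))),
                          func = rhs, parms = NULL, atol = 1e-12, rtol = 1e-10)
    for (q in seq_along(times)) {
      out[q, ] <- sol[match(times[q], sol[, 1L]), -1L]
    }
  }
  drift <- abs(rowSums(out) - 1)
  if (any(drift > 1e-8)) {
    warning(sprintf("normalization drift up to %.3g during evolution", max(drift)))
  }
  out / rowSums(out)
}

#' Stationary distribution of the QS hyperblob chain
#'
#' Computes the quasi-stationary distribution `pi` over `n = 1..N`
#' (`pi_0 = 0`) by an O(N) forward recursion. The balance equations are
#' accumulated across the cut between `n` and `n+1`, giving
#' `delta*(n+1)*pi_{n+1} = beta_n*pi_n + lam_star * sum_{i=theta}^{n} pi_i`:
#' an algebraically equivalent rearrangement of the state-by-state balance
#' recursion in which every term is positive, so the recursion is free of
#' cancellation. Periodic renormalization guards against overflow. The
#' result is checked against the full stationarity equations
#' (`max |Q^T pi|` after normalization).
#'
#' @param p a [blob_params()] with `qs = TRUE`.
#' @param residual_tol acceptable stationarity residual.
#' @return an object of class `blob_stationary`: `pi` (named vector over
#'   `0..N`), `params`, `residual`.
#' @export
blob_stationary <- function(p, residual_tol = 1e-6) {
  stopifnot(inherits(p, "blob_params"))
  if (!p$qs) stop("the stationary recursion requires the QS constraint")
  N <- p$N
  r <- blob_rates(p)
  pi <- numeric(N + 1L)            # index n + 1
  pi[2L] <- 1                      # seed pi_1 = 1
  S <- if (p$theta <= 1L) pi[2L] else 0   # running sum_{i=theta}^{n} pi_i
  for (n in 1:(N - 1L)) {
    flux <- r$beta[n + 1L] * pi[n + 1L] + p$lam_star * S
    pi[n + 2L] <- flux / (p$delta * (n + 1L))
    if (n + 1L >= p$theta) S <- S + pi[n + 2L]
    if (pi[n + 2L] > 1e100) {      # rescale to dodge overflow
      pi <- pi / 1e100
      S <- S / 1e100
    }
  }
  pi <- pi / sum(pi)
  res <- blob_residual(p, pi)
  if (res > residual_tol) {
    stop(sprintf(paste("stationary recursion residual %.3g exceeds %.3g;",
                       "consider blob_nullspace() as a fallback"),
                 res, residual_tol))
  }
  structure(list(pi = stats::setNames(pi, 0:N), params = p, residual = res),
            class = "blob_stationary")
}

# max |Q^T pi| without materializing Q (works at any N).
blob_residual <- function(p, pi) {
  N <- p$N
  r <- blob_rates(p)
  death <- r$death
  if (p$qs) death[2L] <- 0
  jump <- p$lam_star * as.numeric(seq(0, N) >= p$theta & seq(0, N) <= N - 1L)
  outflow <- r$beta + death + jump
  resid <- numeric(N + 1L)
  for (n in 0:N) {
    inflow <- 0
    if (n >= 1L) inflow <- inflow + r$beta[n] * pi[n]           # from n-1
    if (n <= N - 1L) inflow <- inflow + death[n + 2L] * pi[n + 2L] # from n+1
    if (n == N && p$theta <= N - 1L) {
      inflow <- inflow + p$lam_star * sum(pi[(p$theta + 1L):N])  # jumps
    }
    resid[n + 1L] <- inflow - outflow[n + 1L] * pi[n + 1L]
  }
  # the jump inflow from N-1 to N is already inside beta/jump bookkeeping:
  # beta counts n-1 -> n births; the lam_star jumps land at N only.
  max(abs(resid))
}

#' Stationary distribution by null-space extraction
#'
#' Oracle route: extracts the stationary vector as the null space of the
#' transposed generator restricted to the active states `1..N` (under the
#' QS constraint state 0 is disconnected, so it is removed before the
#' decomposition). Errors if the null space is not one-dimensional.
#'
#' @param p a [blob_params()] with `qs = TRUE`, or a QS generator matrix.
#' @return a `blob_stationary` object.
#' @export
blob_nullspace <- function(p) {
  if (inherits(p, "blob_params")) {
    if (!p$qs) stop("null-space extraction expects the QS chain")
    Q <- blob_generator(p)
    active <- 2:(p$N + 1L)
    A <- as.matrix(Matrix::t(Q[active, active, drop = FALSE]))
    N <- p$N
  } else {
    A <- as.matrix(Matrix::t(p))
    active <- seq_len(nrow(A))
    N <- nrow(A) - 1L
    p <- NULL
  }
  if (all(A == 0)) stop("degenerate generator: null space is not one-dimensional")
  sv <- svd(A)
  d <- sv$d
  tolr <- max(dim(A)) * max(d) * .Machine$double.eps * 100
  nullity <- sum(d < tolr)
  if (nullity != 1L) {
    stop(sprintf("degenerate generator: null space dimension %d", nullity))
  }
  v <- sv$v[, length(d)]
  v <- v * sign(sum(v))
  if (any(v < -1e-10 * max(abs(v)))) {
    stop("null vector has significantly negative entries")
  }
  v[v < 0] <- 0
  pi <- numeric(N + 1L)
  pi[active] <- v / sum(v)
  structure(list(pi = stats::setNames(pi, 0:N), params = p,
                 residual = if (!is.null(p)) blob_residual(p, pi) else NA_real_),
            class = "blob_stationary")
}

#' Summaries of a hyperblob stationary distribution
#'
#' Global order parameter `rho = <n>/N` and susceptibility
#' `chi = var(n)/<n>`, the branch probabilities `P_Lower` (mass below the
#' critical mass `theta`) and `P_Upper` (mass at or above it), and the
#' conditional `rho`/`chi` within each region after renormalization
#' (reported as `NA` for a region with zero mass).
#'
#' @param dist a `blob_stationary` or a probability vector over `0..N`.
#' @param p a [blob_params()] (needed when `dist` is a bare vector).
#' @return list with `rho`, `chi`, `P_lower`, `P_upper`, `rho_lower`,
#'   `chi_lower`, `rho_upper`, `chi_upper`.
#' @export
chain_summary <- function(dist, p = NULL) {
  if (inherits(dist, "blob_stationary")) {
    pi <- dist$pi
    if (is.null(p)) p <- dist$params
  } else {
    pi <- dist / sum(dist)
  }
  stopifnot(inherits(p, "blob_params"))
  N <- p$N
  n <- 0:N
  moments <- function(pr) {
    s <- sum(pr)
    if (s <= 0) return(list(rho = NA_real_, chi = NA_real_))
    pr <- pr / s
    m1 <- sum(n * pr); m2 <- sum(n^2 * pr)
    list(rho = m1 / N, chi = if (m1 > 0) (m2 - m1^2) / m1 else NA_real_)
  }
  lower <- pi * (n < p$theta)
  upper <- pi * (n >= p$theta)
  g <- moments(pi); lo <- moments(lower); up <- moments(upper)
  list(rho = g$rho, chi = g$chi,
       P_lower = sum(lower), P_upper = sum(upper),
       rho_lower = lo$rho, chi_lower = lo$chi,
       rho_upper = up$rho, chi_upper = up$chi)
}

#' Least-squares fit of a finite-size scaling exponent
#'
#' Fits `log(width) ~ log(N)` by ordinary least squares and reports the
#' scaling exponent `mu` (minus the slope) with its standard error.
#'
#' @param N vector of system sizes.
#' @param width vector of positive transition-window widths.
#' @return list with `mu`, `se`, and the `lm` fit.
#' @export
fit_scaling_exponent <- function(N, width) {
  ok <- is.finite(width) & width > 0
  if (sum(ok) < 2L) stop("need at least two finite widths to fit")
  fit <- stats::lm(log(width[ok]) ~ log(N[ok]))
  cf <- summary(fit)$coefficients
  list(mu = -unname(cf[2L, 1L]), se = unname(cf[2L, 2L]), fit = fit)
}

#' Finite-size scaling of the transition window
#'
#' For each system size, sweeps the exact QS stationary distribution over
#' the `lam_k` grid and locates the edges of the lower-to-upper jump:
#' `lambda(rho2)` is the largest `lam_k` at which the global order
#' parameter is still within `1/N` of the lower-region conditional order
#' parameter, and `lambda(rho2+)` the smallest `lam_k` at which it is
#' within `1/N` of the upper-region conditional value; the susceptibility
#' markers `lambda(chi2-)`/`lambda(chi2+)` are the extrema of the
#' finite-difference derivative of `chi(lam_k)`. Widths are the absolute
#' marker differences, and the exponent `mu` of `width ~ N^-mu` is fitted
#' on a log-log scale. Sizes at which the grid does not resolve the window
#' are flagged and excluded from the fit.
#'
#' @param Ns vector of system sizes (>= 4 for the fit).
#' @param lam_k_grid grid of pairwise drives resolving the transition at
#'   the largest size.
#' @param lam_star,theta_star,delta chain parameters held fixed across
#'   sizes.
#' @return an object of class `blob_scaling`: per-size data frame `widths`
#'   (with markers and a `resolved` flag) and fits `mu_rho`, `mu_chi`.
#' @export
scaling_analysis <- function(Ns, lam_k_grid, lam_star, theta_star,
                             delta = 1) {
  if (length(Ns) < 4L) stop("need at least 4 system sizes")
  lam_k_grid <- sort(lam_k_grid)
  rows <- lapply(Ns, function(N) {
    summ <- lapply(lam_k_grid, function(lk) {
      p <- blob_params(N = N, lam_k = lk, lam_star = lam_star,
                       delta = delta, theta_star = theta_star, qs = TRUE)
      chain_summary(blob_stationary(p))
    })
    rho <- vapply(summ, `[[`, 0, "rho")
    chi <- vapply(summ, `[[`, 0, "chi")
    rho_lo <- vapply(summ, `[[`, 0, "rho_lower")
    rho_up <- vapply(summ, `[[`, 0, "rho_upper")
    near_lo <- which(is.finite(rho_lo) & abs(rho - rho_lo) <= 1 / N)
    near_up <- which(is.finite(rho_up) & abs(rho - rho_up) <= 1 / N)
    lam_rho_lo <- if (length(near_lo)) lam_k_grid[max(near_lo)] else NA_real_
    lam_rho_up <- if (length(near_up)) lam_k_grid[min(near_up)] else NA_real_
    dchi <- diff(chi) / diff(lam_k_grid)
    mid <- (lam_k_grid[-1L] + lam_k_grid[-length(lam_k_grid)]) / 2
    lam_chi_lo <- mid[which.max(dchi)]
    lam_chi_up <- mid[which.min(dchi)]
    resolved <- is.finite(lam_rho_lo) && is.finite(lam_rho_up) &&
      lam_rho_up > lam_rho_lo
    data.frame(N = N,
               lam_rho_lo = lam_rho_lo, lam_rho_up = lam_rho_up,
               lam_chi_lo = lam_chi_lo, lam_chi_up = lam_chi_up,
               width_rho = abs(lam_rho_up - lam_rho_lo),
               width_chi = abs(lam_chi_up - lam_chi_lo),
               resolved = resolved)
  })
  widths <- do.call(rbind, rows)
  ok <- widths$resolved
  mu_rho <- if (sum(ok) >= 2L) {
    fit_scaling_exponent(widths$N[ok], widths$width_rho[ok])
  } else NULL
  mu_chi <- if (sum(ok) >= 2L) {
    fit_scaling_exponent(widths$N[ok], widths$width_chi[ok])
  } else NULL
  structure(list(widths = widths, mu_rho = mu_rho, mu_chi = mu_chi,
                 lam_k_grid = lam_k_grid, lam_star = lam_star,
                 theta_star = theta_star, delta = delta),
            class = "blob_scaling")
}

#' @export
print.blob_scaling <- function(x, ...) {
  cat("Finite-size scaling of the hyperblob transition window\n")
  print(x$widths, row.names = FALSE)
  if (!is.null(x$mu_rho)) {
    cat(sprintf("mu (order-parameter width) = %.3f +/- %.3f\n",
                x$mu_rho$mu, x$mu_rho$se))
  }
  if (!is.null(x$mu_chi)) {
    cat(sprintf("mu (susceptibility width)  = %.3f +/- %.3f\n",
                x$mu_chi$mu, x$mu_chi$se))
  }
  invisible(x)
}
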