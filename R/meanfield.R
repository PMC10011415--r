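#' Poisson-binomial pmf by subset enumeration
#'
#' Exact probability mass function of the number of successes among
#' independent Bernoulli trials with the given probabilities, computed by
#' explicit enumeration of all subsets (the sum over all micro-states with
#' `k` active members). Exponential cost: refused beyond 20 trials. This
#' is the reference implementation against which the DFT kernel is
#' validated.
#'
#' @param probs vector of probabilities in \[0, 1\].
#' @return numeric pmf over counts `0..length(probs)`.
#' @export
poisson_binomial_enum <- function(probs) {
  m <- length(probs)
  if (m > 20L) stop("enumeration refused for more than 20 probabilities")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  out <- numeric(m + 1L)
  if (m == 0L) { out[1L] <- 1; return(out) }
  for (k in 0:m) {
    if (k == 0L) {
      out[1L] <- prod(1 - probs)
    } else {
      sets <- utils::combn(m, k)
      out[k + 1L] <- sum(apply(sets, 2L, function(A) {
        prod(probs[A]) * prod(1 - probs[-A])
      }))
    }
  }
  out
}

#' Poisson-binomial pmf via the discrete Fourier transform
#'
#' Evaluates the same pmf as [poisson_binomial_enum()] through the DFT of
#' the characteristic function: with `L = length(probs) + 1` and
#' `C = exp(2*pi*i/L)`,
#' `P(K = k) = (1/L) * sum_l C^{-lk} prod_m (1 + (C^l - 1) p_m)`.
#' Unlike the subset expansion, this remains numerically stable for large
#' inputs (hundreds of trials). Tiny negative entries from floating-point
#' round-off are clipped to zero and the pmf renormalized; a drift above
#' 1e-6 raises a warning.
#'
#' @param probs vector of probabilities in \[0, 1\].
#' @return numeric pmf over counts `0..length(probs)`.
#' @export
poisson_binomial_dft <- function(probs) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!length(probs)) return(1)
  p <- cpp_pb_dft(as.numeric(probs))
  p[p < 0] <- 0
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("Poisson-binomial renormalization drift %.3g", abs(s - 1)))
  }
  p / s
}

#' Mean-field right-hand side
#'
#' The individual-based (first-order) approximation closes the exact
#' dynamics by assuming node states independent: writing `y_i` for the
#' activation probability of node `i`,
#' `dy_i/dt = -delta*y_i + (1-y_i) * sum_{e_j ∋ i} lambda_j * P(Theta_j <=
#' K_j^(i) <= |e_j|-1)`, where `K_j^(i)` is the Poisson-binomial count of
#' active members of `e_j` excluding `i`, evaluated with the DFT kernel.
#'
#' @param y activation probabilities in `\[0, 1\]^N`.
#' @param H a `hypergraph`.
#' @param params a [dynamics_params()] object.
#' @return derivative vector of length `N`.
#' @export
ode_rhs <- function(y, H, params) {
  si <- sim_inputs(H, params)
  if (length(y) != H$n) stop("state dimension mismatch")
  cpp_mf_rhs(as.numeric(y), si$n, si$ememb, si$eoff, si$theta, si$rate,
             params$delta)
}

#' Integrate the mean-field system to a steady state
#'
#' Adaptive Runge-Kutta-Fehlberg 4(5) integration (absolute error 1e-4,
#' relative error 1e-3 per step) in growing time chunks until the residual
#' `max|dy/dt|` falls below `residual_tol` or the time budget `t_limit` is
#' spent. The state is clipped into `\[0, 1\]` after every accepted chunk.
#'
#' The accepted local error of the adaptive solver sets a noise floor of
#' roughly the step tolerance on the achievable residual, far above the
#' steady-state criterion. Integration therefore only runs the approach
#' phase -- which also selects the dynamically stable state reachable from
#' `y0` -- and once the residual is small (< 1e-2) a damped Newton
#' iteration on `dy/dt = 0` (finite-difference Jacobian) polishes the root
#' quadratically. The polish is accepted only when it reaches the target
#' residual without moving any coordinate by more than 0.1, so it refines
#' the fixed point the flow selected rather than jumping to a different
#' one; otherwise integration simply continues and the polish is retried
#' after the next chunk.
#'
#' @param y0 initial activation probabilities in `\[0, 1\]^N`.
#' @param H a `hypergraph`.
#' @param params a [dynamics_params()] object.
#' @param residual_tol steady-state criterion on `max|dy/dt|`.
#' @param t_limit maximum integration time.
#' @return list with `y` (final state), `t` (time used), `residual`,
#'   `converged` (logical) and `rho` (mean of `y`).
#' @export
integrate_steady <- function(y0, H, params, residual_tol = 1e-8,
                             t_limit = 1e4) {
  si <- sim_inputs(H, params)
  y <- pmin(pmax(as.numeric(y0), 0), 1)
  if (length(y) != H$n) stop("state dimension mismatch")
  rhs <- function(y) {
    cpp_mf_rhs(y, si$n, si$ememb, si$eoff, si$theta, si$rate, params$delta)
  }
  rhs_fun <- function(t, y, parms) list(rhs(y))
  t_used <- 0
  chunk <- 10
  method <- deSolve::rkMethod("rk45f")
  # relax at the nominal step tolerances; once the residual is small,
  # attempt the Newton polish after every chunk. The polish is accepted
  # only if it reaches the target residual without moving the state far
  # (so it refines the fixed point the flow selected, rather than jumping
  # to a different one).
  repeat {
    res <- max(abs(rhs(y)))
    if (!is.finite(res)) stop("mean-field integration diverged (non-finite state)")
    if (res < residual_tol) break
    if (res < 1e-2) {
      np <- newton_polish(y, rhs, residual_tol)
      if (np$ok && max(abs(np$y - y)) < 0.1) {
        y <- np$y
        res <- np$residual
        break
      }
    }
    if (t_used >= t_limit) break
    span <- min(chunk, t_limit - t_used)
    sol <- deSolve::ode(y = y, times = c(0, span), func = rhs_fun,
                        parms = NULL, method = method,
                        atol = 1e-4, rtol = 1e-3, maxsteps = 1e5)
    y <- pmin(pmax(as.numeric(sol[nrow(sol), -1L]), 0), 1)
    if (anyNA(y)) stop("mean-field integration diverged (NaN state)")
    t_used <- t_used + span
    chunk <- min(chunk * 2, 2000)
  }
  list(y = y, t = t_used, residual = res, converged = res < residual_tol,
       rho = mean(y))
}

# Damped Newton iteration on rhs(y) = 0 with a forward-difference Jacobian.
# Returns ok = TRUE only if the target residual is reached; any step that
# fails to reduce the residual (after halving the damping down to 2^-10)
# aborts, leaving branch selection to the caller's integration phase.
newton_polish <- function(y, rhs, tol, max_iter = 25L) {
  N <- length(y)
  f <- rhs(y)
  res <- max(abs(f))
  for (it in seq_len(max_iter)) {
    if (res < tol) return(list(y = y, residual = res, ok = TRUE))
    J <- matrix(0, N, N)
    h <- 1e-7
    for (j in seq_len(N)) {
      yp <- y
      yp[j] <- yp[j] + h
      J[, j] <- (rhs(yp) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(y = y, residual = res, ok = FALSE))
    lam <- 1
    repeat {
      y2 <- pmin(pmax(y + lam * step, 0), 1)
      f2 <- rhs(y2)
      res2 <- max(abs(f2))
      if (res2 < res) break
      lam <- lam / 2
      if (lam < 2^-10) return(list(y = y, residual = res, ok = FALSE))
    }
    y <- y2
    f <- f2
    res <- res2
  }
  list(y = y, residual = res, ok = res < tol)
}

#' Trace mean-field branches by continuation in lambda
#'
#' For each seed micro-state, integrates to a steady state at the seed's
#' `lambda`, then marches the grid upward and downward, reusing the
#' previous steady state as the initial condition for the adjacent grid
#' point. A direction terminates early when its steady state collapses
#' onto an already-recorded trace (order-parameter distance below
#' `merge_tol` at the same `lambda`) or when integration fails to
#' converge (the trace is truncated and flagged).
#'
#' @param H a `hypergraph`.
#' @param lambdas sorted grid of spreading rates.
#' @param seeds list of seed micro-states (each in `\[0, 1\]^N`); names label
#'   the traces.
#' @param seed_lambda the grid value at which each seed is first relaxed
#'   (default: first grid point).
#' @param delta,theta_star,modulation dynamics template.
#' @param directions subset of `c("up", "down")`.
#' @param residual_tol,t_limit passed to [integrate_steady()].
#' @param merge_tol collapse threshold on `|drho|` (default `1/N`).
#' @return list of traces; each is a list with `label`, a data frame
#'   `path` (`lambda`, `rho`, `converged`, `merged`) and `states` (list of
#'   steady-state vectors in `lambda` order).
#' @export
branch_continuation <- function(H, lambdas, seeds,
                                seed_lambda = lambdas[1L],
                                delta = 1, theta_star = 0.5,
                                modulation = modulation_log2,
                                directions = c("up", "down"),
                                residual_tol = 1e-8, t_limit = 1e4,
                                merge_tol = 1 / H$n) {
  lambdas <- sort(lambdas)
  i0 <- which.min(abs(lambdas - seed_lambda))
  if (is.null(names(seeds))) names(seeds) <- paste0("seed", seq_along(seeds))
  traces <- list()
  recorded <- list()  # per lambda index: vector of recorded rho values
  rec_rho <- function(i) if (i <= length(recorded) && !is.null(recorded[[i]])) recorded[[i]] else numeric(0)
  add_rec <- function(i, rho) {
    while (length(recorded) < i) recorded[length(recorded) + 1L] <<- list(NULL)
    recorded[[i]] <<- c(recorded[[i]], rho)
  }
  for (nm in names(seeds)) {
    fits <- vector("list", length(lambdas))
    params0 <- dynamics_params(lambda = lambdas[i0], delta = delta,
                               theta_star = theta_star,
                               modulation = modulation)
    st0 <- integrate_steady(seeds[[nm]], H, params0, residual_tol, t_limit)
    fits[[i0]] <- st0
    march <- function(idx_seq, start_state) {
      prev <- start_state
      for (i in idx_seq) {
        params <- dynamics_params(lambda = lambdas[i], delta = delta,
                                  theta_star = theta_star,
                                  modulation = modulation)
        st <- integrate_steady(prev, H, params, residual_tol, t_limit)
        fits[[i]] <<- st
        if (!st$converged) break                       # truncate, flagged
        if (any(abs(rec_rho(i) - st$rho) < merge_tol)) break  # collapsed
        prev <- st$y
      }
    }
    if ("up" %in% directions && i0 < length(lambdas)) {
      march((i0 + 1L):length(lambdas), st0$y)
    }
    if ("down" %in% directions && i0 > 1L) {
      march((i0 - 1L):1L, st0$y)
    }
    keep <- which(!vapply(fits, is.null, TRUE))
    path <- data.frame(
      lambda = lambdas[keep],
      rho = vapply(fits[keep], function(f) f$rho, 0),
      residual = vapply(fits[keep], function(f) f$residual, 0),
      converged = vapply(fits[keep], function(f) f$converged, TRUE))
    for (q in seq_along(keep)) add_rec(keep[q], path$rho[q])
    traces[[nm]] <- list(label = nm, path = path,
                         states = lapply(fits[keep], function(f) f$y))
  }
  traces
}
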