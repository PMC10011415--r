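#' Cardinality modulation functions
#'
#' The per-hyperedge spreading rate factorises as `lambda * modulation(|e|)`.
#' The default modulation is the base-2 logarithm of the cardinality: it
#' equals 1 for pairwise interactions (so the pairwise dynamics is the
#' standard SIS model) and grows sublinearly, so the per-member rate
#' `log2(|e|)/|e|` vanishes for very large groups.
#'
#' `modulation_log2` is the default; `modulation_constant(a)` returns the
#' function that ignores cardinality and yields `a` (used e.g. to give the
#' global hyperedge of a hyperblob a bare rate).
#'
#' @param cardinality hyperedge cardinality (>= 2).
#' @param a constant value returned by the function built by
#'   `modulation_constant`.
#' @return `modulation_log2`: a numeric; `modulation_constant`: a function.
#' @export
modulation_log2 <- function(cardinality) log2(cardinality)

#' @rdname modulation_log2
#' @export
modulation_constant <- function(a = 1) {
  force(a)
  function(cardinality) rep(a, length(cardinality))
}

#' Dynamics parameters of the critical-mass contagion model
#'
#' Bundles the free spreading rate `lambda`, the deactivation rate `delta`,
#' the global critical-mass fraction `theta_star` in \[0, 1\], and the
#' cardinality modulation `lambda*(.)`. Each hyperedge `e_j` then carries
#' the threshold `Theta_j = ceiling(theta_star * |e_j|)` and the rate
#' `lambda_j = lambda * modulation(|e_j|)`.
#'
#' @param lambda nonnegative free spreading rate.
#' @param delta nonnegative deactivation rate.
#' @param theta_star critical-mass fraction in \[0, 1\].
#' @param modulation function of cardinality; default [modulation_log2].
#' @return an object of class `dynamics_params`.
#' @export
dynamics_params <- function(lambda, delta = 1, theta_star = 0.5,
                            modulation = modulation_log2) {
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (!is.numeric(delta) || delta < 0) stop("delta must be >= 0")
  if (!is.numeric(theta_star) || theta_star < 0 || theta_star > 1) {
    stop("theta_star must lie in [0, 1]")
  }
  stopifnot(is.function(modulation))
  structure(list(lambda = lambda, delta = delta, theta_star = theta_star,
                 modulation = modulation),
            class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf("Contagion parameters: lambda = %g, delta = %g, theta* = %g\n",
              x$lambda, x$delta, x$theta_star))
  invisible(x)
}

#' Critical-mass threshold of a hyperedge
#'
#' `Theta_j = ceiling(theta_star * cardinality)`: the minimum number of
#' active members for the hyperedge's activation process to exist.
#'
#' @param cardinality integer cardinality >= 2 (vectorised).
#' @param theta_star critical-mass fraction in \[0, 1\].
#' @return integer threshold(s) in `[0, cardinality]`.
#' @export
hyperedge_threshold <- function(cardinality, theta_star) {
  if (any(theta_star < 0) || any(theta_star > 1)) {
    stop("theta_star must lie in [0, 1]")
  }
  as.integer(ceiling(theta_star * cardinality))
}

#' Spreading rate of a hyperedge
#'
#' `lambda_j = lambda * modulation(cardinality)`; with the default base-2
#' logarithm modulation, `lambda_j = lambda * log2(cardinality)`.
#'
#' @param cardinality integer cardinality >= 2 (vectorised).
#' @param params a [dynamics_params()] object.
#' @return nonnegative rate(s).
#' @export
hyperedge_rate <- function(cardinality, params) {
  stopifnot(inherits(params, "dynamics_params"))
  params$lambda * params$modulation(cardinality)
}

# Per-hyperedge thresholds and rates for a whole hypergraph (internal).
edge_dynamics <- function(H, params) {
  card <- hyperedge_cardinalities(H)
  list(card = card,
       theta = hyperedge_threshold(card, params$theta_star),
       rate = hyperedge_rate(card, params))
}
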