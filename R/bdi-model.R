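#' A capped birth-death-innovation model of gene-family size
#'
#' Family copy number evolves on \{0, ..., C\} as a continuous-time Markov
#' chain with upward rate `i*lambda + kappa` (per-copy duplication plus
#' innovation) and downward rate `i*mu` (per-copy loss); the cap `C`
#' truncates the state space.  The root prior defaults to the chain's
#' stationary distribution, keeping simulation and inference self-consistent.
#'
#' @param kappa innovation (gain, 0 -> 1) rate, per unit branch length.
#' @param lambda per-copy duplication (birth) rate.
#' @param mu per-copy loss (death) rate.
#' @param C copy-number cap (>= 1); observed counts above `C` are truncated.
#' @param root_prior `"stationary"`, `"uniform"`, or a numeric vector of
#'   length `C + 1` summing to 1.
#' @return an object of class `gain_loss_model`.
#' @export
gain_loss_model <- function(kappa, lambda, mu, C = 10L,
                            root_prior = "stationary") {
  if (any(c(kappa, lambda, mu) < 0)) stop("rates must be >= 0")
  C <- as.integer(C)
  if (C < 1L) stop("cap C must be >= 1")
  m <- structure(list(kappa = kappa, lambda = lambda, mu = mu, C = C,
                      root_prior = root_prior),
                 class = "gain_loss_model")
  m$prior <- resolve_root_prior(m)
  m
}

resolve_root_prior <- function(model) {
  C <- model$C
  if (is.numeric(model$root_prior)) {
    p <- model$root_prior
    if (length(p) != C + 1L || abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("numeric root prior must be a length C+1 probability vector")
    return(p)
  }
  switch(model$root_prior,
         stationary = stationary_distribution(model),
         uniform = rep(1 / (C + 1), C + 1L),
         stop("unknown root prior: ", model$root_prior))
}

#' Rate matrix (generator) of the capped BDI chain
#'
#' Off-diagonals: `rate(i -> i+1) = i*lambda + kappa` for `i < C`,
#' `rate(i -> i-1) = i*mu` for `i > 0`; rows sum to zero.
#'
#' @param model a [gain_loss_model()].
#' @return a `(C+1) x (C+1)` matrix with dimnames `0..C`.
#' @export
build_generator <- function(model) {
  C <- model$C
  n <- C + 1L
  Q <- matrix(0, n, n, dimnames = list(0:C, 0:C))
  i <- 0:(C - 1L)
  Q[cbind(i + 1L, i + 2L)] <- i * model$lambda + model$kappa
  i <- 1:C
  Q[cbind(i + 1L, i)] <- i * model$mu
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities over a branch
#'
#' The matrix exponential `expm(Q t)` of the BDI generator: row-stochastic,
#' identity at `t = 0`.
#'
#' @param model a [gain_loss_model()].
#' @param t branch length (>= 0).
#' @return a `(C+1) x (C+1)` stochastic matrix.
#' @export
transition_probabilities <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  Q <- build_generator(model)
  if (t == 0) return(diag(nrow(Q)))
  P <- expm::expm(Q * t)
  P[P < 0] <- 0  # clip tiny negative round-off
  P / rowSums(P)
}

#' Stationary distribution of the capped BDI chain
#'
#' Solved from the generator's null space (`pi Q = 0`, `sum(pi) = 1`).  A
#' birth-death chain is reversible, so when all rates are positive this
#' equals the detailed-balance solution; degenerate corners (all rates zero)
#' fall back to a point mass at 0, the chain's absorbing convention.
#'
#' @param model a [gain_loss_model()].
#' @return probability vector over states `0..C`.
#' @export
stationary_distribution <- function(model) {
  Q <- build_generator(model)
  n <- nrow(Q)
  if (max(abs(Q)) == 0) {
    p <- numeric(n); p[1L] <- 1
    return(p)
  }
  A <- rbind(t(Q), rep(1, n))
  b <- c(numeric(n), 1)
  p <- qr.solve(A, b)
  if (any(!is.finite(p))) stop("stationary distribution did not solve: ",
                               "rates are numerically extreme")
  p[p < 0] <- 0
  p / sum(p)
}
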