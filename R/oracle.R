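# Exact continuous-time Markov-chain solution over the full 2^n state
# space. Ground truth for the stochastic engine on small models: the
# master equation dp/dt = p Q is solved with the matrix exponential
# (Matrix::expm), and window averages use fine fixed-step trapezoidal
# quadrature. A verification instrument, guarded to n <= 20.

#' Build the full state-space rate matrix of a small network
#'
#' `Q[S, S xor 2^i] = rate of flipping node i in S`, diagonal = minus the
#' row sum; rows of fixed points are all zero. The initial distribution
#' is the product of the per-node initial-state probabilities.
#'
#' @param network a `boolean_network` with resolved rates, `n <= 20`.
#' @return a `state_space_matrix`: sparse `Q` (2^n x 2^n), `p0`,
#'   `fixed` (logical per state), `n`.
#' @export
build_rate_matrix <- function(network) {
  stopifnot(inherits(network, "boolean_network"))
  n <- network$n
  if (n > 20) stop("state space too large: n = ", n, " (limit 20)")
  model <- compile_model(network)
  ns <- 2^n
  ii <- list()
  jj <- list()
  xx <- list()
  diag_ <- numeric(ns)
  fixed <- logical(ns)
  for (S in 0:(ns - 1)) {
    rates <- compiled_rates_vm(model, S)
    tot <- sum(rates)
    fixed[S + 1] <- tot == 0
    nz <- which(rates > 0)
    if (length(nz)) {
      ii[[length(ii) + 1]] <- rep(S + 1, length(nz))
      jj[[length(jj) + 1]] <-
        S + 1 + (1 - 2 * ((S %/% 2^(nz - 1)) %% 2)) * 2^(nz - 1)
      xx[[length(xx) + 1]] <- rates[nz]
      diag_[S + 1] <- -tot
    }
  }
  Q <- Matrix::sparseMatrix(
    i = c(unlist(ii), seq_len(ns)), j = c(unlist(jj), seq_len(ns)),
    x = c(unlist(xx), diag_), dims = c(ns, ns)
  )
  q <- vapply(network$nodes, `[[`, numeric(1), "istate")
  p0 <- 1
  for (i in seq_len(n)) p0 <- c(p0 * (1 - q[i]), p0 * q[i])
  structure(
    list(Q = Q, p0 = p0, n = n, fixed = fixed, network = network),
    class = "state_space_matrix"
  )
}

#' Exact state distribution at time t
#'
#' Solves the master equation: `p(t) = p(0) exp(Q t)`.
#'
#' @param M a [build_rate_matrix()] result.
#' @param t time, `>= 0`.
#' @return probability vector over all `2^n` states (index = packed
#'   state + 1), summing to 1.
#' @export
state_probabilities <- function(M, t) {
  stopifnot(t >= 0)
  if (t == 0) {
    return(M$p0)
  }
  as.numeric(M$p0 %*% Matrix::expm(M$Q * t))
}

#' Exact window-averaged state distributions
#'
#' For each statistics window `[k tau, min((k+1) tau, max_time))`,
#' the time average `(1/len) int p(t) dt`, computed by composite Simpson
#' quadrature on a fixed grid of 100 steps per window (fourth-order
#' error, negligible against the Monte-Carlo noise the oracle is
#' compared against). Each row sums to 1.
#'
#' @param M a [build_rate_matrix()] result.
#' @param tau window width.
#' @param max_time horizon.
#' @param steps quadrature steps per window (must be even).
#' @return matrix with one row per window, `2^n` columns.
#' @export
window_averaged_probabilities <- function(M, tau, max_time, steps = 100) {
  stopifnot(steps %% 2 == 0)
  W <- window_count(max_time, tau)
  ns <- 2^M$n
  out <- matrix(0, W, ns)
  h_full <- tau / steps
  P_full <- Matrix::expm(M$Q * h_full)
  p <- M$p0
  for (w in seq_len(W)) {
    len <- window_length(w, tau, max_time)
    if (abs(len - tau) < 1e-12) {
      h <- h_full
      P <- P_full
    } else {
      h <- len / steps
      P <- Matrix::expm(M$Q * h)
    }
    # composite Simpson: 1, 4, 2, ..., 4, 1 times h/3
    acc <- p
    for (s in seq_len(steps)) {
      p <- as.numeric(p %*% P)
      acc <- acc + p * (if (s == steps) 1 else if (s %% 2 == 1) 4 else 2)
    }
    out[w, ] <- acc * h / (3 * len)
  }
  out
}

#' Exact absorption probabilities at a time horizon
#'
#' Mass of `p(max_time)` on the fixed points (zero-rate states), per
#' state. Non-decreasing in `max_time`; identically zero for models
#' without stable states.
#'
#' @param M a [build_rate_matrix()] result.
#' @param max_time time horizon.
#' @return named numeric vector (names = packed fixed states), possibly
#'   empty.
#' @export
fixed_point_absorption <- function(M, max_time) {
  p <- state_probabilities(M, max_time)
  idx <- which(M$fixed)
  setNames(p[idx], as.character(idx - 1))
}
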