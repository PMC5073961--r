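#' Forward-filter / backward-smooth a Gaussian topic chain
#'
#' Applies the standard Kalman forward filter and Rauch-Tung-Striebel
#' backward smoother to a chain of variational observations. The state model
#' is a Gaussian random walk on the natural parameters of one topic:
#' `beta_1 ~ N(0, init_var + chain_var)` and
#' `beta_t | beta_{t-1} ~ N(beta_{t-1}, chain_var)`; the observation model is
#' `beta_hat_t ~ N(beta_t, nu_hat_t)`.
#'
#' Because the observation variances do not depend on the observed values,
#' the filtered and smoothed variances are shared by every word; they are
#' returned as length-`T` vectors while the means have one column per word.
#'
#' @param beta_hat Numeric vector (one word) or `T x W` matrix of variational
#'   observations, rows = time slices.
#' @param nu_hat Observation variance(s): scalar or length-`T` vector, all
#'   positive.
#' @param chain_var Transition variance of the random walk (> 0).
#' @param init_var Variance of the slice-1 state prior around 0, *excluding*
#'   the first transition step (> 0).
#' @return List with `m` (filtered means, `T x W`), `V` (filtered variances,
#'   length `T`), `m_tilde` (smoothed means), `V_tilde` (smoothed variances).
#' @export
kalman_smooth <- function(beta_hat, nu_hat, chain_var, init_var) {
  if (is.null(dim(beta_hat))) beta_hat <- matrix(beta_hat, ncol = 1)
  T_ <- nrow(beta_hat)
  if (T_ < 1L) .stopf("need at least one time slice")
  nu_hat <- rep_len(nu_hat, T_)
  if (any(nu_hat <= 0) || chain_var <= 0 || init_var <= 0)
    .stopf("all variances must be positive")

  m <- matrix(0, T_, ncol(beta_hat))
  V <- numeric(T_)
  m_prev <- rep(0, ncol(beta_hat))
  V_prev <- init_var
  for (t in seq_len(T_)) {
    P <- V_prev + chain_var
    m[t, ] <- (nu_hat[t] * m_prev + P * beta_hat[t, ]) / (P + nu_hat[t])
    V[t] <- nu_hat[t] * P / (P + nu_hat[t])
    m_prev <- m[t, ]
    V_prev <- V[t]
  }

  m_tilde <- m
  V_tilde <- V
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      J <- V[t] / (V[t] + chain_var)
      m_tilde[t, ] <- (1 - J) * m[t, ] + J * m_tilde[t + 1L, ]
      V_tilde[t] <- V[t] + J^2 * (V_tilde[t + 1L] - (V[t] + chain_var))
    }
  }
  list(m = m, V = V, m_tilde = m_tilde, V_tilde = V_tilde)
}

# T x T matrix S with m_tilde = S %*% beta_hat (the smoother is linear in the
# observations and word-independent); used for gradients in the M-step.
.smoother_matrix <- function(T_, nu_hat, chain_var, init_var) {
  S <- matrix(0, T_, T_)
  for (s in seq_len(T_)) {
    e <- numeric(T_)
    e[s] <- 1
    S[, s] <- kalman_smooth(e, nu_hat, chain_var, init_var)$m_tilde[, 1]
  }
  S
}
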