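#' @keywords internal
"_PACKAGE"

# Floor applied before any log() so natural parameters stay finite.
.EPS <- 1e-12

#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` with the max subtracted first, so that
#' vectors of large-magnitude log probabilities do not overflow.
#'
#' @param x Numeric vector (may contain `-Inf`).
#' @return A scalar, `log(sum(exp(x)))`.
#' @export
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix; returns a vector of length nrow(x).
# K (ncol) is typically small, so a pmax sweep over columns is fast.
.row_lse <- function(x) {
  m <- x[, 1L]
  nc <- ncol(x)
  if (nc > 1L) for (j in 2L:nc) m <- pmax(m, x[, j])
  m[!is.finite(m)] <- 0
  s <- exp(x[, 1L] - m)
  if (nc > 1L) for (j in 2L:nc) s <- s + exp(x[, j] - m)
  m + log(s)
}

# Round half away from zero (base round() rounds halves to even).
.round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# One Dirichlet(alpha) draw per row; alpha is a vector of concentrations.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 # degenerate tiny-alpha draws: fall back to uniform
  g / rowSums(g)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
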