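# Jacobi-preconditioned conjugate gradients for sparse SPD systems.
# Deterministic; used by the thermal solver where direct factorisation of
# large 3-d operators is too expensive.
cg_solve <- function(A, b, x0 = NULL, tol = 1e-10, maxit = 20000L,
                     diag_A = NULL) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  if (is.null(diag_A)) diag_A <- Matrix::diag(A)
  minv <- 1 / diag_A
  r <- b - as.numeric(A %*% x)
  z <- minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = numeric(n), iterations = 0L,
                              residual = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rnorm <- sqrt(sum(r * r))
    if (rnorm <= tol * bnorm)
      return(list(x = x, iterations = it, residual = rnorm / bnorm))
    z <- minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf(
    "solver failure: conjugate gradients did not converge (residual %.3g)",
    rnorm / bnorm))
}
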