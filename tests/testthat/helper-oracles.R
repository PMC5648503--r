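# Dense-matrix oracles used across tests. These rebuild every quantity from
# the definition with explicit nt x nt matrices, independent of the
# package's structured solvers, and are only used at small n.

# subject-major vectorization: entry (i, j) at position (i-1)*t + j
vec_st <- function(V) as.vector(t(V))

dense_sigma <- function(fit) {
  n <- fit$n; t <- fit$t
  S <- matrix(0, n * t, n * t)
  for (i in seq_len(n)) {
    ii <- ((i - 1) * t + 1):(i * t)
    S[ii, ii] <- sigma_block(fit, i)
  }
  S
}

dense_design <- function(m, n, t) {
  X <- kronecker(rep(1, n), diag(t))
  if (!is.null(m)) X <- cbind(X, vec_st(m))
  X
}

# component kernel columns L = [Gc | Hc | B | C] as a dense nt x (2+2t) matrix
dense_L <- function(g, m, t, with_meth = TRUE) {
  n <- length(g)
  G <- rep(g, each = t)
  cols <- list(G - mean(G))
  if (with_meth) {
    MG <- vec_st(m) * G
    cols <- c(cols, list(MG - mean(MG)))
  }
  B <- matrix(0, n * t, t)
  for (i in seq_len(n)) for (j in seq_len(t)) B[(i - 1) * t + j, j] <- g[i]
  cols <- c(cols, lapply(seq_len(t), function(j) B[, j]))
  if (with_meth) {
    C <- B * vec_st(m)
    cols <- c(cols, lapply(seq_len(t), function(j) C[, j]))
  }
  do.call(cbind, cols)
}

# dense restricted -2 loglik (without constant) at given variances
dense_reml_obj <- function(tau, theta, eps, y, m) {
  n <- nrow(y); t <- ncol(y)
  S <- matrix(0, n * t, n * t)
  for (i in seq_len(n)) {
    Bi <- matrix(tau, t, t)
    diag(Bi) <- tau + eps + if (!is.null(m)) theta * m[i, ]^2 else 0
    ii <- ((i - 1) * t + 1):(i * t)
    S[ii, ii] <- Bi
  }
  X <- dense_design(m, n, t)
  Si <- solve(S)
  yv <- vec_st(y)
  XtSX <- t(X) %*% Si %*% X
  b <- solve(XtSX, t(X) %*% Si %*% yv)
  r <- yv - X %*% b
  as.numeric(determinant(S)$modulus + determinant(XtSX)$modulus +
               t(r) %*% Si %*% r)
}

# dense projected precision P0 for a fit
dense_p0 <- function(fit) {
  S <- dense_sigma(fit)
  X <- dense_design(if (fit$has_meth) fit$m else NULL, fit$n, fit$t)
  Si <- solve(S)
  Si - Si %*% X %*% solve(t(X) %*% Si %*% X, t(X) %*% Si)
}
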