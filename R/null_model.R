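# --- internal covariance algebra -------------------------------------------
#
# Under the null the nt x nt covariance is block diagonal by subject with
# t x t blocks
#   Sigma_i = eps I_t + tau 11' + theta diag(m_i^2).
# Writing D_i = diag(eps + theta m_ij^2), the Sherman-Morrison identity
#   Sigma_i^{-1} = D_i^{-1} - tau/(1 + tau s_i) D_i^{-1} 11' D_i^{-1},
#   s_i = sum_j 1/d_ij,
# turns every solve into n x t matrix arithmetic vectorized over subjects;
# the nt x nt matrix is never formed. nt-vectors are carried as n x t
# matrices throughout.

.sigma_struct <- function(tau, theta, eps, m, n, t) {
  D <- if (is.null(m) || theta == 0) matrix(eps, n, t) else eps + theta * m^2
  Wd <- 1 / D
  s <- rowSums(Wd)
  list(D = D, Wd = Wd, s = s, cfac = tau / (1 + tau * s), tau = tau)
}

# Sigma^{-1} V for V laid out n x t (one row per subject block)
.solve_blocks <- function(st, V) {
  V * st$Wd - (st$cfac * rowSums(st$Wd * V)) * st$Wd
}

.logdet_sigma <- function(st) sum(log(st$D)) + sum(log1p(st$tau * st$s))

# null fixed-design columns as n x t matrices: t tissue intercepts plus,
# when m is present, the overall methylation slope column
.design_cols <- function(m, n, t) {
  X <- vector("list", t + !is.null(m))
  for (j in seq_len(t)) {
    Jj <- matrix(0, n, t)
    Jj[, j] <- 1
    X[[j]] <- Jj
  }
  if (!is.null(m)) X[[t + 1L]] <- m
  X
}

.xtsx <- function(st, Xcols) {
  q <- length(Xcols)
  SX <- lapply(Xcols, function(Xk) .solve_blocks(st, Xk))
  A <- matrix(0, q, q)
  for (a in seq_len(q))
    for (b in a:q)
      A[a, b] <- A[b, a] <- sum(Xcols[[a]] * SX[[b]])
  list(A = A, SX = SX)
}

.xtsv <- function(Xcols, SV) vapply(Xcols, function(Xk) sum(Xk * SV), numeric(1))

# -2 * restricted log-likelihood (without the (nt-q)log(2pi) constant).
# The tissue-intercept block of X' Sigma^{-1} X has the closed form
# diag(colSums(Wd)) - Wd' (cfac Wd), avoiding per-column solves inside the
# optimizer loop.
.reml_obj <- function(par, y, m, n, t, free_theta) {
  tau <- exp(par[1])
  theta <- if (free_theta) exp(par[2]) else 0
  eps <- exp(par[length(par)])
  st <- .sigma_struct(tau, theta, eps, m, n, t)
  A11 <- diag(colSums(st$Wd), t, t) - crossprod(st$Wd, st$cfac * st$Wd)
  Sy <- .solve_blocks(st, y)
  if (is.null(m)) {
    xtsx <- A11
    xtsy <- colSums(Sy)
  } else {
    Sm <- .solve_blocks(st, m)
    a12 <- colSums(Sm)
    xtsx <- rbind(cbind(A11, a12), c(a12, sum(m * Sm)))
    xtsy <- c(colSums(Sy), sum(m * Sy))
  }
  ch <- tryCatch(chol(xtsx), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  b <- backsolve(ch, forwardsolve(t(ch), xtsy))
  quad <- sum(y * Sy) - sum(xtsy * b)
  .logdet_sigma(st) + 2 * sum(log(diag(ch))) + quad
}

#' Fit the null multi-tissue expression model by REML
#'
#' The null model regresses expression on tissue intercepts and (optionally)
#' an overall methylation slope, with a subject random intercept (variance
#' `tau`), per-subject tissue-specific random methylation slopes (common
#' variance `theta`), and i.i.d. residual noise (variance `eps`):
#' `Y = J alpha + M lam + A u + D x + xi`. The marginal covariance of
#' `vec(Y)` is block diagonal by subject with blocks
#' `Sigma_i = eps I + tau 11' + theta diag(m_i^2)`, which the solver
#' exploits (see [sigma_inverse_apply()]). Variances are estimated by
#' restricted maximum likelihood on the log scale (floored at 1e-8 so
#' boundary solutions are admissible); the fixed effects are the GLS
#' solutions at the REML variances.
#'
#' When `m` is `NULL` the methylation terms are dropped (`lam = theta = 0`),
#' giving the null model of the genotype + genotype-by-tissue joint test
#' (see [jaguar_style_test()]).
#'
#' @param y n x t expression matrix (subjects x tissues).
#' @param m n x t methylation matrix, or `NULL` for the methylation-free null.
#' @param max_iter maximum optimizer iterations.
#' @param tol relative convergence tolerance on the REML objective.
#' @return object of class `meqtl_null_fit` with elements `alpha_hat`,
#'   `lam_hat`, `tau_hat`, `theta_hat`, `eps_hat`, `residuals` (GLS residual
#'   matrix), `loglik` (restricted log-likelihood at the optimum),
#'   `converged`, `y`, `m`, `n`, `t`.
#' @export
fit_null <- function(y, m = NULL, max_iter = 200L, tol = 1e-8) {
  y <- as.matrix(y)
  n <- nrow(y)
  t <- ncol(y)
  if (n < 3L || t < 2L) stop("need at least 3 subjects and 2 tissues")
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite with no missing values")
  if (!is.null(m)) {
    m <- as.matrix(m)
    if (!all(dim(m) == dim(y))) stop("m must have the same dimensions as y")
    if (anyNA(m) || any(!is.finite(m))) stop("m must be finite with no missing values")
    if (stats::sd(as.vector(m)) < 1e-12)
      stop("degenerate design: methylation is constant")
  }
  free_theta <- !is.null(m)

  # moment-based starting values from centered per-tissue residual variance
  r0 <- apply(y, 2, function(col) col - mean(col))
  v0 <- max(stats::var(as.vector(r0)), 1e-4)
  par0 <- log(c(0.3 * v0, if (free_theta) 0.1 * v0, 0.6 * v0))

  opt <- stats::nlminb(par0, .reml_obj,
                       y = y, m = m, n = n, t = t, free_theta = free_theta,
                       lower = log(1e-8), upper = log(1e8),
                       control = list(iter.max = max_iter, rel.tol = tol))
  tau <- exp(opt$par[1])
  theta <- if (free_theta) exp(opt$par[2]) else 0
  eps <- exp(opt$par[length(opt$par)])

  st <- .sigma_struct(tau, theta, eps, m, n, t)
  Xcols <- .design_cols(m, n, t)
  xx <- .xtsx(st, Xcols)
  Sy <- .solve_blocks(st, y)
  xtsy <- .xtsv(Xcols, Sy)
  b <- solve(xx$A, xtsy)
  alpha_hat <- b[seq_len(t)]
  lam_hat <- if (free_theta) b[t + 1L] else NULL
  fitted <- rep(alpha_hat, each = n) + if (free_theta) lam_hat * m else 0
  resid <- y - fitted
  q <- t + as.integer(free_theta)
  loglik <- -0.5 * (opt$objective + (n * t - q) * log(2 * pi))

  structure(list(alpha_hat = alpha_hat, lam_hat = lam_hat,
                 tau_hat = tau, theta_hat = theta, eps_hat = eps,
                 residuals = resid, loglik = loglik,
                 converged = (opt$convergence == 0),
                 objective = opt$objective, n = n, t = t,
                 y = y, m = m, has_meth = free_theta),
            class = "meqtl_null_fit")
}

#' @export
print.meqtl_null_fit <- function(x, ...) {
  cat("Null model REML fit (", x$n, " subjects x ", x$t, " tissues)\n", sep = "")
  cat("  variance components: tau =", signif(x$tau_hat, 4),
      " theta =", signif(x$theta_hat, 4),
      " eps =", signif(x$eps_hat, 4), "\n")
  if (x$has_meth) cat("  methylation slope lam =", signif(x$lam_hat, 4), "\n")
  cat("  restricted log-likelihood:", signif(x$loglik, 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

# struct for a fitted object
.fit_struct <- function(fit) {
  .sigma_struct(fit$tau_hat, fit$theta_hat, fit$eps_hat,
                fit$m, fit$n, fit$t)
}

#' Apply the inverse null covariance to a vector or matrix
#'
#' Computes `Sigma^{-1} v` blockwise (each block solve is a closed-form
#' t x t Sherman-Morrison inverse); the full nt x nt matrix is never
#' assembled. Vectors follow the subject-major layout
#' `v[(i-1)*t + j]` (tissue j within subject i), i.e. `as.vector(t(V))`
#' for an n x t matrix `V`.
#'
#' @param fit a [fit_null()] result.
#' @param v numeric vector of length n*t, or an n x t matrix.
#' @return same shape as `v`.
#' @export
sigma_inverse_apply <- function(fit, v) {
  stopifnot(inherits(fit, "meqtl_null_fit"))
  st <- .fit_struct(fit)
  if (is.matrix(v)) {
    if (!all(dim(v) == c(fit$n, fit$t))) stop("v must be n x t")
    return(.solve_blocks(st, v))
  }
  if (length(v) != fit$n * fit$t) stop("v must have length n*t")
  V <- t(matrix(v, fit$t, fit$n))
  as.vector(t(.solve_blocks(st, V)))
}

#' Per-subject covariance block of the fitted null model
#'
#' @param fit a [fit_null()] result.
#' @param i subject index.
#' @return the t x t block `eps I + tau 11' + theta diag(m_i^2)` of the
#'   fitted covariance.
#' @export
sigma_block <- function(fit, i) {
  stopifnot(inherits(fit, "meqtl_null_fit"))
  t <- fit$t
  S <- matrix(fit$tau_hat, t, t)
  diag(S) <- fit$tau_hat + fit$eps_hat +
    if (fit$has_meth) fit$theta_hat * fit$m[i, ]^2 else 0
  S
}

#' Asymptotic standard errors of the REML variance components
#'
#' Inverts the numerically differentiated observed information of the
#' restricted log-likelihood with respect to (tau, theta, eps), on the
#' natural variance scale by default or for the log-variances with
#' `scale = "log"`.
#'
#' @param fit a converged [fit_null()] result.
#' @param scale `"variance"` for the natural scale, `"log"` for SEs of
#'   log(tau), log(theta), log(eps).
#' @return named vector of standard errors.
#' @export
null_fit_se <- function(fit, scale = c("variance", "log")) {
  stopifnot(inherits(fit, "meqtl_null_fit"))
  scale <- match.arg(scale)
  free_theta <- fit$has_meth
  th <- c(fit$tau_hat, if (free_theta) fit$theta_hat, fit$eps_hat)
  f <- if (scale == "log") {
    function(lv) .reml_obj(lv, fit$y, fit$m, fit$n, fit$t, free_theta) / 2
  } else {
    function(v) {
      if (any(v <= 0)) return(NA_real_)
      .reml_obj(log(v), fit$y, fit$m, fit$n, fit$t, free_theta) / 2
    }
  }
  x0 <- if (scale == "log") log(th) else th
  H <- stats::optimHess(x0, f)    # observed information of -loglik_R
  se <- sqrt(diag(solve(H)))
  names(se) <- if (free_theta) c("tau", "theta", "eps") else c("tau", "eps")
  se
}
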