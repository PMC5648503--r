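#' Simulation parameters for the multi-tissue eQTL generative model
#'
#' Bundles every parameter of the single-locus, single-gene generative model
#' used throughout the package: per-subject expression across `n_tissues`
#' tissues is a sum of tissue intercepts, fixed genotype (`beta`),
#' methylation (`lam`) and genotype-by-methylation (`phi`) effects, plus
#' random effects for subject (`tau`), genotype-by-tissue (`gamma`),
#' genotype-by-methylation-by-tissue (`delta`) and methylation-by-tissue
#' (`theta`) interactions, and i.i.d. residual noise (`eps`).
#'
#' The tissue-specific variance components `gamma` and `delta` are usually
#' set through their proportion of variance explained (PVE); see
#' [pve_to_variances()].
#'
#' @param n_subjects number of subjects (n).
#' @param n_tissues number of tissues (t).
#' @param maf minor allele frequency in (0, 0.5].
#' @param alpha tissue intercepts; scalar recycled to length `n_tissues`.
#' @param beta additive genotype fixed effect.
#' @param lam overall methylation fixed effect.
#' @param phi genotype-by-methylation fixed effect.
#' @param tau subject random-intercept variance (>= 0).
#' @param gamma genotype-by-tissue variance component (>= 0).
#' @param delta genotype-by-methylation-by-tissue variance component (>= 0).
#' @param theta methylation-by-tissue variance component (>= 0).
#' @param eps residual variance (> 0).
#' @param meth_cov t x t positive-definite covariance of the per-subject
#'   methylation vector. Default: compound symmetric, unit variance,
#'   correlation 0.5.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_subjects = 500L, n_tissues = 5L, maf = 0.3,
                       alpha = 0, beta = 0, lam = 0, phi = 0,
                       tau = 1, gamma = 0, delta = 0, theta = 1, eps = 1,
                       meth_cov = NULL) {
  n <- as.integer(n_subjects)
  t <- as.integer(n_tissues)
  if (n < 1L || t < 1L) stop("n_subjects and n_tissues must be positive")
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  vc <- c(tau = tau, gamma = gamma, delta = delta, theta = theta)
  if (any(vc < 0)) stop("variance components must be nonnegative")
  if (eps <= 0) stop("eps must be positive")
  if (length(alpha) == 1L) alpha <- rep(alpha, t)
  if (length(alpha) != t) stop("alpha must have length 1 or n_tissues")
  if (is.null(meth_cov)) {
    meth_cov <- matrix(0.5, t, t)
    diag(meth_cov) <- 1
  }
  meth_cov <- as.matrix(meth_cov)
  if (!isTRUE(all.equal(meth_cov, t(meth_cov), tolerance = 1e-10)))
    stop("meth_cov must be symmetric")
  ch <- tryCatch(chol(meth_cov), error = function(e) NULL)
  if (is.null(ch))
    stop("meth_cov must be positive definite (Cholesky factorization failed)")
  structure(list(n_subjects = n, n_tissues = t, maf = maf, alpha = alpha,
                 beta = beta, lam = lam, phi = phi, tau = tau, gamma = gamma,
                 delta = delta, theta = theta, eps = eps, meth_cov = meth_cov),
            class = "sim_params")
}

#' Simulate biallelic genotypes under Hardy-Weinberg equilibrium
#'
#' Minor-allele counts are drawn i.i.d. Binomial(2, maf).
#'
#' @param n number of subjects.
#' @param maf minor allele frequency in (0, 0.5].
#' @return integer vector of length `n` with values in {0, 1, 2}.
#' @export
gen_genotypes <- function(n, maf) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  stats::rbinom(n, size = 2L, prob = maf)
}

#' Simulate cross-tissue methylation values
#'
#' Each subject's t-vector of methylation values is drawn i.i.d. from a
#' mean-zero multivariate normal with covariance `meth_cov`.
#'
#' @param n number of subjects.
#' @param t number of tissues.
#' @param meth_cov t x t positive-definite covariance matrix.
#' @return numeric matrix, `n` subjects x `t` tissues.
#' @export
gen_methylation <- function(n, t, meth_cov) {
  meth_cov <- as.matrix(meth_cov)
  if (nrow(meth_cov) != t || ncol(meth_cov) != t)
    stop("meth_cov must be ", t, " x ", t)
  ch <- tryCatch(chol(meth_cov), error = function(e) NULL)
  if (is.null(ch))
    stop("meth_cov must be positive definite (Cholesky factorization failed)")
  m <- MASS::mvrnorm(n, mu = rep(0, t), Sigma = meth_cov)
  matrix(m, nrow = n, ncol = t)
}

#' Convert PVE targets to variance components
#'
#' The proportion of variance explained by the genotype-by-tissue effect is
#' PVE_gamma = gamma / (theta + tau + eps + gamma + delta), and analogously
#' PVE_delta for the three-way interaction. Given the nuisance variances and
#' the two PVE targets (in percent), the implied (gamma, delta) solve a 2 x 2
#' linear system.
#'
#' @param pve_gamma,pve_delta PVE targets in percent (0-100), summing to
#'   less than 100.
#' @param tau,theta,eps nuisance variances.
#' @return named numeric vector `c(gamma = , delta = )`.
#' @export
pve_to_variances <- function(pve_gamma, pve_delta, tau = 1, theta = 1, eps = 1) {
  if (pve_gamma < 0 || pve_delta < 0)
    stop("PVE values must be nonnegative")
  if (pve_gamma + pve_delta >= 100)
    stop("infeasible PVE: pve_gamma + pve_delta must be < 100")
  pg <- pve_gamma / 100
  pd <- pve_delta / 100
  base <- tau + theta + eps
  total <- base / (1 - pg - pd)
  c(gamma = pg * total, delta = pd * total)
}

#' Simulate multi-tissue expression at one locus
#'
#' Draws the random effects (subject intercepts, genotype-by-tissue,
#' genotype-by-methylation-by-tissue, methylation-by-tissue, residual) and
#' assembles expression as
#' `y_ij = alpha_j + beta g_i + lam m_ij + phi m_ij g_i + a_i + b_ij g_i +
#' c_ij m_ij g_i + d_ij m_ij + xi_ij`.
#' Each subject receives an independent draw of the tissue-indexed effects
#' b, c, d (entries i.i.d. with variances gamma, delta, theta), so all
#' random effects are independent across subjects and the implied
#' covariance of `vec(Y)` is block diagonal by subject.
#'
#' @param p a [sim_params()] object.
#' @param g genotype vector of length n (minor-allele counts).
#' @param m n x t methylation matrix.
#' @return numeric expression matrix, n subjects x t tissues.
#' @export
gen_expression <- function(p, g, m) {
  stopifnot(inherits(p, "sim_params"))
  n <- length(g)
  m <- as.matrix(m)
  if (nrow(m) != n) stop("nrow(m) must equal length(g)")
  t <- ncol(m)
  if (t != p$n_tissues) stop("ncol(m) must equal p$n_tissues")
  a  <- stats::rnorm(n, 0, sqrt(p$tau))
  b  <- matrix(stats::rnorm(n * t, 0, sqrt(p$gamma)), n, t)
  cc <- matrix(stats::rnorm(n * t, 0, sqrt(p$delta)), n, t)
  d  <- matrix(stats::rnorm(n * t, 0, sqrt(p$theta)), n, t)
  xi <- matrix(stats::rnorm(n * t, 0, sqrt(p$eps)), n, t)
  y <- rep(p$alpha, each = n) +
    p$beta * g +
    p$lam * m +
    p$phi * m * g +
    a +
    b * g +
    cc * m * g +
    d * m +
    xi
  matrix(y, n, t)
}

#' Simulate one complete dataset (genotype, methylation, expression)
#'
#' @param p a [sim_params()] object.
#' @param seed optional integer seed; if supplied the R RNG is seeded before
#'   generation so the dataset is fully reproducible.
#' @return list with components `g` (length-n genotype vector), `m` (n x t
#'   methylation matrix), `y` (n x t expression matrix), and `params`.
#' @export
sim_dataset <- function(p, seed = NULL) {
  stopifnot(inherits(p, "sim_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- gen_genotypes(p$n_subjects, p$maf)
  m <- gen_methylation(p$n_subjects, p$n_tissues, p$meth_cov)
  y <- gen_expression(p, g, m)
  list(g = g, m = m, y = y, params = p)
}
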