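# Score machinery notation, all under the fitted null:
#   R  = Sigma^{-1} resid          (n x t)
#   Gc = expanded genotype, grand-mean centered
#   Hc = expanded methylation*genotype, grand-mean centered
#   B  = nt x t stacked-genotype design, column j' holds g_i in tissue j'
#   C  = analogous with entries m_ij * g_i
# Linear scores: U_beta = resid' Sigma^{-1} Gc, U_phi likewise with Hc.
# Quadratic scores: U_gamma = 1/2 ||B' Sigma^{-1} resid||^2, U_delta with C.
# Null moments of any weighted combination come from the projected precision
# P0 = Sigma^{-1} - Sigma^{-1} X (X'Sigma^{-1}X)^{-1} X'Sigma^{-1} through
# the (2+2t) x (2+2t) Gram matrix S = L' P0 L of the stacked kernel columns
# L = [Gc | Hc | B | C]: for kernel K = L W L', E = tr(WS) and
# Var = 2 tr(WSWS). Everything uses blockwise solves only.

# component columns as a list of n x t matrices
.build_L <- function(fit, g, m, components) {
  n <- fit$n; t <- fit$t
  L <- list()
  idx <- list()
  k <- 0L
  if ("beta" %in% components) {
    L[[k + 1L]] <- matrix(g - mean(g), n, t)
    idx$beta <- k + 1L
    k <- k + 1L
  }
  if ("phi" %in% components) {
    H <- g * m
    L[[k + 1L]] <- H - mean(H)
    idx$phi <- k + 1L
    k <- k + 1L
  }
  if ("gamma" %in% components) {
    for (j in seq_len(t)) {
      Bj <- matrix(0, n, t)
      Bj[, j] <- g
      L[[k + j]] <- Bj
    }
    idx$gamma <- k + seq_len(t)
    k <- k + t
  }
  if ("delta" %in% components) {
    for (j in seq_len(t)) {
      Cj <- matrix(0, n, t)
      Cj[, j] <- g * m[, j]
      L[[k + j]] <- Cj
    }
    idx$delta <- k + seq_len(t)
    k <- k + t
  }
  list(L = L, idx = idx)
}

# Gram matrix S = L' P0 L via structured solves
.score_gram <- function(fit, L) {
  st <- .fit_struct(fit)
  Xcols <- .design_cols(if (fit$has_meth) fit$m else NULL, fit$n, fit$t)
  K <- length(L)
  SL <- lapply(L, function(Lk) .solve_blocks(st, Lk))
  S0 <- matrix(0, K, K)
  for (a in seq_len(K))
    for (b in a:K)
      S0[a, b] <- S0[b, a] <- sum(L[[a]] * SL[[b]])
  xx <- .xtsx(st, Xcols)
  XtSL <- vapply(SL, function(SLk) .xtsv(Xcols, SLk),
                 numeric(length(Xcols)))
  S <- S0 - crossprod(XtSL, solve(xx$A, XtSL))
  (S + t(S)) / 2
}

#' Efficient scores for the genetic and interaction effects
#'
#' Evaluates, at the fitted null, the scores for the additive genotype
#' effect (`u_beta`), the genotype-by-methylation fixed effect (`u_phi`),
#' and the genotype-by-tissue (`u_gamma`) and
#' genotype-by-methylation-by-tissue (`u_delta`) variance components. The
#' two variance-component scores are nonnegative quadratic forms in the
#' precision-weighted residuals. For a methylation-free fit only `u_beta`
#' and `u_gamma` are defined.
#'
#' @param fit a [fit_null()] result.
#' @param g genotype vector (minor-allele counts, length n).
#' @param m n x t methylation matrix; defaults to the matrix stored in `fit`.
#' @return object of class `meqtl_scores`: the scores, the component Gram
#'   matrix `S` used for null moments, index bookkeeping, and a
#'   `degenerate` flag (monomorphic genotype).
#' @export
efficient_scores <- function(fit, g, m = fit$m) {
  stopifnot(inherits(fit, "meqtl_null_fit"))
  g <- as.numeric(g)
  if (length(g) != fit$n) stop("g must have length n")
  if (fit$has_meth) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(fit$n, fit$t))) stop("m must be n x t")
  }
  components <- if (fit$has_meth) c("beta", "phi", "gamma", "delta")
                else c("beta", "gamma")
  bl <- .build_L(fit, g, m, components)
  S <- .score_gram(fit, bl$L)

  R <- .solve_blocks(.fit_struct(fit), fit$residuals)
  u_beta <- sum(R * bl$L[[bl$idx$beta]])
  bq <- colSums(g * R)
  u_gamma <- 0.5 * sum(bq^2)
  if (fit$has_meth) {
    u_phi <- sum(R * bl$L[[bl$idx$phi]])
    cq <- colSums(g * m * R)
    u_delta <- 0.5 * sum(cq^2)
  } else {
    u_phi <- NA_real_
    u_delta <- NA_real_
  }
  structure(list(u_beta = u_beta, u_phi = u_phi,
                 u_gamma = u_gamma, u_delta = u_delta,
                 S = S, idx = bl$idx, components = components,
                 t = fit$t, degenerate = (stats::sd(g) == 0)),
            class = "meqtl_scores")
}

# null mean/SD of each component statistic (U_beta^2, U_phi^2 linear-squared;
# U_gamma, U_delta quadratic) from the Gram matrix
.component_moments <- function(S, idx) {
  out <- list()
  for (nm in names(idx)) {
    ii <- idx[[nm]]
    if (length(ii) == 1L) {           # squared linear score: V * chi^2_1
      V <- S[ii, ii]
      out[[nm]] <- c(e = V, sd = sqrt(2) * V)
    } else {                          # quadratic form, kernel 1/2 LL'
      Sg <- S[ii, ii, drop = FALSE]
      e <- 0.5 * sum(diag(Sg))
      v <- 0.5 * sum(Sg * t(Sg))      # 2 tr((P0 K)^2), K = 1/2 LL'
      out[[nm]] <- c(e = e, sd = sqrt(v))
    }
  }
  out
}

#' Null mean and variance of a weighted joint score statistic
#'
#' For weights `(a_beta, a_phi, a_gamma, a_delta)` the joint statistic is a
#' single quadratic form in the residuals with low-rank kernel; its null
#' moments are `E = tr(P0 K)` and `Var = 2 tr(P0 K P0 K)` with `P0` the
#' precision projected off the null fixed design. Cross-component
#' covariances are included automatically since the moments are computed on
#' the combined kernel.
#'
#' @param fit a [fit_null()] result.
#' @param sc an [efficient_scores()] result.
#' @param weights numeric vector, one weight per available component in the
#'   order beta, phi, gamma, delta (length 2 for a methylation-free fit).
#' @return named vector `c(e_null = , var_null = )`.
#' @export
null_moments <- function(fit, sc, weights) {
  stopifnot(inherits(sc, "meqtl_scores"))
  w <- .expand_weights(sc, weights)
  A <- w * sc$S                       # W S with W = diag(w)
  e <- sum(w * diag(sc$S))
  v <- 2 * sum(A * t(A))              # 2 tr(WSWS)
  c(e_null = e, var_null = v)
}

.expand_weights <- function(sc, weights) {
  if (length(weights) != length(sc$components))
    stop("need one weight per component: ", paste(sc$components, collapse = ", "))
  w <- numeric(nrow(sc$S))
  for (i in seq_along(sc$components)) {
    nm <- sc$components[i]
    ii <- sc$idx[[nm]]
    # quadratic components carry kernel 1/2 LL', so the diagonal weight is a/2
    w[ii] <- if (length(ii) == 1L) weights[i] else weights[i] / 2
  }
  w
}

#' Variance-standardizing component weights
#'
#' Each component statistic is scaled by the reciprocal of its null standard
#' deviation (`U_beta^2` and `U_phi^2` for the linear scores, `U_gamma` and
#' `U_delta` for the quadratic ones), putting the four pieces on a common
#' scale before they are summed. Components whose null standard deviation is
#' numerically zero (e.g. a monomorphic genotype annihilating the centered
#' additive contrast) receive weight zero.
#'
#' @param sc an [efficient_scores()] result.
#' @return numeric weight vector matching `sc$components`.
#' @export
default_weights <- function(sc) {
  cm <- .component_moments(sc$S, sc$idx)
  vapply(sc$components, function(nm) {
    s <- cm[[nm]]["sd"]
    if (!is.finite(s) || s < 1e-12) 0 else 1 / s
  }, numeric(1), USE.NAMES = TRUE)
}

.satterthwaite_p <- function(stat, e, v) {
  stat <- unname(stat); e <- unname(e); v <- unname(v)
  if (!is.finite(e) || !is.finite(v) || e <= 0 || v <= 0 || v < 1e-12 * e^2)
    return(list(kappa = NA_real_, nu = NA_real_, p = 1, degenerate = TRUE))
  kappa <- v / (2 * e)
  nu <- 2 * e^2 / v
  list(kappa = kappa, nu = nu,
       p = stats::pchisq(stat / kappa, df = nu, lower.tail = FALSE),
       degenerate = FALSE)
}

# marginal Satterthwaite/chi-square p-value for each component
.component_pvals <- function(sc) {
  cm <- .component_moments(sc$S, sc$idx)
  stats <- c(beta = unname(sc$u_beta)^2, phi = unname(sc$u_phi)^2,
             gamma = unname(sc$u_gamma), delta = unname(sc$u_delta))
  out <- vapply(sc$components, function(nm) {
    e <- cm[[nm]]["e"]; s <- cm[[nm]]["sd"]
    if (!is.finite(e) || e < 1e-12) return(1)
    if (length(sc$idx[[nm]]) == 1L)
      return(stats::pchisq(stats[nm] / e, df = 1, lower.tail = FALSE))
    .satterthwaite_p(stats[nm], e, s^2)$p
  }, numeric(1))
  names(out) <- sc$components
  out
}

#' Joint score test combining all four effect components
#'
#' Assembles the weighted statistic
#' `U = a_beta U_beta^2 + a_phi U_phi^2 + a_gamma U_gamma + a_delta U_delta`
#' (a single quadratic form in the residuals), computes its null mean and
#' variance by the projected-precision trace formulas, and approximates the
#' mixture-of-chi-square null distribution by a scaled chi-square
#' `kappa * chisq(nu)` with `kappa = Var/(2E)` and `nu = 2E^2/Var`
#' (Satterthwaite moment matching).
#'
#' @param fit a [fit_null()] result.
#' @param sc an [efficient_scores()] result for the same fit/genotype.
#' @param weights optional component weights; defaults to
#'   [default_weights()].
#' @return object of class `meqtl_test`: `u_zeta`, `weights`, `e_null`,
#'   `var_null`, `kappa`, `nu`, `p_value`, `degenerate`, the component
#'   `scores`, and marginal `component_p` values.
#' @export
combine_and_test <- function(fit, sc, weights = NULL) {
  stopifnot(inherits(fit, "meqtl_null_fit"), inherits(sc, "meqtl_scores"))
  if (is.null(weights)) weights <- default_weights(sc)
  stats_vec <- c(beta = unname(sc$u_beta)^2, phi = unname(sc$u_phi)^2,
                 gamma = unname(sc$u_gamma), delta = unname(sc$u_delta))
  u_zeta <- sum(weights * stats_vec[sc$components])
  mom <- null_moments(fit, sc, weights)
  sat <- .satterthwaite_p(u_zeta, mom["e_null"], mom["var_null"])
  degenerate <- sc$degenerate || sat$degenerate || all(weights == 0)
  structure(list(u_zeta = unname(u_zeta), weights = weights,
                 e_null = unname(mom["e_null"]), var_null = unname(mom["var_null"]),
                 kappa = sat$kappa, nu = sat$nu,
                 p_value = if (degenerate) 1 else unname(sat$p),
                 degenerate = degenerate,
                 scores = sc[c("u_beta", "u_phi", "u_gamma", "u_delta")],
                 component_p = .component_pvals(sc)),
            class = "meqtl_test")
}

#' @export
print.meqtl_test <- function(x, ...) {
  cat("Joint score test: U =", signif(x$u_zeta, 5),
      " kappa =", signif(x$kappa, 4), " nu =", signif(x$nu, 4),
      " p =", format.pval(x$p_value, digits = 4), "\n")
  if (x$degenerate) cat("  (degenerate statistic; p set to 1)\n")
  invisible(x)
}

#' One-call joint score test for a transcript-CpG-SNP triplet
#'
#' Fits the null model (or reuses a supplied fit — the nuisance parameters
#' depend only on the expression/methylation pair, so one fit serves every
#' cis-SNP of that pair), computes the efficient scores, and returns the
#' Satterthwaite-approximated joint test.
#'
#' @param y n x t expression matrix.
#' @param m n x t methylation matrix.
#' @param g genotype vector of length n.
#' @param fit optional pre-computed [fit_null()] result for (y, m).
#' @return a `meqtl_test` object (see [combine_and_test()]).
#' @export
joint_score_test <- function(y, m, g, fit = NULL) {
  if (is.null(fit)) fit <- fit_null(y, m)
  sc <- efficient_scores(fit, g)
  combine_and_test(fit, sc)
}

#' Genotype + genotype-by-tissue joint score test (no methylation terms)
#'
#' The multi-tissue comparator that models an overall expression shift due
#' to genotype together with its tissue-specific interaction, ignoring
#' methylation: the null is `Y = J alpha + A u + xi` and the statistic
#' combines `a_beta U_beta^2 + a_gamma U_gamma` with the same
#' Satterthwaite machinery as the full joint test.
#'
#' @param fit_nometh a [fit_null()] result fitted with `m = NULL`.
#' @param g genotype vector of length n.
#' @return a `meqtl_test` object.
#' @export
jaguar_style_test <- function(fit_nometh, g) {
  stopifnot(inherits(fit_nometh, "meqtl_null_fit"))
  if (fit_nometh$has_meth)
    stop("fit_nometh must be a methylation-free null fit (fit_null(y, m = NULL))")
  sc <- efficient_scores(fit_nometh, g)
  combine_and_test(fit_nometh, sc)
}
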