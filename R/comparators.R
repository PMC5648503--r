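# fast per-tissue OLS helpers; p-values cross-checked against lm()/anova()
# in the test suite

.ols_fstat_p <- function(X0, X1, y) {
  # F-test of the extra columns of X1 over nested X0
  n <- length(y)
  f1 <- stats::.lm.fit(X1, y)
  r1 <- sum(f1$residuals^2)
  df1 <- n - qr(X1)$rank
  f0 <- stats::.lm.fit(X0, y)
  r0 <- sum(f0$residuals^2)
  df_num <- qr(X1)$rank - qr(X0)$rank
  if (df_num < 1L || df1 < 1L) return(1)
  if (r1 < .Machine$double.eps * r0) {           # saturated fit
    if (r0 <= r1 * (1 + 1e-12)) return(1)
    return(0)
  }
  Fs <- ((r0 - r1) / df_num) / (r1 / df1)
  stats::pf(Fs, df_num, df1, lower.tail = FALSE)
}

.tbt_result <- function(per_tissue_p) {
  per_tissue_p <- pmin(pmax(per_tissue_p, 0), 1)
  structure(list(per_tissue_p = per_tissue_p,
                 min_p = min(per_tissue_p),
                 n_tissues = length(per_tissue_p)),
            class = "tbt_result")
}

#' @export
print.tbt_result <- function(x, ...) {
  cat("Tissue-by-tissue test over", x$n_tissues, "tissues; min p =",
      format.pval(x$min_p, digits = 4), "\n")
  invisible(x)
}

#' Is a tissue-by-tissue result significant at a Bonferroni-adjusted level?
#'
#' Declares significance when the minimum per-tissue p-value falls at or
#' below `level / t`, the Bonferroni threshold over the `t` tissues.
#'
#' @param x a [tbt_eqtl()] or [tbtm_eqtl()] result.
#' @param level nominal family-wise level (default 0.05).
#' @return logical.
#' @export
tbt_significant <- function(x, level = 0.05) {
  stopifnot(inherits(x, "tbt_result"))
  x$min_p <= level / x$n_tissues
}

#' Tissue-by-tissue eQTL regression (genotype only)
#'
#' Fits `y = b0 + b1 g + e` by ordinary least squares separately in each
#' tissue and records the two-sided t-test p-value for the genotype slope.
#' The summary statistic is the minimum p-value across tissues, judged
#' against the Bonferroni threshold `level / t`.
#'
#' @param y n x t expression matrix.
#' @param g genotype vector of length n.
#' @return object of class `tbt_result` with `per_tissue_p`, `min_p`.
#' @export
tbt_eqtl <- function(y, g) {
  y <- as.matrix(y)
  n <- nrow(y)
  g <- as.numeric(g)
  if (length(g) != n) stop("g must have length nrow(y)")
  if (stats::sd(g) == 0) return(.tbt_result(rep(1, ncol(y))))
  gc <- g - mean(g)
  sg2 <- sum(gc^2)
  p <- vapply(seq_len(ncol(y)), function(j) {
    yj <- y[, j]
    b1 <- sum(gc * yj) / sg2
    res <- yj - mean(yj) - b1 * gc
    df <- n - 2L
    s2 <- sum(res^2) / df
    if (s2 < .Machine$double.eps * stats::var(yj)) return(0)
    tstat <- b1 / sqrt(s2 / sg2)
    2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }, numeric(1))
  .tbt_result(p)
}

#' Tissue-by-tissue eQTL regression with methylation covariate
#'
#' Fits, separately in each tissue, the regression of expression on
#' methylation, genotype, and their interaction
#' (`y = a0 + a1 m + b g + phi g*m + e`) and tests the joint null
#' `(b, phi) = 0` with a 2-df F-test against the methylation-only model.
#' The summary statistic is the minimum p-value across tissues.
#'
#' @param y n x t expression matrix.
#' @param g genotype vector of length n.
#' @param m n x t methylation matrix.
#' @return object of class `tbt_result`.
#' @export
tbtm_eqtl <- function(y, g, m) {
  y <- as.matrix(y)
  m <- as.matrix(m)
  n <- nrow(y)
  g <- as.numeric(g)
  if (length(g) != n) stop("g must have length nrow(y)")
  if (!all(dim(m) == dim(y))) stop("m must match dim(y)")
  if (stats::sd(g) == 0) return(.tbt_result(rep(1, ncol(y))))
  ones <- rep(1, n)
  p <- vapply(seq_len(ncol(y)), function(j) {
    X0 <- cbind(ones, m[, j])
    X1 <- cbind(X0, g, g * m[, j])
    if (qr(X1)$rank < 4L) {
      warning("rank-deficient design in tissue ", j, "; p set to 1")
      return(1)
    }
    .ols_fstat_p(X0, X1, y[, j])
  }, numeric(1))
  .tbt_result(p)
}
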