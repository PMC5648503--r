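#' Estimate the null proportion pi0 from a p-value set
#'
#' Storey-style estimate: for a grid of tuning values lambda,
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` is smoothed with a cubic
#' smoothing spline and evaluated at the largest lambda. Falls back to 1
#' (pure Benjamini-Hochberg behavior) when the smoothed estimate leaves
#' (0, 1] or too few p-values are available.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda tuning grid (default 0.05, 0.10, ..., 0.95).
#' @return scalar pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0) return(1)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (length(p) < 100) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  pi0
}

#' Storey q-values for FDR control
#'
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`, clipped to
#' [0, 1]. With `pi0 = 1` this reduces exactly to Benjamini-Hochberg
#' adjusted p-values; by default pi0 is estimated with [estimate_pi0()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0 null proportion; `NULL` (default) to estimate it from `p`.
#' @return numeric vector of q-values, monotone in `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(pi0 * m / (m:1) * p[o]))[ro]
}

#' Monte Carlo type-I error and power study
#'
#' For each grid row, simulates `n_reps` datasets from the generative model
#' and records each requested method's rejection rate. Fixed effects
#' `beta`/`phi` are set to `effect_size` when the row switches them on, and
#' the tissue-interaction variances are derived from the PVE columns via
#' [pve_to_variances()] at the harness's nuisance convention
#' (`tau = eps = 1`, `theta = lam = 0` by default: methylation influences
#' expression only through the effects under test, which keeps the
#' tissue-by-tissue comparators calibrated at the null). The joint and
#' genotype+G-by-T tests reject at `p <= level`; the tissue-by-tissue
#' methods reject at `min p <= level / t` (Bonferroni). Replicate r uses
#' seed `base_seed + r - 1` in every cell, so comparisons across cells and
#' methods are paired.
#'
#' @param grid data.frame with logical columns `additive`, `gxm` and numeric
#'   columns `pve_gxt`, `pve_gxmxt` (percent).
#' @param n,t,maf simulation dimensions and minor allele frequency.
#' @param n_reps Monte Carlo replicates per cell.
#' @param base_seed integer; replicate r is seeded `base_seed + r - 1`.
#' @param methods subset of `"joint"`, `"jaguar"`, `"tbt"`, `"tbtm"`.
#' @param level nominal significance level.
#' @param effect_size magnitude used for `beta` and `phi` when switched on.
#' @param tau,theta,eps nuisance variance components of the generator.
#' @param lam overall methylation fixed effect present in every cell.
#' @return data.frame: one row per grid cell x method with
#'   `rejection_rate`, `n_reps`, `mc_se` (binomial standard error), and
#'   `n_failed` (replicates whose fit failed; excluded from the rate).
#' @export
run_power_study <- function(grid, n = 500L, t = 5L, maf = 0.3,
                            n_reps = 1000L, base_seed = 1L,
                            methods = c("joint", "tbtm"),
                            level = 0.05, effect_size = 0.3,
                            tau = 1, theta = 0, eps = 1, lam = 0) {
  methods <- match.arg(methods, c("joint", "jaguar", "tbt", "tbtm"),
                       several.ok = TRUE)
  grid <- as.data.frame(grid)
  needed <- c("additive", "gxm", "pve_gxt", "pve_gxmxt")
  if (!all(needed %in% names(grid)))
    stop("grid must have columns: ", paste(needed, collapse = ", "))
  out <- list()
  for (ci in seq_len(nrow(grid))) {
    row <- grid[ci, ]
    vc <- pve_to_variances(row$pve_gxt, row$pve_gxmxt,
                           tau = tau, theta = theta, eps = eps)
    p <- sim_params(n_subjects = n, n_tissues = t, maf = maf,
                    beta = if (row$additive) effect_size else 0,
                    phi = if (row$gxm) effect_size else 0,
                    lam = lam, tau = tau, theta = theta, eps = eps,
                    gamma = vc["gamma"], delta = vc["delta"])
    rej <- matrix(NA, n_reps, length(methods),
                  dimnames = list(NULL, methods))
    n_failed <- 0L
    for (r in seq_len(n_reps)) {
      dat <- sim_dataset(p, seed = base_seed + r - 1L)
      ok <- tryCatch({
        fit <- if (any(methods %in% "joint")) fit_null(dat$y, dat$m) else NULL
        fitn <- if ("jaguar" %in% methods) fit_null(dat$y, m = NULL) else NULL
        for (meth in methods) {
          rej[r, meth] <- switch(meth,
            joint  = combine_and_test(fit, efficient_scores(fit, dat$g))$p_value <= level,
            jaguar = jaguar_style_test(fitn, dat$g)$p_value <= level,
            tbt    = tbt_significant(tbt_eqtl(dat$y, dat$g), level),
            tbtm   = tbt_significant(tbtm_eqtl(dat$y, dat$g, dat$m), level))
        }
        TRUE
      }, error = function(e) FALSE)
      if (!ok) n_failed <- n_failed + 1L
    }
    if (n_failed > 0.01 * n_reps)
      warning("cell ", ci, ": ", n_failed, " of ", n_reps,
              " replicates failed to fit")
    for (meth in methods) {
      r_ok <- rej[, meth][!is.na(rej[, meth])]
      rate <- mean(r_ok)
      out[[length(out) + 1L]] <- data.frame(
        additive = row$additive, gxm = row$gxm,
        pve_gxt = row$pve_gxt, pve_gxmxt = row$pve_gxmxt,
        method = meth, rejection_rate = rate,
        n_reps = length(r_ok),
        mc_se = sqrt(rate * (1 - rate) / length(r_ok)),
        n_failed = n_failed)
    }
  }
  do.call(rbind, out)
}
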