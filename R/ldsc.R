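#' Univariate LD-score regression (SNP heritability and intercept)
#'
#' Weighted least-squares regression of per-SNP chi-square statistics on LD
#' scores. Under a polygenic model `E[chi2_j] = intercept + N_j * h2 * l_j / M`;
#' the slope of chi-square on `l_j`, rescaled by `M / mean(N)`, estimates the
#' observed-scale SNP heritability, and the intercept captures confounding
#' and overlap-free inflation. Regression weights
#' `1 / (2 * (1 + N * h2 * l / M)^2 * l)` are iterated twice from an initial
#' unweighted fit. Standard errors come from a delete-a-block jackknife over
#' position-contiguous blocks.
#'
#' @param data A data frame with columns `snp_id`, `n`, and either `chi2` or
#'   `z` (squared internally). A `ddx_differential` table is accepted
#'   directly (its `z` and pass-through sample sizes are used).
#' @param ld A `ddx_ldscores` table, or `NULL` for flat (LD-free) mode, the
#'   setting for panels of independent SNPs. With constant LD scores the
#'   intercept and slope are collinear, so flat-mode fits fix the intercept
#'   at 1 and the regression solves to
#'   `h2_obs = (mean(chi2) - 1) * M / mean(N)` exactly.
#' @param n_blocks Number of jackknife blocks; default 200, reduced to
#'   `max(2, n_snp / 10)` for panels under 2000 SNPs.
#' @param chi2_max Statistics above this are excluded before fitting
#'   (default `max(80, 0.001 * mean(N))`, the usual convention; use `Inf` to
#'   disable, e.g. in simulations with strong single-SNP effects).
#' @return An object of class `ldsc_h2_fit`: a list with `h2_obs`,
#'   `intercept`, `se_h2`, `se_intercept`, `n_blocks`, `n_snp`, `M`,
#'   `mean_n`, `flat`. A negative fitted slope is reported as-is with a
#'   warning, never truncated. Supports [tidy()] and [glance()].
#' @export
ldsc_h2 <- function(data, ld = NULL, n_blocks = NULL, chi2_max = NULL) {
  d <- prepare_ldsc_data(data, ld, chi2_max)
  n_blocks <- default_blocks(nrow(d), n_blocks)
  M <- d$M[1]

  flat <- sd(d$l2) < 1e-12
  fit <- ldsc_wls(d$chi2, d$l2, w = NULL, fix_intercept = if (flat) 1 else NULL)
  for (i in 1:2) {
    h2_cur <- fit$slope * M / mean(d$n)
    w <- ldsc_weights(d$l2, d$n, h2_cur, M)
    fit <- ldsc_wls(d$chi2, d$l2, w = w, fix_intercept = if (flat) 1 else NULL)
  }
  h2 <- fit$slope * M / mean(d$n)
  if (h2 < 0) warn(sprintf("ldsc_h2: negative heritability estimate (%.4g) reported as-is", h2))

  jk <- jackknife_wls(d$chi2, d$l2, w, n_blocks,
                      fix_intercept = if (flat) 1 else NULL,
                      transform = function(f) c(h2 = f$slope * M / mean(d$n),
                                                intercept = f$intercept))
  structure(list(
    h2_obs = h2, intercept = fit$intercept,
    se_h2 = jk["h2"], se_intercept = if (flat) 0 else jk["intercept"],
    n_blocks = n_blocks, n_snp = nrow(d), M = M, mean_n = mean(d$n),
    flat = flat
  ), class = "ldsc_h2_fit")
}

#' Cross-trait LD-score regression (intercept, genetic covariance, rg)
#'
#' Weighted regression of the per-SNP z-score products of two harmonized
#' studies on LD scores. The slope, rescaled by `M / sqrt(mean(N1) * mean(N2))`,
#' estimates the genetic covariance; the intercept estimates the correlation
#' of the two studies' estimation errors (sample overlap times phenotypic
#' correlation) and is the `r_int` consumed by [run_differential()]. The
#' genetic correlation is `rg = gencov / sqrt(h2_1 * h2_2)` with the
#' univariate heritabilities fitted on the same SNPs; `|rg|` may exceed 1
#' numerically and is reported as-is.
#'
#' @param data A `ddx_harmonized` pair (z-scores are `beta_t?/se_t?` and
#'   sample sizes `n_total_t?`), or a data frame with columns `snp_id`,
#'   `z1`, `z2`, `n1`, `n2`.
#' @inheritParams ldsc_h2
#' @return An object of class `ldsc_rg_fit`: a list with `intercept_xt`,
#'   `gencov`, `rg`, jackknife SEs, the two univariate fits, `n_blocks`,
#'   `n_snp`, `flat`. In flat (constant-LD) mode slope and intercept are
#'   collinear: the fit reports the weighted mean of `z1 * z2` as
#'   `intercept_xt` (any genetic covariance is absorbed into it, so `gencov`
#'   and `rg` are `NA`) — appropriate for differential-null simulated panels.
#'   Supports [tidy()] and [glance()].
#' @export
ldsc_rg <- function(data, ld = NULL, n_blocks = NULL, chi2_max = NULL) {
  if (all(c("beta_t1", "se_t1", "beta_t2", "se_t2") %in% names(data))) {
    d0 <- tibble(snp_id = data$snp_id,
                 z1 = data$beta_t1 / data$se_t1, z2 = data$beta_t2 / data$se_t2,
                 n1 = data$n_total_t1 %||% NA_real_,
                 n2 = data$n_total_t2 %||% NA_real_)
  } else {
    need <- c("snp_id", "z1", "z2", "n1", "n2")
    if (!all(need %in% names(data))) {
      abort("ldsc_rg: need a harmonized pair or columns snp_id, z1, z2, n1, n2")
    }
    d0 <- as_tibble(data[, need])
  }
  if (anyNA(d0$n1) || anyNA(d0$n2)) abort("ldsc_rg: missing sample sizes")
  d <- join_ld(d0, ld)
  lim <- chi2_max %||% max(80, 0.001 * mean(c(d$n1, d$n2)))
  d <- d[pmax(d$z1^2, d$z2^2) <= lim, , drop = FALSE]
  if (nrow(d) < 3) abort("ldsc_rg: too few SNPs after filtering")
  n_blocks <- default_blocks(nrow(d), n_blocks)
  M <- d$M[1]
  nbar <- sqrt(mean(d$n1) * mean(d$n2))

  h2_1 <- ldsc_h2(tibble(snp_id = d$snp_id, chi2 = d$z1^2, n = d$n1),
                  ld = ld, n_blocks = n_blocks, chi2_max = lim)
  h2_2 <- ldsc_h2(tibble(snp_id = d$snp_id, chi2 = d$z2^2, n = d$n2),
                  ld = ld, n_blocks = n_blocks, chi2_max = lim)

  y <- d$z1 * d$z2
  flat <- sd(d$l2) < 1e-12
  if (flat) {
    w <- rep(1, nrow(d))
    est <- function(yy, ww) list(intercept = weighted.mean(yy, ww), slope = 0)
    fit <- est(y, w)
    jk <- jackknife_blocks(seq_len(nrow(d)), n_blocks, function(keep) {
      f <- est(y[keep], w[keep]); c(intercept = f$intercept, gencov = NA_real_)
    })
    gencov <- NA_real_
    rg <- NA_real_
    se_gencov <- NA_real_
    inform("ldsc_rg: constant LD scores; genetic covariance is absorbed into the intercept (gencov/rg undefined)")
  } else {
    fit <- ldsc_wls(y, d$l2, w = NULL)
    for (i in 1:2) {
      gencov_cur <- fit$slope * M / nbar
      w <- rg_weights(d$l2, d$n1, d$n2, h2_1$h2_obs, h2_2$h2_obs,
                      gencov_cur, fit$intercept, M)
      fit <- ldsc_wls(y, d$l2, w = w)
    }
    gencov <- fit$slope * M / nbar
    jk <- jackknife_wls(y, d$l2, w, n_blocks,
                        transform = function(f) c(intercept = f$intercept,
                                                  gencov = f$slope * M / nbar))
    se_gencov <- jk["gencov"]
    rg <- if (h2_1$h2_obs > 0 && h2_2$h2_obs > 0) {
      gencov / sqrt(h2_1$h2_obs * h2_2$h2_obs)
    } else {
      warn("ldsc_rg: non-positive univariate heritability; rg reported as NA")
      NA_real_
    }
  }
  se_rg <- if (!is.na(rg) && !is.na(se_gencov)) {
    abs(rg) * abs(se_gencov / gencov)
  } else NA_real_

  structure(list(
    intercept_xt = unname(fit$intercept), gencov = unname(gencov), rg = unname(rg),
    se_intercept = unname(jk["intercept"]), se_gencov = unname(se_gencov),
    se_rg = unname(se_rg),
    h2_1 = h2_1, h2_2 = h2_2,
    n_blocks = n_blocks, n_snp = nrow(d), M = M, flat = flat
  ), class = "ldsc_rg_fit")
}

#' Observed- to liability-scale heritability conversion
#'
#' `h2_liab = h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(t)^2)` with
#' `t = qnorm(1 - K)`: the standard transformation from the 0/1 observed
#' scale of an ascertained case-control study (case fraction `P`) to the
#' liability scale of a disease with population prevalence `K`. For a
#' differential (case-case) trait the natural convention is
#' `K = K_A / (K_A + K_B)` and `P = Ncase / (Ncase + Ncontrol)` of the
#' constructed contrast.
#'
#' @param h2_obs Observed-scale heritability (vectorized).
#' @param K Population prevalence in (0, 1).
#' @param P Sample case fraction in (0, 1).
#' @return Liability-scale heritability.
#' @examples
#' liability_scale(0.1, K = 0.1, P = 0.5) # 0.10519
#' @export
liability_scale <- function(h2_obs, K, P) {
  assert_prob(K, "K"); assert_prob(P, "P")
  t <- qnorm(1 - K)
  h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(t)^2)
}

#' Expected cross-study intercept from shared control samples
#'
#' Correlation of the estimation errors of two case-control GWAS that share
#' `n_shared` control subjects:
#' `r = n_shared * sqrt(p1 * p2 / ((1 - p1) * (1 - p2))) / sqrt(n1 * n2)`,
#' obtained from the covariance of the two per-SNP score statistics over the
#' shared controls. For two studies of equal size with a 50% case fraction
#' this reduces to the overlap rate `n_shared / n`.
#'
#' @param n_shared Number of shared controls.
#' @param n1,n2 Total sample sizes of the two studies.
#' @param p1,p2 Case fractions of the two studies.
#' @return The expected error correlation (the analytic `r_int`).
#' @export
overlap_intercept <- function(n_shared, n1, n2, p1, p2) {
  assert_prob(p1, "p1"); assert_prob(p2, "p2")
  n_shared * sqrt(p1 * p2 / ((1 - p1) * (1 - p2))) / sqrt(n1 * n2)
}

# ---- internals ---------------------------------------------------------

prepare_ldsc_data <- function(data, ld, chi2_max) {
  d <- as_tibble(data)
  if (inherits(data, "ddx_differential")) {
    d <- tibble(snp_id = data$snp_id, chi2 = data$z^2,
                n = attr(data, "n") %||% abort("attach an `n` column to the differential table"))
  }
  if (!"chi2" %in% names(d)) {
    if ("z" %in% names(d)) d$chi2 <- d$z^2 else abort("ldsc_h2: need a `chi2` or `z` column")
  }
  if (!"n" %in% names(d)) abort("ldsc_h2: need an `n` column of per-SNP sample sizes")
  if (any(d$chi2 < 0, na.rm = TRUE)) abort("chi2 must be non-negative")
  d <- d[!is.na(d$chi2) & !is.na(d$n), , drop = FALSE]
  d <- join_ld(d, ld)
  lim <- chi2_max %||% max(80, 0.001 * mean(d$n))
  d <- d[d$chi2 <= lim, , drop = FALSE]
  if (nrow(d) < 10) abort("ldsc_h2: too few SNPs after filtering")
  d
}

join_ld <- function(d, ld) {
  if (is.null(ld)) ld <- flat_ldscores(d$snp_id)
  M <- attr(ld, "M")
  d <- inner_join(d, ld[, c("snp_id", "l2")], by = "snp_id")
  if (nrow(d) == 0) abort("no SNPs shared with the LD-score table")
  d$M <- M
  d
}

default_blocks <- function(n_snp, n_blocks) {
  nb <- n_blocks %||% if (n_snp < 2000) max(2, floor(n_snp / 10)) else 200
  max(2, min(nb, n_snp))
}

ldsc_weights <- function(l2, n, h2, M) {
  l <- pmax(l2, 1)
  het <- pmax(1 + n * pmax(h2, 0) * l / M, 0.05)
  1 / (2 * het^2 * l)
}

rg_weights <- function(l2, n1, n2, h1, h2, gencov, intercept, M) {
  l <- pmax(l2, 1)
  a <- pmax(1 + n1 * pmax(h1, 0) * l / M, 0.05)
  b <- pmax(1 + n2 * pmax(h2, 0) * l / M, 0.05)
  cr <- sqrt(n1 * n2) * gencov * l / M + intercept
  1 / (l * (a * b + cr^2))
}

# closed-form (weighted) simple linear regression y ~ x, optionally with the
# intercept fixed (used when x is constant and the two terms are collinear)
ldsc_wls <- function(y, x, w = NULL, fix_intercept = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  if (!is.null(fix_intercept)) {
    slope <- sum(w * x * (y - fix_intercept)) / sum(w * x^2)
    return(list(intercept = fix_intercept, slope = slope))
  }
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  list(intercept = (sy - slope * sx) / sw, slope = slope)
}

block_ids <- function(n, n_blocks) {
  as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
}

# generic delete-a-block jackknife over position-contiguous blocks
jackknife_blocks <- function(idx, n_blocks, fn) {
  blocks <- block_ids(length(idx), n_blocks)
  est <- vapply(seq_len(n_blocks), function(b) fn(idx[blocks != b]),
                fn(idx))
  if (is.null(dim(est))) est <- matrix(est, nrow = 1, dimnames = list(names(fn(idx))))
  m <- rowMeans(est)
  sqrt((n_blocks - 1) / n_blocks * rowSums((est - m)^2))
}

jackknife_wls <- function(y, x, w, n_blocks, fix_intercept = NULL, transform) {
  jackknife_blocks(seq_along(y), n_blocks, function(keep) {
    transform(ldsc_wls(y[keep], x[keep], w[keep], fix_intercept = fix_intercept))
  })
}

#' @method tidy ldsc_h2_fit
#' @export
tidy.ldsc_h2_fit <- function(x, ...) {
  tibble(term = c("h2_obs", "intercept"),
         estimate = c(x$h2_obs, x$intercept),
         std.error = c(x$se_h2, x$se_intercept))
}

#' @method glance ldsc_h2_fit
#' @export
glance.ldsc_h2_fit <- function(x, ...) {
  tibble(h2_obs = x$h2_obs, intercept = x$intercept, se_h2 = x$se_h2,
         se_intercept = x$se_intercept, n_snp = x$n_snp, n_blocks = x$n_blocks,
         M = x$M, mean_n = x$mean_n, flat = x$flat)
}

#' @method tidy ldsc_rg_fit
#' @export
tidy.ldsc_rg_fit <- function(x, ...) {
  tibble(term = c("intercept_xt", "gencov", "rg"),
         estimate = c(x$intercept_xt, x$gencov, x$rg),
         std.error = c(x$se_intercept, x$se_gencov, x$se_rg))
}

#' @method glance ldsc_rg_fit
#' @export
glance.ldsc_rg_fit <- function(x, ...) {
  tibble(intercept_xt = x$intercept_xt, gencov = x$gencov, rg = x$rg,
         h2_obs_1 = x$h2_1$h2_obs, h2_obs_2 = x$h2_2$h2_obs,
         n_snp = x$n_snp, n_blocks = x$n_blocks, flat = x$flat)
}

#' @export
print.ldsc_h2_fit <- function(x, ...) {
  cat(sprintf("LD-score regression fit (%s mode)\n", if (x$flat) "flat-LD" else "LD"))
  cat(sprintf("  h2 (observed): %.4f (SE %.4f)\n", x$h2_obs, x$se_h2))
  cat(sprintf("  intercept:     %.4f (SE %.4f)\n", x$intercept, x$se_intercept))
  cat(sprintf("  %d SNPs, %d jackknife blocks, M = %g\n", x$n_snp, x$n_blocks, x$M))
  invisible(x)
}

#' @export
print.ldsc_rg_fit <- function(x, ...) {
  cat("Cross-trait LD-score regression fit\n")
  cat(sprintf("  intercept: %.4f (SE %.4f)\n", x$intercept_xt, x$se_intercept))
  cat(sprintf("  gencov:    %.4f  rg: %.4f\n", x$gencov, x$rg))
  invisible(x)
}
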