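#' Empirical-Bayes (Tweedie) shrinkage of z-scores
#'
#' Estimates the marginal density of the observed z-scores by Lindsey's
#' method — histogram counts modeled by a Poisson log-linear regression on a
#' natural-cubic-spline basis — and shrinks each z to its posterior mean via
#' Tweedie's formula with unit sampling variance:
#' `z_post = z + d/dz log f(z)`. Under a pure null the marginal is standard
#' normal, `d/dz log f(z) = -z`, and every score shrinks to about zero.
#'
#' @param data A data frame with a `z` column, or a bare numeric vector of
#'   z-scores. At least 200 values are required for a stable density fit.
#' @param df Degrees of freedom of the spline basis (default 7).
#' @param bins Number of histogram bins on
#'   `[min(z) - 0.1, max(z) + 0.1]` (default 199).
#' @return A tibble of class `tweedie_fit` with columns `z` and `z_post`, in
#'   input order; the density fit (`glm` object), bin width and a fallback
#'   flag are attached as attributes. If the spline fit fails to converge, a
#'   normal-marginal fallback `z_post = z * (s2 - 1) / s2` (with
#'   `s2 = var(z)`, floored at 1) is used with a warning.
#' @examples
#' set.seed(1)
#' fit <- tweedie_shrink(rnorm(5000))
#' mean(abs(fit$z_post)) # close to 0: complete shrinkage under the null
#' @export
tweedie_shrink <- function(data, df = 7, bins = 199) {
  z <- if (is.numeric(data)) data else {
    if (!"z" %in% names(data)) abort("tweedie_shrink: need a `z` column")
    data$z
  }
  if (length(z) < 200) abort("tweedie_shrink: need at least 200 z-scores")
  if (anyNA(z)) abort("tweedie_shrink: z-scores contain NA")

  breaks <- seq(min(z) - 0.1, max(z) + 0.1, length.out = bins + 1)
  width <- breaks[2] - breaks[1]
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  counts <- tabulate(findInterval(z, breaks, all.inside = TRUE), nbins = bins)

  fit <- tryCatch({
    basis <- splines::ns(mids, df = df)
    g <- suppressWarnings(glm(counts ~ basis, family = poisson()))
    if (!g$converged) stop("density fit did not converge")
    g
  }, error = function(e) NULL)

  if (is.null(fit)) {
    warn("tweedie_shrink: spline density fit failed; falling back to a normal marginal")
    s2 <- max(var(z), 1)
    z_post <- z * (s2 - 1) / s2
    return(structure(tibble(z = z, z_post = z_post),
                     fallback = TRUE, df = df, bins = bins,
                     class = c("tweedie_fit", class(tibble()))))
  }

  # d/dz log f(z) from the fitted log-density (central differences);
  # the histogram normalization constant drops out of the derivative
  h <- width / 10
  eta_at <- function(x) {
    predict(fit, newdata = list(basis = predict(splines::ns(mids, df = df), x)),
            type = "link")
  }
  zc <- pmin(pmax(z, mids[1]), mids[bins]) # clamp to the fitted range
  score <- (eta_at(zc + h) - eta_at(zc - h)) / (2 * h)
  structure(tibble(z = z, z_post = z + score),
            density_fit = fit, fallback = FALSE, df = df, bins = bins,
            breaks = breaks,
            class = c("tweedie_fit", class(tibble())))
}

#' The 18 p-value thresholds used for score construction
#'
#' @return Numeric vector `1e-5, 1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.03, 0.05,
#'   0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1`.
#' @export
ddx_thresholds <- function() {
  c(1e-5, 1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.03, 0.05,
    0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
}

#' Greedy LD pruning of a summary-statistics table
#'
#' Sorts SNPs by p-value and keeps each SNP only if no already-kept SNP
#' within `window_kb` of it has squared correlation above `r2_threshold`.
#' With `ld = NULL` the input is declared independent and passed through
#' unchanged.
#'
#' @param data A data frame with `snp_id` and `pval`; `chrom`/`pos` are
#'   required when `ld` is provided.
#' @param ld Pairwise LD: either a long data frame with columns `snp_a`,
#'   `snp_b`, `r2`, or a symmetric matrix with SNP IDs as dimnames, or
#'   `NULL` (pass-through).
#' @param r2_threshold Maximum allowed r-squared between kept SNPs
#'   (default 0.1).
#' @param window_kb Window in kilobases within which the constraint applies
#'   (default 1000).
#' @return The retained rows of `data`, attribute `"pruned"` holding the
#'   dropped SNP IDs.
#' @export
prune_snps <- function(data, ld = NULL, r2_threshold = 0.1, window_kb = 1000) {
  if (is.null(ld)) {
    return(structure(as_tibble(data), pruned = character(0)))
  }
  if (!all(c("chrom", "pos") %in% names(data))) {
    abort("prune_snps: `chrom` and `pos` are required when LD is provided")
  }
  if (is.matrix(ld)) {
    idx <- which(upper.tri(ld), arr.ind = TRUE)
    ld <- tibble(snp_a = rownames(ld)[idx[, 1]], snp_b = colnames(ld)[idx[, 2]],
                 r2 = ld[idx])
  }
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ld))) {
    assign(paste(ld$snp_a[i], ld$snp_b[i]), ld$r2[i], envir = lookup)
    assign(paste(ld$snp_b[i], ld$snp_a[i]), ld$r2[i], envir = lookup)
  }
  r2_of <- function(a, b) {
    v <- mget(paste(a, b), envir = lookup, ifnotfound = 0)
    unlist(v, use.names = FALSE)
  }
  d <- as_tibble(data)
  ord <- order(d$pval)
  kept <- integer(0)
  for (i in ord) {
    near <- kept[d$chrom[kept] == d$chrom[i] &
                   abs(d$pos[kept] - d$pos[i]) <= window_kb * 1000]
    if (length(near) == 0 || all(r2_of(d$snp_id[i], d$snp_id[near]) <= r2_threshold)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  structure(d[kept, , drop = FALSE], pruned = d$snp_id[-kept])
}

#' Forecast polygenic-score discrimination across p-value thresholds
#'
#' For each threshold `t`, selects the (pruned) SNPs with `p <= t`, forecasts
#' the liability variance the score explains from their shrunken z-scores,
#' and maps it to an AUC with the liability-threshold machinery of
#' [max_auc()]. Because the shrunken z is approximately the posterior mean
#' of the true noncentrality, the sum forecasts the discrimination of a
#' score whose weights still carry estimation noise — the quantity realized
#' when the score is applied to an independent cohort — rather than the
#' noiseless maximum.
#'
#' @details The default per-SNP conversion reconstructs each shrunken
#' per-allele log-odds effect `beta_post = z_post * se` and de-ascertains it
#' to the liability scale. A per-allele log-odds effect from a case-control
#' study of a disorder with population prevalence `K0` corresponds to a
#' per-standardized-genotype liability effect `beta_logodds / c(K0)` with
#' `c(K0) = dnorm(qnorm(1 - K0)) / (K0 * (1 - K0))` — the slope is invariant
#' to the study's case fraction because odds ratios are unaffected by
#' outcome-dependent sampling. A differential effect inherits the scales of
#' its two constituent studies, so the squared slope is taken as
#' `c(K_case) * c(K_control)` (exact when the prevalences are equal). The
#' forecast liability variance at threshold `t` is then
#' `sum(beta_post^2 * varx) / (c(K_case) * c(K_control))` with
#' `varx = 2 * eaf * (1 - eaf)` (1 when `eaf` is absent, i.e. effects per
#' standardized genotype).
#'
#' Two mappings from the shrunken effects to an AUC are available. The
#' default `mapping = "casecase"` forecasts the AUC of the score for
#' distinguishing patients of the first disorder from patients of the
#' second — both groups ascertained beyond their own liability thresholds —
#' by the normal discriminant of the score difference between the two
#' patient groups: `AUC_t = pnorm(sqrt(S_t / 2))` with
#' `S_t = sum(beta_post^2 * varx)` over the selected SNPs, the squared
#' per-standardized-genotype group separation. This is the quantity realized
#' when the score is applied to a fresh cohort of patients and is what the
#' simulation validation measures. `mapping = "liability"` instead treats
#' the de-ascertained variance `v_liab = S_t / (c(K_case) * c(K_control))`
#' as the variance explained in the reduced single-liability model of
#' [max_auc()]; it converges to `max_auc(h2)` of the true heritability but
#' understates the separation of two tail-ascertained patient groups.
#'
#' @param data A differential result ([run_differential()] output or a data
#'   frame) with `pval` (or `p_raw`) and either `z` or `beta13`/`se13`
#'   (or `beta`/`se`); per-SNP `se` and, when available, `eaf` feed the
#'   effective-sample-size computation.
#' @param K_case,K_control Lifetime prevalences of the two disorders. Besides
#'   fixing the conditional prevalence `K = K_case / (K_case + K_control)` of
#'   the liability model, they set the de-ascertainment slope used to put
#'   per-allele log-odds effects on the liability scale (see Details).
#' @param shrink Optional precomputed [tweedie_shrink()] fit aligned with
#'   `data`; fitted internally when `NULL`.
#' @param n_eff Optional scalar effective sample size. The default `NULL`
#'   uses the per-SNP conversion described in Details, which requires `se`
#'   (and uses `eaf` when present). When a scalar is given, the simpler
#'   observed-scale forecast `v_obs = sum(z_post^2) / n_eff` is used and
#'   converted with [liability_scale()].
#' @param sample_case_fraction Case fraction `P` of the contrast; defaults to
#'   `n_case / (n_case + n_control)` when those columns are present, else
#'   0.5.
#' @param ld,r2_threshold,window_kb Passed to [prune_snps()] before
#'   selection.
#' @param thresholds P-value thresholds (default [ddx_thresholds()]).
#' @param mapping `"casecase"` (default) or `"liability"`; see Details.
#' @return A tibble of class `ddx_threshold_curve` with one row per
#'   threshold: `threshold`, `n_snp`, `v_obs`, `v_liab`, `auc`. The best
#'   threshold (highest AUC) is attached as attribute `"best"` and surfaced
#'   by [glance()]. Thresholds selecting no SNP record `auc = 0.5`.
#' @export
forecast_auc <- function(data, K_case, K_control, shrink = NULL, n_eff = NULL,
                         sample_case_fraction = NULL, ld = NULL,
                         r2_threshold = 0.1, window_kb = 1000,
                         thresholds = ddx_thresholds(),
                         mapping = c("casecase", "liability")) {
  mapping <- match.arg(mapping)
  d <- as_tibble(data)
  if (!"pval" %in% names(d)) {
    if ("p_raw" %in% names(d)) d$pval <- d$p_raw else abort("forecast_auc: need `pval` or `p_raw`")
  }
  if (!"z" %in% names(d)) {
    if (all(c("beta13", "se13") %in% names(d))) d$z <- d$beta13 / d$se13
    else if (all(c("beta", "se") %in% names(d))) d$z <- d$beta / d$se
    else abort("forecast_auc: need `z` or beta/se columns")
  }
  if (!"se" %in% names(d) && "se13" %in% names(d)) d$se <- d$se13

  d <- prune_snps(d, ld = ld, r2_threshold = r2_threshold, window_kb = window_kb)

  P <- sample_case_fraction %||% {
    if (all(c("n_case", "n_control") %in% names(d)) && !anyNA(d$n_case)) {
      sum(d$n_case[1]) / (d$n_case[1] + d$n_control[1])
    } else 0.5
  }
  assert_prob(P, "sample_case_fraction")
  K <- K_case / (K_case + K_control)

  if (is.null(shrink)) shrink <- tweedie_shrink(d)
  if (nrow(shrink) != nrow(d)) abort("forecast_auc: `shrink` is not aligned with `data`")
  z_post <- shrink$z_post

  # per-SNP squared per-standardized-genotype shrunken effect and its
  # de-ascertained liability-variance contribution
  deasc <- function(K0) dnorm(qnorm(1 - K0)) / (K0 * (1 - K0))
  c2 <- deasc(K_case) * deasc(K_control)
  if (is.null(n_eff)) {
    if (!"se" %in% names(d)) abort("forecast_auc: per-SNP `se` needed (or pass a scalar `n_eff`)")
    varx <- if ("eaf" %in% names(d) && !anyNA(d$eaf)) 2 * d$eaf * (1 - d$eaf) else 1
    sep_contrib <- (z_post * d$se)^2 * varx
  } else {
    sep_contrib <- liability_scale(z_post^2 / n_eff, K, P) * c2
  }
  lee <- liability_scale(1, K, P) # liability units per observed-scale unit

  rows <- purrr::map(thresholds, function(t) {
    sel <- which(d$pval <= t)
    if (length(sel) == 0) {
      return(tibble(threshold = t, n_snp = 0L, v_obs = 0, v_liab = 0, auc = 0.5))
    }
    S <- sum(sep_contrib[sel])
    v_liab <- min(1, S / c2)
    auc <- if (mapping == "casecase") {
      pnorm(sqrt(S / 2))
    } else {
      auc_liability(liability_model(K, v_liab))
    }
    tibble(threshold = t, n_snp = length(sel), v_obs = v_liab / lee,
           v_liab = v_liab, auc = auc)
  })
  out <- bind_rows(rows)
  best <- out[which.max(out$auc), ]
  structure(out, best = best, K = K, P = P,
            class = c("ddx_threshold_curve", class(tibble())))
}

#' @method glance ddx_threshold_curve
#' @export
glance.ddx_threshold_curve <- function(x, ...) {
  b <- attr(x, "best")
  tibble(best_threshold = b$threshold, best_auc = b$auc, best_n_snp = b$n_snp,
         v_obs_best = b$v_obs, v_liab_best = b$v_liab,
         K = attr(x, "K"), P = attr(x, "P"))
}

#' @method tidy tweedie_fit
#' @export
tidy.tweedie_fit <- function(x, ...) as_tibble(x)

#' @method glance tweedie_fit
#' @export
glance.tweedie_fit <- function(x, ...) {
  tibble(n = nrow(x), fallback = attr(x, "fallback"),
         df = attr(x, "df"), bins = attr(x, "bins"),
         mean_sq_z = mean(x$z^2), mean_sq_z_post = mean(x$z_post^2))
}
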