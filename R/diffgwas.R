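#' Per-SNP differential effect between two aligned estimates
#'
#' Computes the case-case (disorder A vs disorder B) log-odds ratio as the
#' difference of the two studies' log-odds effects, with a variance that
#' subtracts twice the covariance induced by sample overlap:
#' `beta13 = b1 - b2`, `se13 = sqrt(se1^2 + se2^2 - 2 * r_int * se1 * se2)`.
#' The covariance term is `r_int * se1 * se2`, with `r_int` the cross-trait
#' LD-score-regression intercept (or an externally supplied correlation of
#' the estimation errors).
#'
#' @param b1,se1 Effect and standard error of trait 1 (the "case" disorder).
#' @param b2,se2 Effect and standard error of trait 2, aligned to the same
#'   effect allele.
#' @param r_int Correlation of the two estimation errors, in (-1, 1).
#' @return A tibble with columns `beta13`, `se13`, `z`, `p_raw`. SNPs whose
#'   corrected variance is numerically non-positive get `NA` statistics and a
#'   warning (`degenerate_variance`).
#' @examples
#' differential_effect(0.10, 0.02, 0.04, 0.02, r_int = 0)
#' @export
differential_effect <- function(b1, se1, b2, se2, r_int = 0) {
  if (!is.numeric(r_int) || length(r_int) != 1 || !is.finite(r_int) || abs(r_int) >= 1) {
    abort("`r_int` must be a single number strictly inside (-1, 1)")
  }
  if (any(se1 <= 0, na.rm = TRUE) || any(se2 <= 0, na.rm = TRUE)) {
    abort("standard errors must be positive")
  }
  beta13 <- b1 - b2
  v <- se1^2 + se2^2 - 2 * r_int * se1 * se2
  bad <- is.finite(v) & v <= 0
  if (any(bad)) {
    warn(sprintf("differential_effect: %d SNP(s) with degenerate_variance set to NA",
                 sum(bad)))
    v[bad] <- NA_real_
  }
  se13 <- sqrt(v)
  z <- beta13 / se13
  tibble(beta13 = beta13, se13 = se13, z = z, p_raw = two_sided_p(z))
}

#' Differential (case-case) GWAS from a harmonized pair
#'
#' Applies [differential_effect()] to every SNP of a harmonized pair and then
#' genomic control to the resulting chi-square statistics. The differential
#' statistics mimic a case-control GWAS in which cases carry disorder 1 and
#' controls carry disorder 2.
#'
#' @param pair A `ddx_harmonized` tibble from [harmonize_pair()].
#' @param r_int Either a number in (-1, 1) (the cross-trait intercept), or an
#'   `ldsc_rg_fit` from [ldsc_rg()] whose `intercept_xt` is used. If both
#'   `r_int` and `ld` are supplied, the user value wins with a warning. The
#'   default `NULL` estimates it from `ld` when available, else uses 0.
#' @param ld Optional `ddx_ldscores` table used (i) to estimate `r_int` when
#'   not supplied and (ii) for `gc = "ldsc"`.
#' @param gc Source of the genomic-control inflation factor: the intercept of
#'   an LD-score regression on the differential chi-squares (`"ldsc"`), the
#'   median chi-square divided by 0.4549 (`"median"`, default), none
#'   (`"none"`), or a user value (`"user"` with `lambda`). Lambda is clamped
#'   at 1 or above; deflation is never applied.
#' @param lambda Inflation factor for `gc = "user"`.
#' @param sig_threshold Significance threshold reported by [glance()]
#'   (default genome-wide 5e-8).
#' @return A tibble of class `ddx_differential`, sorted by (chromosome,
#'   position, SNP ID), with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta13`, `se13`, `z`, `p_raw`,
#'   `chi2_gc`, `p_gc`. The genomic-control report (lambda, its source,
#'   median chi-square before/after) is attached as attribute `"gc_report"`
#'   and surfaced by [glance()].
#' @export
run_differential <- function(pair, r_int = NULL, ld = NULL,
                             gc = c("median", "ldsc", "none", "user"),
                             lambda = NULL, sig_threshold = 5e-8) {
  gc <- match.arg(gc)
  if (nrow(pair) == 0) abort("empty harmonized pair")
  if (inherits(r_int, "ldsc_rg_fit")) r_int <- r_int$intercept_xt
  if (!is.null(r_int) && !is.null(ld)) {
    warn("run_differential: both `r_int` and `ld` given; using the user-supplied `r_int`")
  }
  if (is.null(r_int)) {
    r_int <- if (!is.null(ld)) ldsc_rg(pair, ld = ld)$intercept_xt else 0
  }

  de <- differential_effect(pair$beta_t1, pair$se_t1, pair$beta_t2, pair$se_t2,
                            r_int = r_int)
  res <- bind_cols(
    pair[, intersect(c("snp_id", "chrom", "pos", "effect_allele", "other_allele"),
                     names(pair))],
    de
  )
  if ("eaf_t1" %in% names(pair)) res$eaf <- pair$eaf_t1
  if (all(is.na(res$se13))) abort("all SNPs have degenerate variance")

  chi2 <- res$z^2
  n_eff_cols <- intersect(c("n_case_t1", "n_control_t1", "n_case_t2", "n_control_t2"),
                          names(pair))
  lam <- switch(gc,
    none = 1,
    user = {
      if (is.null(lambda)) abort("gc = \"user\" requires `lambda`")
      lambda
    },
    median = median(chi2, na.rm = TRUE) / qchisq(0.5, df = 1),
    ldsc = {
      if (is.null(ld)) {
        warn("run_differential: gc = \"ldsc\" but no LD scores; falling back to median")
        median(chi2, na.rm = TRUE) / qchisq(0.5, df = 1)
      } else {
        n <- differential_n(pair)
        fit <- ldsc_h2(tibble(snp_id = res$snp_id, chi2 = chi2, n = n), ld = ld)
        fit$intercept
      }
    })
  lam_used <- max(1, lam)
  res$chi2_gc <- chi2 / lam_used
  res$p_gc <- pchisq(res$chi2_gc, df = 1, lower.tail = FALSE)

  res <- res |> arrange(chrom_order(.data$chrom), .data$pos, .data$snp_id)
  gc_report <- list(
    lambda_used = lam_used,
    lambda_raw = lam,
    lambda_source = switch(gc, none = "none", user = "user",
                           median = "median_chi2", ldsc = if (is.null(ld)) "median_chi2" else "ldsc_intercept"),
    median_chi2_before = median(chi2, na.rm = TRUE),
    median_chi2_after = median(res$chi2_gc, na.rm = TRUE),
    r_int = r_int,
    sig_threshold = sig_threshold
  )
  structure(res, gc_report = gc_report,
            class = c("ddx_differential", class(as_tibble(res))))
}

# effective per-SNP sample size of the differential contrast: cases of study 1
# against cases of study 2 (used only for the LDSC lambda fit)
differential_n <- function(pair) {
  if (all(c("n_case_t1", "n_case_t2") %in% names(pair)) &&
      !all(is.na(pair$n_case_t1)) && !all(is.na(pair$n_case_t2))) {
    return(pair$n_case_t1 + pair$n_case_t2)
  }
  if (all(c("n_total_t1", "n_total_t2") %in% names(pair))) {
    return((pair$n_total_t1 + pair$n_total_t2) / 2)
  }
  abort("harmonized pair carries no sample-size columns; cannot run gc = \"ldsc\"")
}

#' Write differential GWAS results as a sumstats-compatible TSV
#'
#' Columns `SNP, CHR, BP, A1, A2, EAF, BETA, SE, Z, P, P_GC`; the file is a
#' valid input for [read_sumstats()] and downstream forecasting.
#'
#' @param x A `ddx_differential` tibble.
#' @param path Output path; written atomically.
#' @return `path`, invisibly.
#' @export
write_differential <- function(x, path) {
  out <- data.frame(
    SNP = x$snp_id, CHR = x$chrom, BP = x$pos,
    A1 = x$effect_allele, A2 = x$other_allele,
    EAF = if ("eaf" %in% names(x)) x$eaf else NA_real_,
    BETA = x$beta13, SE = x$se13, Z = x$z, P = x$p_raw, P_GC = x$p_gc
  )
  write_tsv_atomic(out, path)
  invisible(path)
}

#' @method glance ddx_differential
#' @export
glance.ddx_differential <- function(x, ...) {
  g <- attr(x, "gc_report")
  tibble(
    n_snp = nrow(x),
    lambda_used = g$lambda_used,
    lambda_source = g$lambda_source,
    median_chi2_before = g$median_chi2_before,
    median_chi2_after = g$median_chi2_after,
    r_int = g$r_int,
    n_sig_raw = sum(x$p_raw < g$sig_threshold, na.rm = TRUE),
    n_sig_gc = sum(x$p_gc < g$sig_threshold, na.rm = TRUE)
  )
}

#' @method tidy ddx_differential
#' @export
tidy.ddx_differential <- function(x, ...) {
  as_tibble(x)
}
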