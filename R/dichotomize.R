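#' Convert continuous-trait summary statistics to a case-control scale
#'
#' Maps per-allele effects on a standardized continuous phenotype to the
#' summary statistics of the corresponding case-control study in which
#' subjects in the top `top_fraction` of the outcome are "cases", under a
#' threshold model: with `T = qnorm(1 - q)`,
#' `beta_bin = beta * dnorm(T) / (q * (1 - q))` and
#' `z_bin = z * dnorm(T) / sqrt(q * (1 - q))` (the asymptotic efficiency of
#' dichotomizing at the q-quantile). P-values are recomputed from `z_bin`,
#' and effective case/control counts are `q * N` and `(1 - q) * N`.
#'
#' @param t A summary-statistics tibble whose `beta`/`se` are linear-scale
#'   effects on a standardized continuous trait.
#' @param top_fraction Fraction `q` of subjects labelled cases (default 0.20,
#'   the top-20% convention).
#' @return A `ddx_sumstats` tibble on the binary (log-odds-like) scale.
#' @examples
#' t <- tibble::tibble(snp_id = "rs1", effect_allele = "A", other_allele = "G",
#'                     beta = 0.02, se = 0.005, n_total = 1e5)
#' dichotomize_continuous(t, 0.2)$beta # 0.02 * dnorm(0.8416) / 0.16 = 0.035
#' @export
dichotomize_continuous <- function(t, top_fraction = 0.2) {
  q <- top_fraction
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("`top_fraction` must be a single number in (0, 1)")
  }
  t <- ensure_sumstat_cols(t)
  T_ <- qnorm(1 - q)
  fac_beta <- dnorm(T_) / (q * (1 - q))
  fac_z <- dnorm(T_) / sqrt(q * (1 - q))
  out <- t |>
    mutate(
      beta = .data$beta * fac_beta,
      se = .data$se * fac_beta / fac_z, # = se / sqrt(q (1 - q))
      pval = two_sided_p(.data$beta / .data$se),
      n_case = round(q * .data$n_total),
      n_control = .data$n_total - round(q * .data$n_total)
    )
  new_sumstats(out, drop_log = drop_log(t))
}
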