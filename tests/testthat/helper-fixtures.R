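# shared helpers: small in-memory sumstats tables and empirical AUC

make_sumstats <- function(snp_id, effect_allele, other_allele, beta,
                          se = 0.02, chrom = "1", pos = seq_along(snp_id) * 1000L,
                          pval = NA_real_, n_total = 50000, eaf = NA_real_) {
  tibble::tibble(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = effect_allele, other_allele = other_allele,
    beta = beta, se = se, pval = pval,
    n_total = n_total, n_case = NA_real_, n_control = NA_real_, eaf = eaf
  )
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  ddx::write_sumstats(df, path)
  path
}

# rank-based empirical AUC (probability a case scores above a control)
empirical_auc <- function(score_case, score_ctrl) {
  r <- rank(c(score_case, score_ctrl))
  n1 <- as.numeric(length(score_case))
  n0 <- as.numeric(length(score_ctrl))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# forecast-vs-realized gap for one simulated replicate (used by the
# end-to-end forecasting checks)
forecast_gap_one_rep <- function(cfg, fresh_n = 20000) {
  pop <- simulate_population(cfg)
  st <- build_casecontrol_studies(pop)
  de <- differential_effect(st$study_a$beta, st$study_a$se,
                            st$study_b$beta, st$study_b$se,
                            r_int = st$overlap$r_int)
  d <- tibble::tibble(snp_id = st$study_a$snp_id, z = de$z, pval = de$p_raw,
                      se = de$se13, eaf = (st$study_a$eaf + st$study_b$eaf) / 2)
  shr <- tweedie_shrink(d)
  fc <- forecast_auc(d, K_case = cfg$K, K_control = cfg$K, shrink = shr)
  g <- glance(fc)
  sel <- d$pval <= g$best_threshold
  w <- (shr$z_post * de$se13)[sel]
  fresh <- simulate_population(cfg, betas = pop$snps, n_override = fresh_n)
  a <- fresh$case_a & !fresh$case_b
  b <- fresh$case_b & !fresh$case_a
  score <- fresh$X[, sel, drop = FALSE] %*% w
  c(forecast = g$best_auc, realized = empirical_auc(score[a], score[b]))
}
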