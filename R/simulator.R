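#' Configuration for the two-disorder case-control simulator
#'
#' Defines a simulated population with two genetically influenced disorders
#' under a liability-threshold model: independent biallelic SNPs with allele
#' frequencies drawn uniformly from `maf_range`, per-trait liability-scale
#' SNP heritabilities `h2_A`/`h2_B` spread over the causal SNPs, disease
#' prevalence `K` for both disorders, and two overlapping case-control
#' studies sampled from the population.
#'
#' SNPs fall into four classes (`shared_equal` SNPs carry the identical
#' effect on both traits; `A_only`/`B_only` affect one trait; `null` affect
#' neither), so the differential (A-vs-B) effect is null exactly for the
#' `shared_equal` and `null` classes. Effect sizes are drawn
#' `beta_j ~ N(0, h2 / n_causal)` per standardized genotype
#' (`allocation = "random"`, the default) or set to
#' `+/- sqrt(h2 / n_causal)` (`allocation = "equal"`); for trait B the
#' `B_only` SNPs carry the heritability not already contributed by the
#' shared SNPs.
#'
#' @param ncases Expected number of cases of each disorder in the population
#'   (population size is `ncases / K`).
#' @param K Disease prevalence of each disorder (default 0.10).
#' @param n_snp Number of independent SNPs (default 300).
#' @param h2_A,h2_B Liability-scale SNP heritabilities of the two traits
#'   (defaults 0.2 and 0.3).
#' @param overlap_rate Fraction `P` of each study's samples shared with the
#'   other study (shared controls): `n_shared = round(P * 2N)`.
#' @param comorbidity If `FALSE` (default) subjects qualifying for both
#'   disorders are alternately reassigned to exactly one; if `TRUE` they
#'   keep both labels and study cases are drawn ignoring the other label.
#' @param class_fractions Named fractions of the four SNP classes
#'   (`shared_equal`, `A_only`, `B_only`, `null`), summing to 1.
#' @param maf_range Range of the uniform allele-frequency draw.
#' @param allocation `"random"` (default) or `"equal"` per-SNP effect-size
#'   allocation.
#' @param n_reps Default replicate count for [run_validation()].
#' @return A list of class `ddx_sim_config`.
#' @export
sim_config <- function(ncases = 10000, K = 0.1, n_snp = 300,
                       h2_A = 0.2, h2_B = 0.3, overlap_rate = 0.15,
                       comorbidity = FALSE,
                       class_fractions = c(shared_equal = 0.25, A_only = 0.25,
                                           B_only = 0.25, null = 0.25),
                       maf_range = c(0.05, 0.95),
                       allocation = c("random", "equal"), n_reps = 30) {
  allocation <- match.arg(allocation)
  assert_prob(K, "K")
  if (h2_A < 0 || h2_A >= 1 || h2_B < 0 || h2_B >= 1) {
    abort("`h2_A` and `h2_B` must lie in [0, 1)")
  }
  if (overlap_rate < 0 || overlap_rate >= 1) abort("`overlap_rate` must lie in [0, 1)")
  cf <- class_fractions[c("shared_equal", "A_only", "B_only", "null")]
  if (anyNA(cf) || abs(sum(cf) - 1) > 1e-8) {
    abort("`class_fractions` must name shared_equal, A_only, B_only, null and sum to 1")
  }
  counts <- round(cf * n_snp)
  counts["null"] <- n_snp - sum(counts[1:3])
  n_causal_A <- counts[["shared_equal"]] + counts[["A_only"]]
  n_causal_B <- counts[["shared_equal"]] + counts[["B_only"]]
  if (h2_A > 0 && n_causal_A == 0) abort("h2_A > 0 requires causal SNPs for trait A")
  if (h2_B > 0 && n_causal_B == 0) abort("h2_B > 0 requires causal SNPs for trait B")
  shared_h2 <- if (n_causal_A > 0) h2_A * counts[["shared_equal"]] / n_causal_A else 0
  if (h2_B < shared_h2 - 1e-12) {
    abort(sprintf("h2_B (%.3g) is below the %.3g contributed by shared SNPs", h2_B, shared_h2))
  }
  structure(list(
    ncases = ncases, K = K, n_snp = n_snp, h2_A = h2_A, h2_B = h2_B,
    overlap_rate = overlap_rate, comorbidity = comorbidity,
    class_counts = counts, maf_range = maf_range, allocation = allocation,
    n_reps = n_reps
  ), class = "ddx_sim_config")
}

#' Simulate a population with two liability-threshold disorders
#'
#' Draws genotypes `~ Binomial(2, maf_j)` per SNP, builds each trait's
#' liability as the standardized-genotype score plus `N(0, 1 - h2)` noise,
#' and assigns disease status by thresholding at `qnorm(1 - K)`. Without
#' comorbidity, subjects exceeding both thresholds are alternately assigned
#' to exactly one disorder.
#'
#' @param cfg A [sim_config()].
#' @param betas Optional effect table from a previous population (as found
#'   in `$snps`), reused to simulate a fresh cohort with the same genetic
#'   architecture.
#' @param n_override Optional population size overriding `ncases / K` (used
#'   for fresh validation cohorts).
#' @return A list of class `ddx_population`: `X` (raw 0/1/2 dosage matrix),
#'   `snps` (tibble: `snp_id`, `chrom`, `pos`, `maf`, `class`, liability
#'   effects `beta_a`, `beta_b` per standardized genotype), logical disease
#'   vectors `case_a`, `case_b`, and `cfg`.
#' @export
simulate_population <- function(cfg, betas = NULL, n_override = NULL) {
  stopifnot(inherits(cfg, "ddx_sim_config"))
  ntotal <- n_override %||% round(cfg$ncases / cfg$K)
  if (is.null(betas)) {
    maf <- runif(cfg$n_snp, cfg$maf_range[1], cfg$maf_range[2])
    cls <- rep(names(cfg$class_counts), times = cfg$class_counts)
    n_causal_A <- sum(cls %in% c("shared_equal", "A_only"))
    n_b_only <- sum(cls == "B_only")
    draw <- function(n, v) {
      if (v <= 0 || n == 0) return(numeric(n))
      if (cfg$allocation == "random") rnorm(n, 0, sqrt(v))
      else sample(c(-1, 1), n, replace = TRUE) * sqrt(v)
    }
    beta_a <- numeric(cfg$n_snp)
    causal_a <- cls %in% c("shared_equal", "A_only")
    beta_a[causal_a] <- draw(sum(causal_a), cfg$h2_A / n_causal_A)
    shared_h2 <- cfg$h2_A * sum(cls == "shared_equal") / max(n_causal_A, 1)
    beta_b <- ifelse(cls == "shared_equal", beta_a, 0)
    if (n_b_only > 0) {
      beta_b[cls == "B_only"] <- draw(n_b_only, (cfg$h2_B - shared_h2) / n_b_only)
    }
    betas <- tibble(
      snp_id = sprintf("sim%04d", seq_len(cfg$n_snp)),
      chrom = "1", pos = 10000L * seq_len(cfg$n_snp),
      maf = maf, class = cls, beta_a = beta_a, beta_b = beta_b
    )
  }
  maf <- betas$maf
  X <- vapply(maf, function(m) rbinom(ntotal, 2, m), numeric(ntotal))
  sdx <- sqrt(2 * maf * (1 - maf))
  # standardized score folded into the raw dosage product
  g_a <- drop(X %*% (betas$beta_a / sdx)) - sum(2 * maf * betas$beta_a / sdx)
  g_b <- drop(X %*% (betas$beta_b / sdx)) - sum(2 * maf * betas$beta_b / sdx)
  lia_a <- g_a + rnorm(ntotal, 0, sqrt(1 - cfg$h2_A))
  lia_b <- g_b + rnorm(ntotal, 0, sqrt(1 - cfg$h2_B))
  thr <- qnorm(1 - cfg$K)
  case_a <- lia_a > thr
  case_b <- lia_b > thr
  if (!cfg$comorbidity) {
    dual <- which(case_a & case_b)
    if (length(dual) > 0) {
      case_a[dual[seq_along(dual) %% 2 == 0]] <- FALSE
      case_b[dual[seq_along(dual) %% 2 == 1]] <- FALSE
    }
  }
  structure(list(X = X, snps = betas, case_a = case_a, case_b = case_b,
                 cfg = cfg),
            class = "ddx_population")
}

#' Build two overlapping case-control studies and a direct case-case GWAS
#'
#' With `N = max(N_A, N_B)` realized cases, study A takes the `N_A` cases of
#' disorder A plus `2N - N_A` controls and study B its `N_B` cases plus
#' `2N - N_B` controls; the two control sets share exactly
#' `round(P * 2N)` subjects (all controls are free of both disorders).
#' Per-SNP logistic regressions on raw allele counts produce each study's
#' summary statistics. The direct ("real") GWAS contrasts the disorder-A
#' cases against the disorder-B cases and serves as the individual-level
#' benchmark for the inferred differential statistics.
#'
#' @param pop A [simulate_population()] result.
#' @param cfg Its configuration (defaults to `pop$cfg`).
#' @return A list of class `ddx_studies`: sumstats tibbles `study_a`,
#'   `study_b`, `real` (each in [read_sumstats()] layout), and `overlap`, a
#'   list with `n_shared`, study sizes/case fractions, and the analytic
#'   error correlation `r_int` from [overlap_intercept()].
#' @export
build_casecontrol_studies <- function(pop, cfg = pop$cfg) {
  stopifnot(inherits(pop, "ddx_population"))
  idx_a <- which(pop$case_a); idx_b <- which(pop$case_b)
  n_a <- length(idx_a); n_b <- length(idx_b)
  N <- max(n_a, n_b)
  n_shared <- round(cfg$overlap_rate * 2 * N)
  pool <- which(!pop$case_a & !pop$case_b)
  need <- n_shared + (2 * N - n_a - n_shared) + (2 * N - n_b - n_shared)
  if (need > length(pool)) {
    abort(sprintf("requested overlap needs %d controls but only %d disorder-free subjects exist",
                  need, length(pool)))
  }
  picked <- sample(pool, need)
  shared <- picked[seq_len(n_shared)]
  extra_a <- picked[n_shared + seq_len(2 * N - n_a - n_shared)]
  extra_b <- picked[n_shared + (2 * N - n_a - n_shared) + seq_len(2 * N - n_b - n_shared)]

  sumstats_of <- function(case_idx, ctrl_idx) {
    gc <- genotype_counts(pop$X, case_idx, ctrl_idx)
    fit <- logistic_from_counts(gc$case, gc$ctrl)
    n1 <- length(case_idx); n0 <- length(ctrl_idx)
    eaf <- colSums((gc$case + gc$ctrl) * c(0, 1, 2)) / (2 * (n1 + n0))
    tibble(
      snp_id = pop$snps$snp_id, chrom = pop$snps$chrom, pos = pop$snps$pos,
      effect_allele = "A", other_allele = "G",
      beta = fit$beta, se = fit$se, pval = two_sided_p(fit$beta / fit$se),
      n_total = n1 + n0, n_case = n1, n_control = n0, eaf = eaf
    )
  }

  study_a <- sumstats_of(idx_a, c(shared, extra_a))
  study_b <- sumstats_of(idx_b, c(shared, extra_b))
  # direct GWAS of subjects with exactly one disorder (A-only vs B-only)
  real <- sumstats_of(which(pop$case_a & !pop$case_b),
                      which(pop$case_b & !pop$case_a))

  p1 <- n_a / (2 * N); p2 <- n_b / (2 * N)
  overlap <- list(
    n_shared = n_shared, n1 = 2 * N, n2 = 2 * N, p1 = p1, p2 = p2,
    r_int = overlap_intercept(n_shared, 2 * N, 2 * N, p1, p2)
  )
  structure(list(study_a = study_a, study_b = study_b, real = real,
                 overlap = overlap),
            class = "ddx_studies")
}

#' Validate the inferred differential GWAS against the direct case-case GWAS
#'
#' Runs the full validation loop: simulate a population, build the two
#' overlapping case-control studies, form the inferred differential
#' statistics (difference of effects with the overlap-corrected variance),
#' run the direct disorder-A-versus-disorder-B GWAS on the same subjects,
#' and pool the comparison metrics over replicates. Power is computed over
#' SNPs whose true differential effect is nonzero (`A_only`/`B_only`
#' classes) and type-I error over differential-null SNPs (`shared_equal` and
#' `null`), both at `p < alpha` on the uncorrected differential p-values.
#'
#' @param cfg A [sim_config()].
#' @param reps Number of replicates (default `cfg$n_reps`).
#' @param r_int `"analytic"` (default) uses the shared-control formula of
#'   [overlap_intercept()] with the realized study composition — the true
#'   error correlation of the design; a number fixes the correlation (0
#'   omits the overlap correction entirely); `"ldsc"` estimates it per
#'   replicate by flat-LD cross-trait regression, which also absorbs any
#'   genetic covariance of the two studies.
#' @param alpha Significance level for power/type-I error (default 0.05).
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `ddx_sim_metrics`: list with `metrics` (one-row
#'   tibble: `corr_beta`, `corr_se`, `rmse_beta`, `rmse_se`,
#'   `power_inferred`, `t1e_inferred`, `power_real`, `t1e_real`,
#'   `mean_r_int`), `per_rep` metrics, and the configuration. Supports
#'   [tidy()] and [glance()].
#' @export
run_validation <- function(cfg, reps = cfg$n_reps, r_int = "analytic",
                           alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cfg, "ddx_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (reps < 1) abort("`reps` must be at least 1")

  per_rep <- vector("list", reps)
  pooled <- vector("list", reps)
  for (rep in seq_len(reps)) {
    pop <- simulate_population(cfg)
    st <- build_casecontrol_studies(pop, cfg)
    r <- if (identical(r_int, "analytic")) {
      st$overlap$r_int
    } else if (identical(r_int, "ldsc")) {
      ldsc_rg(tibble(snp_id = st$study_a$snp_id,
                     z1 = st$study_a$beta / st$study_a$se,
                     z2 = st$study_b$beta / st$study_b$se,
                     n1 = st$study_a$n_total, n2 = st$study_b$n_total),
              chi2_max = Inf)$intercept_xt
    } else if (is.numeric(r_int)) r_int else abort("invalid `r_int`")

    de <- differential_effect(st$study_a$beta, st$study_a$se,
                              st$study_b$beta, st$study_b$se, r_int = r)
    nonnull <- pop$snps$class %in% c("A_only", "B_only")
    p_real <- st$real$pval
    pooled[[rep]] <- tibble(
      beta13 = de$beta13, se13 = de$se13, p13 = de$p_raw,
      beta_real = st$real$beta, se_real = st$real$se, p_real = p_real,
      nonnull = nonnull, rep = rep
    )
    per_rep[[rep]] <- tibble(
      rep = rep, r_int = r,
      corr_beta = cor(de$beta13, st$real$beta),
      power_inferred = mean(de$p_raw[nonnull] < alpha),
      t1e_inferred = mean(de$p_raw[!nonnull] < alpha),
      power_real = mean(p_real[nonnull] < alpha),
      t1e_real = mean(p_real[!nonnull] < alpha)
    )
  }
  all <- bind_rows(pooled)
  metrics <- tibble(
    corr_beta = cor(all$beta13, all$beta_real),
    corr_se = cor(all$se13, all$se_real),
    rmse_beta = sqrt(mean((all$beta13 - all$beta_real)^2)),
    rmse_se = sqrt(mean((all$se13 - all$se_real)^2)),
    power_inferred = if (any(all$nonnull)) mean(all$p13[all$nonnull] < alpha) else NA_real_,
    t1e_inferred = if (any(!all$nonnull)) mean(all$p13[!all$nonnull] < alpha) else NA_real_,
    power_real = if (any(all$nonnull)) mean(all$p_real[all$nonnull] < alpha) else NA_real_,
    t1e_real = if (any(!all$nonnull)) mean(all$p_real[!all$nonnull] < alpha) else NA_real_,
    mean_r_int = mean(bind_rows(per_rep)$r_int),
    n_draws_null = sum(!all$nonnull),
    n_draws_nonnull = sum(all$nonnull)
  )
  structure(list(metrics = metrics, per_rep = bind_rows(per_rep),
                 cfg = cfg, reps = reps, alpha = alpha),
            class = "ddx_sim_metrics")
}

#' Write a simulated study pair as sumstats fixtures plus a truth table
#'
#' Generates one population, builds the overlapping study pair, and writes
#' `study_a.sumstats.tsv`, `study_b.sumstats.tsv` and `truth.tsv` (per-SNP
#' class, liability-scale effects, allele frequency, and the analytic
#' `r_int`) under `dir` — a download-free end-to-end test input whose files
#' round-trip through [read_sumstats()].
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Optional RNG seed.
#' @return Invisibly, a list with elements `paths` (the three files),
#'   `truth` (the truth tibble) and `overlap` (the overlap report).
#' @export
generate_sumstats_fixture <- function(cfg, dir, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- simulate_population(cfg)
  st <- build_casecontrol_studies(pop, cfg)
  paths <- list(
    study_a = file.path(dir, "study_a.sumstats.tsv"),
    study_b = file.path(dir, "study_b.sumstats.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_sumstats(st$study_a, paths$study_a)
  write_sumstats(st$study_b, paths$study_b)
  truth <- pop$snps |>
    mutate(r_int_true = st$overlap$r_int)
  write_tsv_atomic(as.data.frame(truth), paths$truth)
  invisible(list(paths = paths, truth = truth, overlap = st$overlap))
}

# ---- fast per-SNP logistic regression on 0/1/2 dosages -----------------

# 3 x p genotype count tables for a subject subset split by case status
genotype_counts <- function(X, case_idx, ctrl_idx) {
  count3 <- function(rows) {
    Xs <- X[rows, , drop = FALSE]
    rbind(colSums(Xs == 0), colSums(Xs == 1), colSums(Xs == 2))
  }
  list(case = count3(case_idx), ctrl = count3(ctrl_idx))
}

# exact per-SNP logistic MLE y ~ dosage from 2 x 3 contingency counts,
# vectorized across SNPs (IRLS on the three aggregated design points)
logistic_from_counts <- function(case_counts, ctrl_counts, max_iter = 30, tol = 1e-10) {
  p <- ncol(case_counts)
  ng <- case_counts + ctrl_counts
  xg <- matrix(c(0, 1, 2), 3, p)
  a <- rep(qlogis(colSums(case_counts) / colSums(ng)), each = 3)
  dim(a) <- c(3, p)
  b <- matrix(0, 3, p)
  for (it in seq_len(max_iter)) {
    mu <- plogis(a + b * xg)
    W <- ng * mu * (1 - mu)
    S0 <- colSums(W); S1 <- colSums(W * xg); S2 <- colSums(W * xg * xg)
    resid <- case_counts - ng * mu
    U0 <- colSums(resid); U1 <- colSums(resid * xg)
    det <- S0 * S2 - S1^2
    da <- (S2 * U0 - S1 * U1) / det
    db <- (-S1 * U0 + S0 * U1) / det
    a <- a + rep(da, each = 3)
    b <- b + rep(db, each = 3)
    if (max(abs(db)) < tol) break
  }
  list(beta = b[1, ], se = sqrt(S0 / det), iterations = it)
}

#' @method tidy ddx_sim_metrics
#' @export
tidy.ddx_sim_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @method glance ddx_sim_metrics
#' @export
glance.ddx_sim_metrics <- function(x, ...) {
  bind_cols(x$metrics, tibble(reps = x$reps, ncases = x$cfg$ncases,
                              overlap_rate = x$cfg$overlap_rate,
                              h2_A = x$cfg$h2_A, h2_B = x$cfg$h2_B))
}

#' @export
print.ddx_sim_metrics <- function(x, ...) {
  cat(sprintf("Simulation validation: %d replicates, ncases = %g, overlap = %.2f\n",
              x$reps, x$cfg$ncases, x$cfg$overlap_rate))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}
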