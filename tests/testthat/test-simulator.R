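test_that("simulator configuration validates its inputs", {
  cfg <- sim_config()
  expect_equal(sum(cfg$class_counts), 300)
  expect_error(sim_config(class_fractions = c(shared_equal = 0.5, A_only = 0.5,
                                              B_only = 0.5, null = 0)), "sum to 1")
  # shared SNPs already contribute more than h2_B allows
  expect_error(sim_config(h2_A = 0.4, h2_B = 0.1,
                          class_fractions = c(shared_equal = 0.5, A_only = 0,
                                              B_only = 0.5, null = 0)),
               "shared")
  expect_error(sim_config(K = 1.5), "K")
})

test_that("population size and prevalence follow the configuration", {
  cfg <- sim_config(ncases = 2000, K = 0.1, comorbidity = TRUE)
  set.seed(7501)
  expect_equal(round(2000 / 0.1), 20000)
  hits_a <- hits_b <- 0; n_tot <- 0
  for (r in 1:10) {
    pop <- simulate_population(cfg)
    expect_equal(nrow(pop$X), 20000)
    hits_a <- hits_a + sum(pop$case_a)
    hits_b <- hits_b + sum(pop$case_b)
    n_tot <- n_tot + nrow(pop$X)
  }
  # realized prevalence within 3 binomial SEs of K
  se3 <- 3 * sqrt(0.1 * 0.9 / n_tot)
  expect_lt(abs(hits_a / n_tot - 0.1), se3)
  expect_lt(abs(hits_b / n_tot - 0.1), se3)
})

test_that("a zero-heritability trait is independent of genotype", {
  cfg <- sim_config(ncases = 2000, h2_A = 0, h2_B = 0.3,
                    class_fractions = c(shared_equal = 0, A_only = 0,
                                        B_only = 0.5, null = 0.5))
  set.seed(7502)
  pop <- simulate_population(cfg)
  expect_true(all(pop$snps$beta_a == 0))
  st <- build_casecontrol_studies(pop)
  # study A's GWAS should be null at roughly the nominal rate
  expect_lt(mean(st$study_a$pval < 0.05), 0.12)
})

test_that("study construction yields the stated sizes and shared-control counts", {
  cfg <- sim_config(ncases = 1000, overlap_rate = 0.25)
  set.seed(7503)
  pop <- simulate_population(cfg)
  st <- build_casecontrol_studies(pop)
  N <- max(sum(pop$case_a), sum(pop$case_b))
  expect_equal(st$overlap$n_shared, round(0.25 * 2 * N))
  expect_equal(st$study_a$n_total[1], 2 * N)
  expect_equal(st$study_b$n_total[1], 2 * N)
  expect_equal(st$study_a$n_case[1], sum(pop$case_a))
  # balanced studies: analytic error correlation reduces to the overlap rate
  expect_equal(st$overlap$r_int, st$overlap$n_shared / (2 * N), tolerance = 0.02)

  # zero overlap
  cfg0 <- sim_config(ncases = 1000, overlap_rate = 0)
  st0 <- build_casecontrol_studies(simulate_population(cfg0))
  expect_equal(st0$overlap$n_shared, 0)
  expect_equal(st0$overlap$r_int, 0)
})

test_that("vectorized logistic regression matches glm exactly", {
  set.seed(7504)
  n <- 1500
  X <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.7), rbinom(n, 2, 0.1))
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * X[, 1] - 0.2 * X[, 2]))
  gc <- ddx:::genotype_counts(X, which(y == 1), which(y == 0))
  fit <- ddx:::logistic_from_counts(gc$case, gc$ctrl)
  for (j in 1:3) {
    ref <- glm(y ~ X[, j], family = binomial())
    expect_equal(fit$beta[j], unname(coef(ref)[2]), tolerance = 1e-7)
    expect_equal(fit$se[j], unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-6)
  }
})

test_that("simulation runs are fully deterministic given a seed", {
  cfg <- sim_config(ncases = 500, n_reps = 2)
  m1 <- run_validation(cfg, reps = 2, seed = 7505)
  m2 <- run_validation(cfg, reps = 2, seed = 7505)
  expect_identical(m1$metrics, m2$metrics)

  d1 <- tempfile(); d2 <- tempfile()
  generate_sumstats_fixture(cfg, d1, seed = 99)
  generate_sumstats_fixture(cfg, d2, seed = 99)
  for (f in c("study_a.sumstats.tsv", "study_b.sumstats.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("fixtures round-trip and study effects are unbiased on the log-odds scale", {
  cfg <- sim_config(ncases = 20000)
  dir <- tempfile()
  fx <- generate_sumstats_fixture(cfg, dir, seed = 7506)
  sa <- read_sumstats(file.path(dir, "study_a.sumstats.tsv"))
  sb <- read_sumstats(file.path(dir, "study_b.sumstats.tsv"))
  expect_equal(nrow(sa), 300)
  expect_equal(nrow(drop_log(sa)), 0)
  expect_equal(nrow(drop_log(sb)), 0)

  truth <- fx$truth
  shared <- truth$class == "shared_equal"
  expect_equal(truth$beta_a[shared], truth$beta_b[shared])
  expect_true(all(truth$beta_a[truth$class == "null"] == 0))

  # per-study regression of estimated per-SD log-odds on the de-ascertained
  # truth has slope 1 (liability effect times dnorm(t)/(K(1-K)))
  c0 <- dnorm(qnorm(1 - cfg$K)) / (cfg$K * (1 - cfg$K))
  sdx <- sqrt(2 * truth$maf * (1 - truth$maf))
  for (study in list(list(ss = sa, bl = truth$beta_a),
                     list(ss = sb, bl = truth$beta_b))) {
    est <- study$ss$beta * sdx
    tru <- c0 * study$bl
    slope <- unname(coef(lm(est ~ tru))[2])
    expect_equal(slope, 1, tolerance = 0.05)
  }
})

test_that("comorbidity leaves estimates aligned while trimming differential power", {
  cfg_no <- sim_config(ncases = 10000, n_reps = 4)
  cfg_co <- sim_config(ncases = 10000, n_reps = 4, comorbidity = TRUE)
  m_no <- run_validation(cfg_no, reps = 4, seed = 7507)
  m_co <- run_validation(cfg_co, reps = 4, seed = 7507)
  expect_gt(m_co$metrics$corr_beta, 0.97)
  expect_lt(m_co$metrics$power_inferred, m_no$metrics$power_inferred + 0.02)

  # a noticeable fraction of one disorder's cases also carries the other
  set.seed(7508)
  pop <- simulate_population(cfg_co)
  frac <- sum(pop$case_a & pop$case_b) / sum(pop$case_a)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.35)
})
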