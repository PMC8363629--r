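test_that("read_sumstats converts odds ratios and drops invalid records with reasons", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tCHR\tBP\tA1\tA2\tOR\tSE\tP\tN",
    "rs1\t1\t100\tA\tG\t1.0\t0.02\t1.0\t50000",
    "rs2\t1\t200\tC\tT\t1.105170918\t0.02\t4e-7\t50000",
    "rs3\t1\t300\tA\tG\t1.2\t0\t0.5\t50000",
    "rs4\t1\t400\tA\tN\t1.1\t0.02\t0.5\t50000",
    "rs5\t1\t500\tG\tA\t0.9\t0.03\t4.5e-4\t50000"
  ), f)
  expect_warning(ss <- read_sumstats(f, effect_scale = "oddsratio"), "dropped")
  expect_equal(ss$snp_id, c("rs1", "rs2", "rs5")) # row order preserved
  expect_equal(ss$beta[1], 0)
  expect_equal(ss$beta[2], 0.1, tolerance = 1e-9)
  log <- drop_log(ss)
  expect_equal(log$reason[log$snp_id == "rs3"], "nonpositive_se")
  expect_equal(log$reason[log$snp_id == "rs4"], "bad_allele")
})

test_that("column mapping is explicit-first and missing mandatory columns are fatal", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("marker\tea\toa\teffect_size\tstderr",
               "rs1\tA\tG\t0.05\t0.01"), f)
  ss <- read_sumstats(f, column_map = c(snp_id = "marker", effect_allele = "ea",
                                        other_allele = "oa", beta = "effect_size",
                                        se = "stderr"), n_total = 1000)
  expect_equal(ss$beta, 0.05)
  expect_equal(ss$n_total, 1000)
  expect_error(read_sumstats(f), "mandatory")
  expect_error(read_sumstats(f, column_map = c(snp_id = "nope", effect_allele = "ea",
                                               other_allele = "oa", beta = "effect_size",
                                               se = "stderr")),
               "not present")
})

test_that("zscore effect scale reconstructs beta from z and se", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tZ\tSE\tN",
               "rs1\tA\tG\t2.5\t0.04\t10000"), f)
  ss <- read_sumstats(f, effect_scale = "zscore")
  expect_equal(ss$beta, 0.1)
  expect_equal(ss$se, 0.04)
})

test_that("harmonization aligns swapped and strand-flipped alleles to trait 1", {
  t1 <- make_sumstats(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                      c("A", "A", "A", "A", "C"), c("G", "T", "G", "G", "G"),
                      beta = c(0.10, 0.05, 0.02, 0.03, 0.04))
  t2 <- make_sumstats(c("rs1", "rs2", "rs3", "rs4", "rs6"),
                      c("G", "A", "T", "C", "C"), c("A", "T", "C", "A", "G"),
                      beta = c(-0.10, 0.05, 0.07, 0.01, 0.02))
  pair <- harmonize_pair(t1, t2)

  expect_equal(pair$snp_id, c("rs1", "rs3"))
  # swapped alleles: sign flipped to +0.10
  expect_equal(pair$beta_t2[pair$snp_id == "rs1"], 0.10)
  expect_equal(pair$alignment_action[pair$snp_id == "rs1"], "sign_flipped")
  # strand complement, same orientation: beta unchanged
  expect_equal(pair$beta_t2[pair$snp_id == "rs3"], 0.07)
  expect_equal(pair$alignment_action[pair$snp_id == "rs3"], "strand_flipped")

  log <- drop_log(pair)
  expect_equal(log$reason[log$snp_id == "rs2"], "dropped_palindromic")
  expect_equal(log$reason[log$snp_id == "rs4"], "dropped_mismatch")
  expect_setequal(log$snp_id[log$reason == "dropped_missing"], c("rs5", "rs6"))
  # every input SNP appears exactly once in the pair or the log
  expect_setequal(c(pair$snp_id, log$snp_id), union(t1$snp_id, t2$snp_id))
  expect_equal(length(c(pair$snp_id, log$snp_id)),
               length(union(t1$snp_id, t2$snp_id)))
})

test_that("palindromic keep policy requires informative, same-side frequencies", {
  t1 <- make_sumstats(c("p1", "p2", "p3"), c("A", "A", "C"), c("T", "T", "G"),
                      beta = 0.1, eaf = c(0.2, 0.47, 0.25))
  t2 <- make_sumstats(c("p1", "p2", "p3"), c("A", "A", "C"), c("T", "T", "G"),
                      beta = 0.1, eaf = c(0.22, 0.45, 0.8))
  pair <- harmonize_pair(t1, t2, palindromic_policy = "keep_if_eaf_informative",
                         eaf_window = 0.08)
  expect_equal(pair$snp_id, "p1") # p2 inside window, p3 opposite sides
  expect_setequal(drop_log(pair)$snp_id, c("p2", "p3"))
  # default policy drops all of them
  expect_equal(nrow(harmonize_pair(t1, t2)), 0)
})

test_that("harmonization is idempotent and symmetric under full sign flips", {
  set.seed(7001)
  n <- 60
  alleles <- list(c("A", "G"), c("C", "T"), c("G", "C"), c("T", "G"))
  pick <- sample(4, n, replace = TRUE)
  t1 <- make_sumstats(sprintf("rs%03d", 1:n),
                      vapply(pick, function(i) alleles[[i]][1], ""),
                      vapply(pick, function(i) alleles[[i]][2], ""),
                      beta = rnorm(n, 0, 0.05), eaf = runif(n, 0.1, 0.9))
  # trait 2: randomly swap allele order or complement strand
  swap <- runif(n) < 0.5
  comp <- runif(n) < 0.5
  t2 <- t1
  t2$beta <- t1$beta + rnorm(n, 0, 0.01)
  ea <- t1$effect_allele; oa <- t1$other_allele
  ea[comp] <- chartr("ACGT", "TGCA", ea[comp])
  oa[comp] <- chartr("ACGT", "TGCA", oa[comp])
  t2$effect_allele <- ifelse(swap, oa, ea)
  t2$other_allele <- ifelse(swap, ea, oa)
  t2$beta <- ifelse(swap, -t2$beta, t2$beta)
  t2$eaf <- ifelse(swap, 1 - t1$eaf, t1$eaf)

  pair <- harmonize_pair(t1, t2)
  expect_true(all(pair$alignment_action %in% c("kept", "sign_flipped", "strand_flipped")))

  # idempotence: harmonizing the aligned halves changes nothing
  halves <- split_pair(pair)
  pair2 <- harmonize_pair(halves$t1, halves$t2)
  expect_equal(pair2$beta_t2, pair$beta_t2)
  expect_true(all(pair2$alignment_action == "kept"))

  # sign symmetry: flipping every allele pair and beta sign of input 2
  t2_flip <- t2
  t2_flip$effect_allele <- t2$other_allele
  t2_flip$other_allele <- t2$effect_allele
  t2_flip$beta <- -t2$beta
  t2_flip$eaf <- 1 - t2$eaf
  pair3 <- harmonize_pair(t1, t2_flip)
  expect_equal(pair3$beta_t2, pair$beta_t2, tolerance = 1e-12)
  expect_equal(pair3$eaf_t2, pair$eaf_t2, tolerance = 1e-12)
})

test_that("dichotomization follows the threshold-model factors", {
  t <- make_sumstats("rs1", "A", "G", beta = 0.02, se = 0.005, n_total = 1e5)
  out <- dichotomize_continuous(t, top_fraction = 0.2)
  expect_equal(out$beta, 0.02 * dnorm(qnorm(0.8)) / 0.16, tolerance = 1e-9)
  expect_equal(out$n_case, 2e4)
  expect_equal(out$n_control, 8e4)

  # null maps to null with p = 1
  t0 <- make_sumstats("rs1", "A", "G", beta = 0, se = 0.005, n_total = 1e5)
  out0 <- dichotomize_continuous(t0, 0.2)
  expect_equal(out0$beta, 0)
  expect_equal(out0$pval, 1)

  # q = 0.5 scale factor on beta is dnorm(0)/0.25 = 1.5958
  out5 <- dichotomize_continuous(t, 0.5)
  expect_equal(out5$beta / t$beta, dnorm(0) / 0.25, tolerance = 1e-6)

  # z-ratio invariant across q
  for (q in c(0.1, 0.2, 0.35, 0.5, 0.8)) {
    oq <- dichotomize_continuous(t, q)
    expect_equal((oq$beta / oq$se) / (t$beta / t$se),
                 dnorm(qnorm(1 - q)) / sqrt(q * (1 - q)), tolerance = 1e-9)
  }
  expect_error(dichotomize_continuous(t, 1.2), "top_fraction")
})

test_that("dichotomization matches a logistic regression on a simulated cohort", {
  # oracle: standardized continuous trait with a per-allele effect, cases are
  # the top 20%; the logistic slope should match the threshold-model beta
  set.seed(7002)
  n <- 1e7
  maf <- 0.3
  beta_cont <- 0.02
  x <- rbinom(n, 2, maf)
  y <- beta_cont * x + rnorm(n, 0, sqrt(1 - beta_cont^2 * 2 * maf * (1 - maf)))
  case <- y >= quantile(y, 0.8)
  k <- tapply(case, x, sum)
  m <- tabulate(x + 1, nbins = 3)
  fit <- glm(cbind(k, m - k) ~ c(0, 1, 2), family = binomial())
  oracle_slope <- unname(coef(fit)[2])

  t <- make_sumstats("rs1", "A", "G", beta = beta_cont, se = 0.001, n_total = n)
  beta_bin <- dichotomize_continuous(t, 0.2)$beta
  expect_equal(beta_bin, 0.035, tolerance = 1e-3)
  expect_lt(abs(beta_bin - oracle_slope) / oracle_slope, 0.05)
})
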