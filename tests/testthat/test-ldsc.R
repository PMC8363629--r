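test_that("flat-LD univariate fit solves to the closed form exactly", {
  set.seed(7201)
  chi2 <- rchisq(1500, df = 1) * 1.3
  n <- rep(40000, 1500)
  fit <- ldsc_h2(tibble::tibble(snp_id = paste0("s", 1:1500), chi2 = chi2, n = n),
                 chi2_max = Inf)
  expect_true(fit$flat)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$h2_obs, (mean(chi2) - 1) * 1500 / 40000, tolerance = 1e-12)
  expect_gt(fit$se_h2, 0)
  # glance/tidy surface the same numbers
  expect_equal(glance(fit)$h2_obs, fit$h2_obs)
  expect_equal(tidy(fit)$estimate[1], fit$h2_obs)
})

test_that("free-intercept fit recovers heritability and intercept with calibrated jackknife", {
  set.seed(7202)
  M <- 2000; N <- 50000; h2 <- 0.2
  covered <- logical(30)
  ests <- numeric(30)
  for (r in 1:30) {
    l2 <- runif(M, 1, 50)
    lam <- 1 + N * h2 * l2 / M
    chi2 <- rnorm(M, 0, sqrt(lam))^2
    ldtab <- flat_ldscores(paste0("s", 1:M))
    ldtab$l2 <- l2
    fit <- ldsc_h2(tibble::tibble(snp_id = paste0("s", 1:M), chi2 = chi2, n = N),
                   ld = ldtab, chi2_max = Inf)
    ests[r] <- fit$h2_obs
    covered[r] <- abs(fit$h2_obs - h2) < 1.96 * fit$se_h2
  }
  expect_equal(mean(ests), h2, tolerance = 0.02)
  expect_gte(mean(covered), 0.9)
})

test_that("cross-trait intercept separates overlap from independence", {
  set.seed(7203)
  m <- 3000
  ids <- paste0("s", 1:m)
  # two independent null studies: intercept near 0
  z1 <- rnorm(m); z2 <- rnorm(m)
  # suppressed warnings: null panels legitimately give negative h2 estimates
  f0 <- suppressWarnings(
    ldsc_rg(tibble::tibble(snp_id = ids, z1 = z1, z2 = z2,
                           n1 = 5e4, n2 = 5e4), chi2_max = Inf))
  expect_lt(abs(f0$intercept_xt), 0.06)
  expect_true(f0$flat)

  # byte-identical null studies: z1 z2 = chi2, intercept near 1
  f1 <- suppressWarnings(
    ldsc_rg(tibble::tibble(snp_id = ids, z1 = z1, z2 = z1,
                           n1 = 5e4, n2 = 5e4), chi2_max = Inf))
  expect_equal(f1$intercept_xt, 1, tolerance = 0.06)

  # correlated errors (overlap rho): intercept recovers rho, symmetric in traits
  rho <- 0.25
  z2c <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
  ab <- tibble::tibble(snp_id = ids, z1 = NA, z2 = NA, n1 = 5e4, n2 = 5e4)
  ab$z1 <- z1; ab$z2 <- z2c
  ba <- ab; ba$z1 <- z2c; ba$z2 <- z1
  fab <- suppressWarnings(ldsc_rg(ab, chi2_max = Inf))
  fba <- suppressWarnings(ldsc_rg(ba, chi2_max = Inf))
  expect_equal(fab$intercept_xt, rho, tolerance = 0.06)
  expect_equal(fab$intercept_xt, fba$intercept_xt, tolerance = 1e-12)
})

test_that("cross-trait fit with varying LD scores recovers genetic covariance", {
  set.seed(7204)
  M <- 20000; N <- 20000
  h1 <- 0.3; h2_ <- 0.2; gcov <- 0.15
  l2 <- runif(M, 1, 20)
  x <- l2 / M
  v1 <- 1 + N * h1 * x; v2 <- 1 + N * h2_ * x
  cv <- N * gcov * x # no overlap: intercept 0
  rho <- cv / sqrt(v1 * v2)
  e1 <- rnorm(M); e2 <- rnorm(M)
  z1 <- sqrt(v1) * e1
  z2 <- sqrt(v2) * (rho * e1 + sqrt(1 - rho^2) * e2)
  ldtab <- flat_ldscores(paste0("s", 1:M)); ldtab$l2 <- l2
  d <- tibble::tibble(snp_id = paste0("s", 1:M), z1 = NA, z2 = NA, n1 = N, n2 = N)
  d$z1 <- z1; d$z2 <- z2
  fit <- ldsc_rg(d, ld = ldtab, chi2_max = Inf)
  expect_lt(abs(fit$gencov - gcov), 0.03)
  expect_lt(abs(fit$intercept_xt), 0.2)
  expect_lt(abs(fit$rg - gcov / sqrt(h1 * h2_)), 0.25)
})

test_that("liability-scale conversion matches its closed form", {
  expect_equal(liability_scale(1, K = 0.5, P = 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(liability_scale(0.1, K = 0.1, P = 0.5), 0.10519, tolerance = 1e-4)
  expect_equal(liability_scale(0, K = 0.3, P = 0.4), 0)
  # linear in h2 and continuous in K
  expect_equal(liability_scale(0.4, 0.2, 0.5), 4 * liability_scale(0.1, 0.2, 0.5))
  ks <- seq(0.01, 0.99, by = 0.01)
  fac <- liability_scale(1, ks, 0.5)
  expect_true(all(is.finite(fac)))
  expect_true(max(abs(diff(fac))) < 1.2) # no jumps on a fine grid
  expect_error(liability_scale(0.1, K = 0, P = 0.5), "K")
})

test_that("LD-score files in the .l2.ldscore dialect round-trip, with per-chromosome merging", {
  dir <- tempfile(); dir.create(dir)
  for (chr in 1:2) {
    write.table(
      data.frame(CHR = chr, SNP = paste0("c", chr, "_", 1:50), BP = 1:50 * 1000,
                 L2 = runif(50, 1, 20)),
      file.path(dir, sprintf("test.%d.l2.ldscore", chr)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(600 + chr), file.path(dir, sprintf("test.%d.l2.M_5_50", chr)))
  }
  ld <- read_ldscores(dir)
  expect_equal(nrow(ld), 100)
  expect_equal(attr(ld, "M"), 1203)
  one <- read_ldscores(file.path(dir, "test.1"))
  expect_equal(nrow(one), 50)
  expect_equal(attr(one, "M"), 601)
})

test_that("expected overlap intercept reduces to the overlap rate for balanced studies", {
  expect_equal(overlap_intercept(5000, 20000, 20000, 0.5, 0.5), 0.25)
  expect_equal(overlap_intercept(0, 20000, 20000, 0.5, 0.5), 0)
  # asymmetric case fractions shrink the correlation
  expect_lt(overlap_intercept(5000, 20000, 20000, 0.2, 0.5),
            overlap_intercept(5000, 20000, 20000, 0.5, 0.5))
})
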