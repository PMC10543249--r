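test_that("sum test matches the normal-tail closed forms", {
  # perfect cancellation
  expect_equal(sumTest(c(1, -1), diag(2))$p, 1)
  # B = 2, Var = 2 under identity LD: two-sided normal tail
  st <- sumTest(c(1, 1), diag(2))
  expect_equal(st$B, 2)
  expect_equal(st$p, 2 * pnorm(-sqrt(2)), tolerance = 1e-10)
  expect_equal(round(st$p, 5), 0.15730)
  # single SNP
  expect_equal(sumTest(1.5, matrix(1))$p, 2 * pnorm(-1.5), tolerance = 1e-10)
  expect_error(sumTest(c(1, 1), matrix(c(1, -1, -1, 1), 2)), "1'R1")
})

test_that("squared-sum test matches chi-square closed forms under identity LD", {
  s2t <- squaredSumTest(c(1, 1), diag(2))
  expect_equal(s2t$Q, 2)
  expect_equal(s2t$p, exp(-1), tolerance = 1e-10)
  expect_equal(squaredSumTest(2, matrix(1))$p,
               pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(squaredSumTest(c(0, 0, 0), diag(3))$p, 1)
})

test_that("single-SNP genes collapse all three tests to the same p-value", {
  at <- adaptiveTest(2, matrix(1))
  p1 <- pchisq(4, 1, lower.tail = FALSE)
  expect_equal(at$T, p1, tolerance = 1e-10)
  expect_equal(at$p, p1, tolerance = 1e-10)
  expect_equal(sumTest(2, matrix(1))$p, p1, tolerance = 1e-10)
  expect_equal(squaredSumTest(2, matrix(1))$p, p1, tolerance = 1e-10)
})

test_that("rho grid endpoints reproduce the squared-sum and sum tests exactly", {
  z <- c(1.2, -0.4, 2.1)
  R <- makeLD(list(type = "ar1", r = 0.5), 3)
  at <- adaptiveTest(z, R)
  expect_identical(at$p_rho[1], squaredSumTest(z, R)$p)
  expect_identical(at$p_rho[length(at$p_rho)], sumTest(z, R)$p)
})

test_that("adaptive p is sandwiched between T and |grid| * T", {
  R <- makeLD(list(type = "ar1", r = 0.5), 8)
  zs <- simulateZ(R, 0, 25, seed = 202)
  for (i in seq_len(nrow(zs))) {
    at <- adaptiveTest(zs[i, ], R)
    expect_gte(at$p, at$T)
    expect_lte(at$p, min(1, length(at$rho_grid) * at$T))
  }
})

test_that("integration-based adaptive p agrees with the Monte-Carlo estimator", {
  # the worked two-SNP case: per-rho p at the endpoints only
  ai <- adaptiveTest(c(1, -1), diag(2), rho_grid = c(0, 1))
  expect_equal(ai$p_rho, c(exp(-1), 1), tolerance = 1e-10)
  expect_equal(ai$T, exp(-1), tolerance = 1e-10)
  am <- adaptiveTest(c(1, -1), diag(2), rho_grid = c(0, 1),
                     method = "monte_carlo", mc_draws = 2e5, seed = 71)
  se <- sqrt(am$p * (1 - am$p) / 2e5)
  expect_lt(abs(ai$p - am$p), 3 * se)

  # random AR(1) instances across the p range
  R <- makeLD(list(type = "ar1", r = 0.5), 10)
  zs <- simulateZ(R, 0, 6, seed = 303)
  for (i in seq_len(nrow(zs))) {
    ai <- adaptiveTest(zs[i, ], R)
    am <- adaptiveTest(zs[i, ], R, method = "monte_carlo",
                       mc_draws = 1e5, seed = 400 + i)
    se <- sqrt(am$p * (1 - am$p) / 1e5)
    expect_lt(abs(ai$p - am$p), 3 * se)
  }
})

test_that("null weights conserve the trace at every rho grid point", {
  R <- makeLD(list(type = "ar1", r = 0.5), 7)
  m <- nrow(R)
  s2 <- sum(R)
  lam_s2t <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(lam_s2t), m, tolerance = 1e-8)
  for (rho in c(0, 0.09, 0.25, 0.64, 1)) {
    lam <- geneSAT:::rhoKernelEigen(R, rho)
    expect_equal(sum(lam), (1 - rho) * m + rho * s2, tolerance = 1e-8)
  }
})

test_that("permuting SNPs within a gene leaves all p-values unchanged", {
  R <- makeLD(list(type = "ar1", r = 0.6), 8)
  z <- as.vector(simulateZ(R, 0.4, 1, seed = 17))
  perm <- sample(8)
  zp <- z[perm]; Rp <- R[perm, perm]
  expect_lt(abs(sumTest(zp, Rp)$p - sumTest(z, R)$p), 1e-10)
  expect_lt(abs(squaredSumTest(zp, Rp)$p - squaredSumTest(z, R)$p), 1e-10)
  expect_lt(abs(adaptiveTest(zp, Rp)$p - adaptiveTest(z, R)$p), 1e-10)
})

test_that("adaptive power is non-decreasing in the shift under AR(1) LD", {
  R <- makeLD(list(type = "ar1", r = 0.5), 10)
  nrep <- 200
  power <- vapply(c(0, 0.3, 0.6), function(delta) {
    zs <- simulateZ(R, delta, nrep, seed = 1000 + round(100 * delta))
    mean(vapply(seq_len(nrep),
                function(i) adaptiveTest(zs[i, ], R)$p, numeric(1)) < 0.05)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_lt(power[1], 0.12)   # near-nominal at the null
  expect_gt(power[3], power[1])
})

test_that("gene scan applies the Bonferroni threshold and emits a Manhattan table", {
  expect_equal(bonferroniThreshold(0.05, 20000), 2.5e-6)
  gs1 <- toy_gene_set(z = c(0.3, -0.2, 0.5), gene_id = "NULL1")
  gs2 <- toy_gene_set(z = c(4, 4.5, 4.2), gene_id = "HIT1", chrom = "2")
  scan <- geneScan(list(NULL1 = gs1, HIT1 = gs2), alpha_fw = 0.05)
  expect_equal(scan$threshold, 0.025)
  expect_equal(scan$results$significant, c(FALSE, TRUE))
  expect_equal(scan$manhattan$neg_log10_p, -log10(scan$results$p_at))
  expect_equal(scan$manhattan$pos, c(200, 200))
  # nominal family-size override
  scan2 <- geneScan(list(NULL1 = gs1, HIT1 = gs2), alpha_fw = 0.05,
                    family_size = 20000)
  expect_equal(scan2$threshold, 2.5e-6)
  expect_error(geneScan(list()), "empty")
})
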