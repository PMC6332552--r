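test_that("pbvnorm matches brute-force 2-D quadrature and closed forms", {
  # closed form at h = k = 0: 1/4 + asin(rho) / (2 pi)
  rho <- c(-0.9, -0.5, 0, 0.3, 0.8, 0.99)
  expect_equal(pbvnorm(0, 0, rho), 0.25 + asin(rho) / (2 * pi),
               tolerance = 1e-12)
  # brute-force grid quadrature oracle at assorted (h, k, rho)
  cases <- expand.grid(h = c(-1, 0.3, 1.5), k = c(-0.5, 0.8),
                       rho = c(-0.7, 0.2, 0.9))
  got <- pbvnorm(cases$h, cases$k, cases$rho)
  ora <- mapply(orthant_quad, cases$h, cases$k, cases$rho)
  expect_lt(max(abs(got - ora)), 1e-5)
  # limits
  expect_equal(pbvnorm(1, 2, 1), pnorm(1))
  expect_equal(pbvnorm(1, -1, -1), pnorm(1) + pnorm(-1) - 1)
  expect_equal(pbvnorm(Inf, 0.5, 0.7), pnorm(0.5))
})

test_that("latent correlation solves the orthant equation", {
  # independence and comonotone limits
  expect_equal(latent_correlation(0.5, 0.5, 0.25), 0, tolerance = 1e-7)
  expect_equal(latent_correlation(0.3, 0.3, 0.3), 0.999)
  expect_equal(latent_correlation(0.3, 0.4, max(0, 0.3 + 0.4 - 1)), -0.999)
  # p_j = p_k = 0.5, p_jk = 0.35: oracle scans a rho grid against 2-D
  # quadrature of the bivariate density over the quadrant
  coarse <- seq(0.5, 0.7, by = 0.01)
  vc <- vapply(coarse, function(r) orthant_quad(0, 0, r, n = 500), 0)
  c0 <- coarse[which.min(abs(vc - 0.35))]
  fine <- seq(c0 - 0.01, c0 + 0.01, by = 1e-4)
  vf <- vapply(fine, function(r) orthant_quad(0, 0, r, n = 500), 0)
  rho_oracle <- fine[which.min(abs(vf - 0.35))]
  expect_equal(latent_correlation(0.5, 0.5, 0.35), rho_oracle,
               tolerance = 1e-4)
  # round trip: orthant probability of the solved rho reproduces p_jk
  pj <- c(0.1, 0.25, 0.5, 0.7); pk <- c(0.3, 0.5, 0.2, 0.6)
  rho_true <- c(-0.6, 0.4, 0.85, -0.2)
  pjk <- pbvnorm(qnorm(pj), qnorm(pk), rho_true)
  expect_equal(latent_correlation(pj, pk, pjk), rho_true, tolerance = 1e-6)
  # invalid inputs
  expect_error(latent_correlation(0.3, 0.3, 0.35), "Frechet")
  expect_error(latent_correlation(0, 0.5, 0), "strictly")
})

test_that("PD repair clips eigenvalues and preserves unit diagonal", {
  expect_identical(repair_pd(diag(3))[1:3, 1:3], diag(3))
  R_ok <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(repair_pd(R_ok)[1:2, 1:2], R_ok)
  expect_equal(attr(repair_pd(R_ok), "max_deviation"), 0)
  # a 3x3 correlation-like matrix with a negative eigenvalue
  R_bad <- matrix(c(1, 0.9, -0.3, 0.9, 1, 0.9, -0.3, 0.9, 1), 3)
  expect_lt(min(eigen(R_bad, symmetric = TRUE)$values), 0)
  R_fix <- suppressMessages(repair_pd(R_bad))
  expect_gte(min(eigen(R_fix, symmetric = TRUE)$values), 1e-6 * 0.5)
  expect_equal(diag(R_fix), rep(1, 3))
  expect_gt(attr(R_fix, "max_deviation"), 0)
  expect_error(repair_pd(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
})

test_that("model fitting recovers marginals and pairwise structure", {
  # duplicated columns hit the clip bound; independent columns give rho = 0
  A <- cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  haps <- haps_with_counts(c(2L, 2L, 2L), 4L)
  haps$alleles <- A
  m <- fit_haplotype_model(haps)
  expect_equal(m$p, rep(0.5, 3))
  expect_equal(m$R[1, 2], 0.999)
  expect_equal(m$R[1, 3], 0, tolerance = 1e-6)
  # monomorphic columns are rejected with advice
  bad <- haps_with_counts(c(0L, 2L), 4L)
  expect_error(fit_haplotype_model(bad), "MAF pre-filter")
})

test_that("fitted latent correlations track the generating truth", {
  pref <- file.path(tempdir(), "fit_truth")
  fx <- make_fixture(pref, n_variants = 20, n_samples = 1000,
                     maf_range = c(0.2, 0.5),
                     ld = list(type = "ar1", rho = 0.7), seed = 31)
  m <- fit_haplotype_model(read_phased_vcf(fx$vcf))
  iu <- upper.tri(m$R)
  err <- abs(m$R[iu] - fx$manifest$R[iu])
  expect_lt(mean(err), 0.03)   # ~sampling error at 2000 haplotypes
  expect_lt(max(err), 0.15)
})

test_that("haplotype pool regenerates batches of batch_size on exhaustion", {
  m <- model_from_truth(c(0.2, 0.4), diag(2))
  pool <- with_seed(5, haplotype_pool(m, batch_size = 1000L))
  expect_equal(pool_batches(pool), 1L)
  h0 <- with_seed(6, generate_haplotypes(pool, 0))
  expect_equal(nrow(h0$alleles), 0L)
  expect_equal(pool_batches(pool), 1L)
  with_seed(6, generate_haplotypes(pool, 1200))
  expect_equal(pool_batches(pool), 2L)      # 1200 draws = 2 batches of 1000
  with_seed(6, generate_haplotypes(pool, 800))
  expect_equal(pool_batches(pool), 2L)      # buffer still has capacity
  with_seed(6, generate_haplotypes(pool, 2))
  expect_equal(pool_batches(pool), 3L)
})

test_that("simulated haplotypes preserve marginals and pairwise r", {
  R <- matrix(c(1, 0.6, 0.6, 1), 2)
  m <- model_from_truth(c(0.1, 0.3), R)
  pool <- with_seed(11, haplotype_pool(m))
  sim <- with_seed(12, generate_haplotypes(pool, 10000))
  p_hat <- colMeans(sim$alleles)
  se <- sqrt(m$p * (1 - m$p) / 10000)
  expect_true(all(abs(p_hat - m$p) <= 3 * se))
  # realized allele-scale r versus the r implied by the latent model
  r_target <- (pbvnorm(m$q[1], m$q[2], R[1, 2]) - m$p[1] * m$p[2]) /
    sqrt(prod(m$p * (1 - m$p)))
  r_hat <- cor(sim$alleles[, 1], sim$alleles[, 2])
  expect_lt(abs(r_hat - r_target), 0.03)
})

test_that("haplotype models round-trip through the JSON archive", {
  R <- matrix(c(1, 0.4, 0.4, 1), 2)
  m <- model_from_truth(c(0.15, 0.3), R)
  p <- withr::local_tempfile(fileext = ".json")
  write_haplotype_model(m, p)
  m2 <- read_haplotype_model(p)
  expect_equal(m2$p, m$p)
  expect_equal(m2$R, m$R)
  expect_equal(m2$chol, m$chol)
  expect_equal(m2$variants$pos, m$variants$pos)
  a <- with_seed(9, famvarsim:::draw_model_haplotypes(m, 50))
  b <- with_seed(9, famvarsim:::draw_model_haplotypes(m2, 50))
  expect_identical(a, b)
})

test_that("generation is deterministic under a fixed seed", {
  m <- model_from_truth(c(0.2, 0.35, 0.45), diag(3))
  a <- with_seed(21, generate_haplotypes(haplotype_pool(m), 500))
  b <- with_seed(21, generate_haplotypes(haplotype_pool(m), 500))
  expect_identical(a$alleles, b$alleles)
})
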