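# Shared fixtures and independent oracles, built in code at test time.

# Hand-written VCF text (independent of write_phased_vcf) for reader tests.
write_vcf_text <- function(path, records, samples = c("s1", "s2")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, gts, ref = "A", alt = "G") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# A HaplotypeMatrix with exactly k_j ALT alleles in column j (2N haplotypes),
# deterministic, so empirical MAFs are known exactly.
haps_with_counts <- function(counts, n_haps) {
  A <- vapply(counts, function(k) c(rep(1L, k), rep(0L, n_haps - k)),
              integer(n_haps))
  v <- data.frame(chrom = "1", pos = seq_len(length(counts)) * 1000,
                  id = sprintf("v%d", seq_along(counts)), ref = "A",
                  alt = "G", maf = pmin(counts / n_haps, 1 - counts / n_haps),
                  stringsAsFactors = FALSE)
  structure(list(alleles = A, sample_ids = sprintf("s%d", 1:(n_haps / 2)),
                 variants = v), class = "HaplotypeMatrix")
}

# Build a HaplotypeModel directly from known (p, R) without fitting.
model_from_truth <- function(p, R, pos = seq_along(p) * 1e4) {
  v <- data.frame(chrom = "1", pos = pos, id = sprintf("v%d", seq_along(p)),
                  ref = "A", alt = "G", maf = pmin(p, 1 - p),
                  stringsAsFactors = FALSE)
  structure(list(p = p, q = qnorm(p), R = R, chol = chol(R), variants = v),
            class = "HaplotypeModel")
}

# Brute-force bivariate-normal orthant probability by 2-D grid quadrature
# (midpoint rule on a truncated lattice); independent of pbvnorm.
orthant_quad <- function(h, k, rho, lim = 8, n = 1200) {
  x <- seq(-lim, h, length.out = n)
  y <- seq(-lim, k, length.out = n)
  dx <- x[2] - x[1]; dy <- y[2] - y[1]
  xm <- x[-1] - dx / 2; ym <- y[-1] - dy / 2
  det <- 1 - rho^2
  q <- outer(xm^2, ym^2, "+") - 2 * rho * outer(xm, ym)
  sum(exp(-q / (2 * det))) * dx * dy / (2 * pi * sqrt(det))
}

# Founder pair over a given region with recognizable alleles.
make_founders <- function(n_var = 40, span_cm = 50) {
  cms <- seq(0, span_cm, length.out = n_var)
  region <- c(0, span_cm)
  f <- famvarsim:::new_individual(
    "dad", rep(0L, n_var), rep(1L, n_var),
    famvarsim:::new_track(region, numeric(0), 1L),
    famvarsim:::new_track(region, numeric(0), 2L))
  m <- famvarsim:::new_individual(
    "mum", rep(0L, n_var), rep(1L, n_var),
    famvarsim:::new_track(region, numeric(0), 3L),
    famvarsim:::new_track(region, numeric(0), 4L))
  list(father = f, mother = m, cms = cms, region = region)
}

# Small haplotype panel + pool for pedigree tests (cached per test file run).
test_pool <- function(n_variants = 30, maf_range = c(0.1, 0.5),
                      span_bp = 2e7, seed = 99, n_samples = 300) {
  pref <- file.path(tempdir(),
                    sprintf("ttpool_%d_%d", n_variants, seed))
  fx <- make_fixture(pref, n_variants = n_variants, n_samples = n_samples,
                     maf_range = maf_range, span_bp = span_bp, seed = seed)
  haps <- read_phased_vcf(fx$vcf)
  with_seed(seed + 1, haplotype_pool(fit_haplotype_model(haps)))
}

# Direct (independent) Weibull-PH log-likelihood with sigma2 = 0.
weibull_ph_loglik <- function(rho, lambda, beta, time, status, X) {
  eta <- as.numeric(as.matrix(X) %*% beta)
  h0 <- (rho / lambda) * (time / lambda)^(rho - 1)
  H0 <- (time / lambda)^rho
  sum(status * (log(h0) + eta) - H0 * exp(eta))
}

# Marginal family likelihood by nested adaptive quadrature (k = 1 or 2) or
# mode-centred Gauss-Hermite tensor quadrature (k = 3); independent of the
# package's Laplace code path.
family_loglik_quad <- function(params, time, status, X, B) {
  k <- length(time)
  S <- params$sigma2 * B
  lik <- function(b) {
    eta <- as.numeric(as.matrix(X) %*% params$beta) + b
    h0 <- (params$rho / params$lambda) * (time / params$lambda)^(params$rho - 1)
    H0 <- (time / params$lambda)^params$rho
    exp(sum(status * (log(h0) + eta) - H0 * exp(eta)))
  }
  if (k == 1) {
    f <- function(b) vapply(b, lik, 0) * dnorm(b, sd = sqrt(S[1, 1]))
    return(log(integrate(f, -12 * sqrt(S[1, 1]), 12 * sqrt(S[1, 1]),
                         rel.tol = 1e-10)$value))
  }
  L <- t(chol(S))
  gh <- famvarsim:::gauss_legendre(48)  # nodes reused for GL on a box
  lim <- 9
  nodes <- gh$nodes * lim
  wts <- gh$weights * lim
  if (k == 2) {
    tot <- 0
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
      z <- c(nodes[i], nodes[j])
      tot <- tot + wts[i] * wts[j] * lik(as.numeric(L %*% z)) *
        exp(-sum(z^2) / 2) / (2 * pi)
    }
    return(log(tot))
  }
  gh3 <- famvarsim:::gauss_legendre(32)
  nodes <- gh3$nodes * lim
  wts <- gh3$weights * lim
  tot <- 0
  for (i in seq_along(nodes)) for (j in seq_along(nodes))
    for (l in seq_along(nodes)) {
      z <- c(nodes[i], nodes[j], nodes[l])
      tot <- tot + wts[i] * wts[j] * wts[l] * lik(as.numeric(L %*% z)) *
        exp(-sum(z^2) / 2) / (2 * pi)^1.5
    }
  log(tot)
}
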