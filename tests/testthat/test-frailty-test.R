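sim_frailty_data <- function(n_fam = 120, seed = 1, beta_g = numeric(0),
                             sigma2 = 0) {
  with_seed(seed, {
    sizes <- sample(2:4, n_fam, replace = TRUE)
    fam <- rep(seq_len(n_fam), sizes)
    n <- length(fam)
    d <- data.frame(family = fam, sex = rbinom(n, 1, 0.5),
                    generation = sample(1:3, n, replace = TRUE))
    B_list <- lapply(split(seq_len(n), fam), function(idx) {
      B <- matrix(0.5, length(idx), length(idx)); diag(B) <- 1; B
    })
    names(B_list) <- as.character(seq_len(n_fam))
    m <- survival_trait_model(sigma2 = sigma2)
    out <- simulate_survival(m, d, B_list = if (sigma2 > 0) B_list)
    list(data = out, B_list = B_list)
  })
}

test_that("sigma2 = 0 family loglik equals the closed-form Weibull PH value", {
  sim <- sim_frailty_data(n_fam = 5, seed = 10)
  d <- sim$data
  for (f in 1:5) {
    idx <- d$family == f
    pars <- list(rho = 2.5, lambda = 120, beta = 0.4, sigma2 = 0)
    ll <- family_loglik(pars, d$time[idx], d$status[idx],
                        matrix(d$sex[idx]), sim$B_list[[as.character(f)]])
    expect_equal(ll, weibull_ph_loglik(2.5, 120, 0.4, d$time[idx],
                                       d$status[idx], matrix(d$sex[idx])),
                 tolerance = 1e-10)
  }
})

test_that("Laplace marginal matches quadrature on families of size 1 to 3", {
  pars <- list(rho = 3, lambda = 143, beta = 0.5, sigma2 = 0.8)
  # size 1: adaptive 1-D quadrature
  ll1 <- family_loglik(pars, 70, 1, matrix(1), matrix(1))
  q1 <- family_loglik_quad(pars, 70, 1, matrix(1), matrix(1))
  expect_lt(abs(ll1 - q1), 1e-4 * abs(q1))
  # size 2, correlated B
  B2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  t2 <- c(60, 85); s2 <- c(1, 0); X2 <- matrix(c(1, 0))
  ll2 <- family_loglik(pars, t2, s2, X2, B2)
  q2 <- family_loglik_quad(pars, t2, s2, X2, B2)
  expect_lt(abs(ll2 - q2), 1e-3 * abs(q2))
  # size 3, mixed censoring
  B3 <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3)
  t3 <- c(55, 90, 74); s3 <- c(0, 1, 1); X3 <- matrix(c(0, 1, 1))
  ll3 <- family_loglik(pars, t3, s3, X3, B3)
  q3 <- family_loglik_quad(pars, t3, s3, X3, B3)
  expect_lt(abs(ll3 - q3), 1e-3 * abs(q3))
})

test_that("independent members factorize the marginal likelihood", {
  pars <- list(rho = 3, lambda = 143, beta = 0.3, sigma2 = 0.6)
  t2 <- c(66, 92); s2 <- c(1, 0); X2 <- matrix(c(0, 1))
  joint <- family_loglik(pars, t2, s2, X2, diag(2))
  seps <- family_loglik(pars, t2[1], s2[1], X2[1, , drop = FALSE],
                        matrix(1)) +
    family_loglik(pars, t2[2], s2[2], X2[2, , drop = FALSE], matrix(1))
  # equality holds to the accuracy of the corrected Laplace approximation
  expect_equal(joint, seps, tolerance = 1e-3)
})

test_that("null fits agree with an independent parametric survival oracle", {
  sim <- sim_frailty_data(n_fam = 150, seed = 11)
  d <- sim$data
  X <- matrix(d$sex, dimnames = list(NULL, "sex"))
  f0 <- fit_frailty(d$time, d$status, X, d$family, sim$B_list, null = TRUE)
  sr <- survival::survreg(survival::Surv(time, status) ~ sex, data = d)
  expect_equal(f0$loglik, sr$loglik[2], tolerance = 1e-6)
  expect_equal(f0$rho_hat, 1 / sr$scale, tolerance = 1e-3)
  expect_equal(f0$lambda_hat, exp(coef(sr)[[1]]), tolerance = 1e-3)
  expect_equal(unname(f0$beta_hat), -coef(sr)[[2]] / sr$scale,
               tolerance = 1e-3)
})

test_that("frailty fits recover the generating parameters", {
  sim <- sim_frailty_data(n_fam = 500, seed = 12)
  d <- sim$data
  X <- matrix(d$sex, dimnames = list(NULL, "sex"))
  f0 <- fit_frailty(d$time, d$status, X, d$family, sim$B_list, null = TRUE)
  expect_true(f0$converged)
  # truth: rho 3, lambda 143, beta_sex 0.5; generous Monte-Carlo bands
  expect_lt(abs(f0$rho_hat - 3), 0.5)
  expect_lt(abs(f0$lambda_hat - 143), 12)
  expect_lt(abs(f0$beta_hat - 0.5), 0.3)
})

test_that("alternative fit respects the boundary and likelihood nesting", {
  for (s in c(13, 14)) {
    sim <- sim_frailty_data(n_fam = 100, seed = s)
    d <- sim$data
    X <- matrix(d$sex, dimnames = list(NULL, "sex"))
    f0 <- fit_frailty(d$time, d$status, X, d$family, sim$B_list,
                      null = TRUE)
    f1 <- fit_frailty(d$time, d$status, X, d$family, sim$B_list,
                      null = FALSE,
                      init = c(log(f0$rho_hat), log(f0$lambda_hat),
                               f0$beta_hat))
    expect_gte(f1$sigma2_hat, 0)
    expect_gte(f1$loglik, f0$loglik - 1e-6)   # nesting
    lrt <- frailty_lrt(f0, f1)
    expect_gte(lrt$statistic, 0)
    expect_true(lrt$p_value > 0 && lrt$p_value <= 1)
  }
})

test_that("all-censored data and tiny studies are rejected", {
  sim <- sim_frailty_data(n_fam = 10, seed = 15)
  d <- sim$data
  expect_error(fit_frailty(d$time, rep(0, nrow(d)), matrix(d$sex),
                           d$family, sim$B_list), "censored")
  pool <- test_pool()
  expect_error(run_frailty_study(pool, replicates = 0), "replicate")
})

test_that("the mixture chi-squared p-value handles the boundary mass", {
  expect_equal(lrt_pvalue(0), 1)
  expect_equal(lrt_pvalue(2.706), 0.05, tolerance = 1e-3)
  expect_equal(lrt_pvalue(3.841), 0.025, tolerance = 1e-3)
  expect_error(lrt_pvalue(-1), "non-negative")
})
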