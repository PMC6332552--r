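# Phenotype generators: logistic case-control outcomes and Weibull
# correlated-frailty survival times.

#' Variant effect size from its minor allele frequency
#'
#' Rarer variants get larger log-odds effects:
#' `beta = (ln 5 / 4) * |log10(maf)|`.
#'
#' @param maf minor allele frequency in (0, 1].
#' @return log-odds effect size(s).
#' @export
effect_from_maf <- function(maf) {
  if (any(maf <= 0)) stop("maf must be positive")
  (log(5) / 4) * abs(log10(maf))
}

#' Binary trait model (logistic)
#'
#' Disease status follows
#' `logit P(y = 1) = b0 + b1 * s + sum_j G_j * c_j`, with `s` a binary
#' stratum indicator (e.g. population membership) and `c_j` per-variant
#' log-odds effects on the causal set.
#'
#' @param b0 baseline log-odds.
#' @param b1 stratum log-odds.
#' @param c_effects numeric vector of causal-variant log-odds effects.
#' @param causal_set column indices of the causal variants in the dosage
#'   matrix (same length as `c_effects`).
#' @return an object of class `BinaryTraitModel`.
#' @export
binary_trait_model <- function(b0 = 0, b1 = 0, c_effects = numeric(0),
                               causal_set = integer(0)) {
  if (length(c_effects) != length(causal_set))
    stop("c_effects and causal_set must have equal length")
  structure(list(b0 = b0, b1 = b1, c = c_effects,
                 causal_set = as.integer(causal_set)),
            class = "BinaryTraitModel")
}

#' Simulate binary outcomes under the logistic model
#'
#' @param model a [binary_trait_model()].
#' @param G additive dosage matrix (individuals x variants, entries 0/1/2).
#' @param strata per-individual stratum indicator in `{0, 1}` (default all 0).
#' @return integer vector of 0/1 outcomes.
#' @export
simulate_binary <- function(model, G, strata = rep(0L, nrow(G))) {
  stopifnot(inherits(model, "BinaryTraitModel"))
  if (length(strata) != nrow(G)) stop("strata/G dimension mismatch")
  if (length(model$causal_set) &&
      max(model$causal_set) > ncol(G)) stop("causal_set outside G columns")
  eta <- model$b0 + model$b1 * strata
  if (length(model$causal_set))
    eta <- eta + as.numeric(G[, model$causal_set, drop = FALSE] %*% model$c)
  rbinom(nrow(G), 1L, plogis(eta))
}

#' Weibull correlated-frailty survival model
#'
#' Hazard for individual `i` of family `f`:
#' `lambda_fi(t | b) = lambda0(t) * exp(b_fi + X'_fi beta)`, with Weibull
#' baseline `lambda0(t) = (rho/lambda) (t/lambda)^(rho - 1)` and family
#' random effects `b ~ MVN(0, sigma2 * B)` where `B` is the IBD-derived
#' relationship matrix (off-diagonals: pairwise mean IBD over the simulated
#' region; unit diagonal). Right-censoring occurs at an individual's current
#' age, drawn from a normal with generation-specific mean.
#'
#' @param rho,lambda Weibull shape and scale (defaults 3 and 143).
#' @param beta_sex log-hazard effect of the 0/1 sex covariate (default 0.5).
#' @param beta_g numeric vector of log-hazard effects of causal-variant
#'   dosages (default none).
#' @param sigma2 frailty variance (default 0).
#' @param censor_age_means censoring-age means per generation
#'   (defaults 95, 75, 55 for generations 1-3).
#' @param censor_age_var variance of the censoring-age normal (default 2.5).
#' @return an object of class `SurvivalTraitModel`.
#' @export
survival_trait_model <- function(rho = 3, lambda = 143, beta_sex = 0.5,
                                 beta_g = numeric(0), sigma2 = 0,
                                 censor_age_means = c(95, 75, 55),
                                 censor_age_var = 2.5) {
  stopifnot(rho > 0, lambda > 0, sigma2 >= 0, censor_age_var >= 0)
  structure(list(rho = rho, lambda = lambda, beta_sex = beta_sex,
                 beta_g = beta_g, sigma2 = sigma2,
                 censor_age_means = censor_age_means,
                 censor_age_var = censor_age_var),
            class = "SurvivalTraitModel")
}

# Draw one MVN(0, sigma2 * B) vector (ridge for numerical PSD).
draw_frailty <- function(sigma2, B, ridge = 1e-8) {
  k <- nrow(B)
  if (sigma2 == 0) return(numeric(k))
  S <- sigma2 * B + diag(ridge, k)
  L <- tryCatch(chol(S), error = function(e) {
    e2 <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (min(e2$values) < -1e-6)
      stop("frailty covariance not positive semidefinite after jitter")
    chol(e2$vectors %*% (pmax(e2$values, 1e-10) * t(e2$vectors)))
  })
  as.numeric(crossprod(L, rnorm(k)))
}

#' Simulate right-censored survival data
#'
#' Event times are drawn by Weibull inversion
#' `T = lambda * (-log(U) / exp(b + X'beta))^(1/rho)`, with per-family
#' frailties `b ~ MVN(0, sigma2 * B)`; each individual is censored at a
#' current age drawn from `N(mean[generation], censor_age_var)` (truncated at
#' 0), so `status = 1` iff `T <= age` and the observed time is `min(T, age)`.
#'
#' @param model a [survival_trait_model()].
#' @param data data frame with columns `family`, `sex` (0/1) and
#'   `generation` (1-based index into `censor_age_means`).
#' @param G optional dosage matrix of the causal variants
#'   (`ncol(G) == length(model$beta_g)`).
#' @param B_list optional named list of per-family relationship matrices
#'   (required when `model$sigma2 > 0`).
#' @return `data` augmented with columns `time`, `status`, `age`, `frailty`.
#' @export
simulate_survival <- function(model, data, G = NULL, B_list = NULL) {
  stopifnot(inherits(model, "SurvivalTraitModel"))
  n <- nrow(data)
  stopifnot(all(c("family", "sex", "generation") %in% names(data)))
  eta <- model$beta_sex * data$sex
  if (length(model$beta_g)) {
    if (is.null(G) || ncol(G) != length(model$beta_g))
      stop("G must have one column per beta_g effect")
    eta <- eta + as.numeric(G %*% model$beta_g)
  }
  b <- numeric(n)
  if (model$sigma2 > 0) {
    if (is.null(B_list)) stop("B_list required when sigma2 > 0")
    for (f in unique(data$family)) {
      idx <- which(data$family == f)
      b[idx] <- draw_frailty(model$sigma2, B_list[[as.character(f)]])
    }
  }
  U <- runif(n)
  T_event <- model$lambda * (-log(U) / exp(b + eta))^(1 / model$rho)
  age <- rnorm(n, mean = model$censor_age_means[data$generation],
               sd = sqrt(model$censor_age_var))
  age <- pmax(age, 0)
  data$time <- pmin(T_event, age)
  data$status <- as.integer(T_event <= age)
  data$age <- age
  data$frailty <- b
  data
}
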