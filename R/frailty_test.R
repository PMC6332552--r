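# Correlated-frailty Weibull model: maximum likelihood fit and the
# boundary-mixture likelihood-ratio test of the frailty variance, plus the
# replicated three-generation family study driver.

# Clip the eigenvalues of a symmetric matrix below at eps (numerical PSD).
psd_clip <- function(B, eps = 1e-6) {
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (min(e$values) >= eps) return(B)
  e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
}

#' Marginal log-likelihood contribution of one family
#'
#' Integrates the family's `MVN(0, sigma2 * B)` random effects out of the
#' Weibull proportional-hazards likelihood via a Laplace approximation around
#' the mode of the joint log-density (Newton inner loop, tolerance 1e-8).
#' Exact (no integration) when `sigma2 = 0`.
#'
#' @param params list with elements `rho`, `lambda`, `beta` (numeric vector,
#'   possibly empty) and `sigma2`.
#' @param time,status observed times and event indicators (0/1).
#' @param X covariate matrix (rows = family members).
#' @param B the family's relationship matrix (unit diagonal, PSD after
#'   eigenvalue clipping).
#' @return the family's marginal log-likelihood.
#' @export
family_loglik <- function(params, time, status, X, B) {
  stopifnot(all(c("rho", "lambda", "sigma2") %in% names(params)))
  k <- length(time)
  X <- as.matrix(X)
  stopifnot(length(status) == k, nrow(X) == k, nrow(B) == k)
  beta <- if (is.null(params$beta)) numeric(0) else as.numeric(params$beta)
  Bc <- psd_clip(as.matrix(B))
  ll <- frailty_family_loglik_cpp(log(params$rho), log(params$lambda), beta,
                                  params$sigma2, as.numeric(time),
                                  as.numeric(status), X,
                                  c(0L, k), list(solve(Bc)),
                                  determinant(Bc, logarithm = TRUE)$modulus,
                                  .gh40$nodes, .gh40$weights)
  if (is.na(ll)) stop("inner mode-finding did not converge")
  as.numeric(ll)
}

# Assemble the contiguous-family representation used by the optimizer.
prep_frailty_data <- function(time, status, X, family, B_list) {
  o <- order(match(family, unique(family)))
  fam <- family[o]
  ufam <- unique(fam)
  sizes <- as.integer(table(factor(fam, levels = ufam)))
  fam_start <- c(0L, cumsum(sizes))
  Binv <- vector("list", length(ufam))
  logdetB <- numeric(length(ufam))
  for (i in seq_along(ufam)) {
    B <- psd_clip(as.matrix(B_list[[as.character(ufam[i])]]))
    Bi <- solve(B)
    Binv[[i]] <- (Bi + t(Bi)) / 2
    logdetB[i] <- as.numeric(determinant(B, logarithm = TRUE)$modulus)
  }
  list(time = as.numeric(time)[o], status = as.numeric(status)[o],
       X = as.matrix(X)[o, , drop = FALSE], fam_start = fam_start,
       Binv = Binv, logdetB = logdetB, order = o, n_families = length(ufam))
}

frailty_total_nll <- function(par, prep, null) {
  p <- ncol(prep$X)
  beta <- par[2 + seq_len(p)]
  sigma2 <- if (null) 0 else par[3 + p]
  ll <- frailty_family_loglik_cpp(par[1], par[2], beta, sigma2, prep$time,
                                  prep$status, prep$X, prep$fam_start,
                                  prep$Binv, prep$logdetB,
                                  .gh40$nodes, .gh40$weights)
  if (anyNA(ll)) return(1e10)
  -sum(ll)
}

# Starting values for (log rho, log lambda, beta) from a parametric AFT fit.
frailty_start <- function(time, status, X) {
  p <- ncol(X)
  st <- tryCatch({
    df <- data.frame(time = time, status = status)
    sr <- survival::survreg(survival::Surv(time, status) ~ .,
                            data = cbind(df, as.data.frame(X)),
                            dist = "weibull")
    cf <- stats::coef(sr)
    c(-log(sr$scale), cf[1], -cf[-1] / sr$scale)
  }, error = function(e) NULL)
  if (is.null(st) || anyNA(st) || any(!is.finite(st)))
    st <- c(0, log(stats::median(time) * 1.44), rep(0, p))
  unname(st)
}

#' Fit the correlated-frailty Weibull model by maximum likelihood
#'
#' Maximizes the total Laplace marginal log-likelihood over
#' `(rho, lambda, beta)` with `sigma2` fixed at 0 (`null = TRUE`) or over
#' `(rho, lambda, beta, sigma2)` with `sigma2 >= 0` (`null = FALSE`), using
#' bounded quasi-Newton (L-BFGS-B) on log-transformed positive parameters
#' (`sigma2` itself is box-constrained at 0 so boundary estimates are exact).
#'
#' @param time,status observed times and event indicators.
#' @param X covariate matrix.
#' @param family family identifier per row.
#' @param B_list named list (by family id) of relationship matrices.
#' @param null logical: fix `sigma2 = 0`?
#' @param init optional initial `(log rho, log lambda, beta...)` vector.
#' @param sigma2_init initial frailty variance for the alternative fit.
#' @return an object of class `FrailtyFitResult`: `rho_hat`, `lambda_hat`,
#'   `beta_hat`, `sigma2_hat`, `loglik`, `converged`, `n_families`.
#' @export
fit_frailty <- function(time, status, X, family, B_list, null = FALSE,
                        init = NULL, sigma2_init = 0.2) {
  X <- as.matrix(X)
  if (sum(status) == 0) stop("all observations are censored; cannot fit")
  if (length(unique(family)) < 2) stop("need at least 2 families")
  prep <- prep_frailty_data(time, status, X, family, B_list)
  p <- ncol(X)
  if (is.null(init)) init <- frailty_start(prep$time, prep$status, prep$X)
  par0 <- if (null) init else c(init, sigma2_init)
  lower <- c(rep(-Inf, 2 + p), if (!null) 0)
  upper <- c(log(1e3), rep(Inf, 1 + p), if (!null) Inf)
  opt <- stats::optim(par0, frailty_total_nll, prep = prep, null = null,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 300, factr = 1e7, pgtol = 1e-5))
  beta_hat <- opt$par[2 + seq_len(p)]
  names(beta_hat) <- colnames(X)
  structure(list(rho_hat = exp(opt$par[1]), lambda_hat = exp(opt$par[2]),
                 beta_hat = beta_hat,
                 sigma2_hat = if (null) 0 else opt$par[3 + p],
                 loglik = -opt$value, converged = opt$convergence == 0,
                 message = opt$message, n_families = prep$n_families,
                 null = null),
            class = "FrailtyFitResult")
}

#' @exportS3Method base::print
print.FrailtyFitResult <- function(x, ...) {
  cat(sprintf(
    "Frailty Weibull fit (%s): rho=%.3f lambda=%.2f sigma2=%.4f loglik=%.3f%s\n",
    if (x$null) "null, sigma2=0" else "alternative", x$rho_hat, x$lambda_hat,
    x$sigma2_hat, x$loglik, if (x$converged) "" else " [NOT CONVERGED]"))
  if (length(x$beta_hat))
    cat("  beta:", paste(sprintf("%.3f", x$beta_hat), collapse = " "), "\n")
  invisible(x)
}

#' Mixture chi-squared p-value for the frailty-variance LRT
#'
#' Under the null `sigma2 = 0` the LRT statistic is asymptotically a 50:50
#' mixture of a point mass at 0 and chi-squared with 1 df, so
#' `p = 1` when the statistic is 0 and `0.5 * P(chisq_1 >= statistic)`
#' otherwise.
#'
#' @param statistic the (non-negative) LRT statistic.
#' @return p-value in (0, 1].
#' @export
lrt_pvalue <- function(statistic) {
  if (any(statistic < 0)) stop("LRT statistic must be non-negative")
  ifelse(statistic == 0, 1, 0.5 * pchisq(statistic, df = 1,
                                         lower.tail = FALSE))
}

#' Likelihood-ratio test of the frailty variance
#'
#' @param fit_null,fit_alt `FrailtyFitResult`s from [fit_frailty()] with
#'   `null = TRUE` / `FALSE` on the same data.
#' @return an object of class `LRTResult`: `statistic` (floored at 0) and
#'   `p_value`.
#' @export
frailty_lrt <- function(fit_null, fit_alt) {
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  structure(list(statistic = stat, p_value = lrt_pvalue(stat)),
            class = "LRTResult")
}

#' @exportS3Method base::print
print.LRTResult <- function(x, ...) {
  cat(sprintf("Frailty LRT: statistic = %.4f, mixture-chisq p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

# ---- three-generation family study ----------------------------------------

#' Simulate three-generation families with genotypes and IBD matrices
#'
#' Each family has two founder parents (generation 1), one or two children
#' (generation 2) and, for each child, one or two grandchildren (generation
#' 3) produced with an out-of-family founder spouse; spouses are not family
#' members, so families have 4-8 members. Sexes: one parent of each sex;
#' other members Bernoulli(1/2). The family relationship matrix `B` has unit
#' diagonal and pairwise mean-IBD off-diagonals computed exactly from the
#' origin tracks over the simulated region.
#'
#' @param pool a [haplotype_pool()].
#' @param n_families number of families.
#' @param params a [recomb_params()].
#' @param map optional [genetic_map()].
#' @return list with `data` (data frame: `family`, `id`, `sex`,
#'   `generation`), `G` (dosage matrix over all variants, rows aligned with
#'   `data`), and `B_list` (named list of per-family matrices).
#' @export
sim_three_gen_families <- function(pool, n_families,
                                   params = recomb_params(), map = NULL) {
  cms <- bp_to_cm(map, pool$model$variants$pos)
  region <- region_from_variants(cms)
  meta <- vector("list", n_families)
  Gs <- vector("list", n_families)
  B_list <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fa <- draw_founder(pool, cms, region, id = sprintf("F%d:1", f))
    mo <- draw_founder(pool, cms, region, id = sprintf("F%d:2", f))
    members <- list(fa, mo)
    gen <- c(1L, 1L)
    sex <- c(1L, 0L)
    nid <- 2L
    nc <- sample.int(2L, 1L)
    for (ci in seq_len(nc)) {
      child <- mate(fa, mo, cms, params,
                    id = sprintf("F%d:%d", f, nid + 1L))
      nid <- nid + 1L
      members[[length(members) + 1L]] <- child
      gen <- c(gen, 2L)
      sex <- c(sex, rbinom(1L, 1L, 0.5))
      spouse <- draw_founder(pool, cms, region)   # married-in, not a member
      ng <- sample.int(2L, 1L)
      for (gi in seq_len(ng)) {
        gc <- mate(child, spouse, cms, params,
                   id = sprintf("F%d:%d", f, nid + 1L))
        nid <- nid + 1L
        members[[length(members) + 1L]] <- gc
        gen <- c(gen, 3L)
        sex <- c(sex, rbinom(1L, 1L, 0.5))
      }
    }
    k <- length(members)
    B <- diag(k)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      B[i, j] <- B[j, i] <-
        compute_pair_ibd12(members[[i]], members[[j]])$mean_ibd
    }
    meta[[f]] <- data.frame(
      family = f, id = vapply(members, function(x) as.character(x$id), ""),
      sex = sex, generation = gen, stringsAsFactors = FALSE)
    Gs[[f]] <- t(vapply(members, dosage, integer(length(cms))))
    B_list[[f]] <- B
  }
  names(B_list) <- as.character(seq_len(n_families))
  list(data = do.call(rbind, meta), G = do.call(rbind, Gs), B_list = B_list)
}

#' Replicated type-I error / power study for the frailty LRT
#'
#' Runs the full pipeline per replicate: simulate three-generation families
#' from a haplotype panel, compute per-family mean-IBD matrices, generate
#' Weibull survival data with `s` causal-variant dosage effects of size
#' `beta` (Eq.-style hazard, sex covariate effect 0.5), fit the null
#' (`sigma2 = 0`) and alternative frailty models with sex as the only fitted
#' covariate, and record whether the mixture-chi-squared LRT p-value falls at
#' or below `alpha`.
#'
#' @param pool a [haplotype_pool()] for the variant panel (variants should
#'   already be MAF-filtered to the study range).
#' @param n_families families per replicate (paper grid: 100, 200, 500).
#' @param beta common log-hazard effect of the `s` causal dosages
#'   (paper grid: 0, 0.5, 1.0).
#' @param s number of causal variants (default 3).
#' @param replicates number of study replicates.
#' @param seed master seed for the study stream.
#' @param alpha rejection threshold (default 0.05).
#' @param surv_model baseline [survival_trait_model()] (its `beta_g` is
#'   replaced by `rep(beta, s)`).
#' @param params a [recomb_params()].
#' @param map optional [genetic_map()].
#' @return list with `rejection_rate`, `n_reject`, `replicates`, `failures`,
#'   `pvalues`, `n_families`, `beta`.
#' @export
run_frailty_study <- function(pool, n_families = 100, beta = 0, s = 3,
                              replicates = 200, seed = 1, alpha = 0.05,
                              surv_model = survival_trait_model(),
                              params = recomb_params(), map = NULL) {
  if (replicates < 1) stop("need at least 1 replicate")
  M <- nrow(pool$model$variants)
  if (M < s) stop("panel has fewer variants than s")
  surv_model$beta_g <- rep(beta, s)
  pvals <- rep(NA_real_, replicates)
  failures <- 0L
  set.seed(derive_seed(seed, "frailty-study"))
  for (r in seq_len(replicates)) {
    fams <- sim_three_gen_families(pool, n_families, params, map)
    causal <- sample.int(M, s)
    dat <- simulate_survival(surv_model, fams$data,
                             G = fams$G[, causal, drop = FALSE])
    X <- matrix(dat$sex, ncol = 1, dimnames = list(NULL, "sex"))
    res <- tryCatch({
      f0 <- fit_frailty(dat$time, dat$status, X, dat$family, fams$B_list,
                        null = TRUE)
      f1 <- fit_frailty(dat$time, dat$status, X, dat$family, fams$B_list,
                        null = FALSE, init = c(log(f0$rho_hat),
                                               log(f0$lambda_hat),
                                               f0$beta_hat))
      frailty_lrt(f0, f1)$p_value
    }, error = function(e) NA_real_)
    if (is.na(res)) failures <- failures + 1L else pvals[r] <- res
  }
  ok <- !is.na(pvals)
  if (!any(ok)) stop("all replicates failed")
  list(rejection_rate = mean(pvals[ok] <= alpha),
       n_reject = sum(pvals[ok] <= alpha), replicates = sum(ok),
       failures = failures, pvalues = pvals,
       n_families = n_families, beta = beta)
}
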