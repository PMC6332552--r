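# Latent-Gaussian haplotype model.
#
# A haplotype is modelled as a thresholded multivariate normal: allele j is 1
# iff Z_j < q_j with q_j = qnorm(p_j), Z ~ N(0, R). Marginal allele
# frequencies are therefore preserved exactly, and R is chosen so that the
# bivariate orthant probabilities reproduce the observed pairwise joint
# haplotype frequencies (the tetrachoric construction). The model matches
# pairwise LD only; higher-order haplotype moments are not constrained.

#' Latent (tetrachoric) correlation for a pair of variants
#'
#' Solves `P(Z_j < q_j, Z_k < q_k; rho) = p_jk` for `rho`, where
#' `q = qnorm(p)`, by vectorized bisection on `rho` (the orthant probability
#' is strictly increasing in `rho`). The result is clipped to
#' `[-0.999, 0.999]` so that the correlation matrix stays factorizable.
#'
#' @param p_j,p_k marginal ALT-allele frequencies in (0, 1).
#' @param p_jk joint frequency of the 1/1 haplotype pair; must respect the
#'   Frechet bounds `max(0, p_j + p_k - 1) <= p_jk <= min(p_j, p_k)`.
#' @param tol bisection tolerance on `rho`.
#' @param clip clipping bound for `|rho|`.
#' @return vector of latent correlations.
#' @export
latent_correlation <- function(p_j, p_k, p_jk, tol = 1e-8, clip = 0.999) {
  n <- max(length(p_j), length(p_k), length(p_jk))
  p_j <- rep_len(p_j, n); p_k <- rep_len(p_k, n); p_jk <- rep_len(p_jk, n)
  if (any(p_j <= 0 | p_j >= 1 | p_k <= 0 | p_k >= 1))
    stop("marginal frequencies must lie strictly in (0, 1)")
  lo_b <- pmax(0, p_j + p_k - 1); hi_b <- pmin(p_j, p_k)
  if (any(p_jk < lo_b - 1e-9 | p_jk > hi_b + 1e-9))
    stop("p_jk outside the Frechet bounds for (p_j, p_k)")
  qj <- qnorm(p_j); qk <- qnorm(p_k)
  rho <- numeric(n)
  f_lo <- pbvnorm(qj, qk, -clip)
  f_hi <- pbvnorm(qj, qk, clip)
  at_lo <- p_jk <= f_lo
  at_hi <- p_jk >= f_hi
  rho[at_lo] <- -clip
  rho[at_hi] <- clip
  act <- which(!(at_lo | at_hi))
  if (length(act)) {
    lo <- rep(-clip, length(act)); hi <- rep(clip, length(act))
    qa <- qj[act]; qb <- qk[act]; tgt <- p_jk[act]
    iters <- ceiling(log2(2 * clip / tol))
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      up <- pbvnorm(qa, qb, mid) < tgt
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    rho[act] <- (lo + hi) / 2
  }
  rho
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalues below `eps_pd` are clipped up to `eps_pd` and the matrix is
#' rescaled back to unit diagonal. An already-PD input is returned unchanged.
#' The maximum absolute elementwise change is attached as attribute
#' `"max_deviation"` and logged when non-zero.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps_pd smallest admissible eigenvalue.
#' @return the repaired matrix.
#' @export
repair_pd <- function(R, eps_pd = 1e-6) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps_pd) {
    attr(R, "max_deviation") <- 0
    return(R)
  }
  for (pass in 1:10) {
    lam <- pmax(e$values, eps_pd)
    R2 <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    diag(R2) <- 1
    R2 <- (R2 + t(R2)) / 2
    e <- eigen(R2, symmetric = TRUE)
    if (min(e$values) >= eps_pd * 0.5) break
  }
  dev <- max(abs(R2 - R))
  vs_log(sprintf("PD repair applied: max |dR| = %.3g", dev))
  attr(R2, "max_deviation") <- dev
  R2
}

#' Fit the latent-Gaussian haplotype model
#'
#' Estimates per-variant ALT frequencies `p` from column means, pairwise
#' joint 1/1 haplotype frequencies from column co-occurrence, converts each
#' pair to a latent correlation with [latent_correlation()] and repairs the
#' resulting matrix to positive definiteness. Cost scales with the square of
#' the number of variants.
#'
#' @param haps a `HaplotypeMatrix` with at least 2 haplotypes, every variant
#'   polymorphic.
#' @param eps_pd eigenvalue floor for [repair_pd()].
#' @return an object of class `HaplotypeModel` with fields `p`, `q`, `R`,
#'   `chol` (upper-triangular factor, `R = t(chol) %*% chol`) and `variants`.
#' @export
fit_haplotype_model <- function(haps, eps_pd = 1e-6) {
  stopifnot(inherits(haps, "HaplotypeMatrix"))
  A <- haps$alleles
  if (nrow(A) < 2L) stop("need at least 2 haplotypes")
  p <- colMeans(A)
  if (any(p <= 1e-6 | p >= 1 - 1e-6))
    stop("monomorphic or near-monomorphic variant in input; ",
         "apply a MAF pre-filter before fitting")
  M <- length(p)
  P11 <- crossprod(A) / nrow(A)      # joint 1/1 haplotype frequencies
  iu <- which(upper.tri(P11), arr.ind = TRUE)
  rho <- latent_correlation(p[iu[, 1]], p[iu[, 2]], P11[iu])
  R <- diag(M)
  R[iu] <- rho
  R <- R + t(R) - diag(M)
  R <- repair_pd(R, eps_pd)
  structure(list(p = p, q = qnorm(p), R = R, chol = chol(R),
                 variants = haps$variants),
            class = "HaplotypeModel")
}

#' @exportS3Method base::print
print.HaplotypeModel <- function(x, ...) {
  cat(sprintf("HaplotypeModel: %d variants, MAF range [%.4g, %.4g]\n",
              length(x$p), min(pmin(x$p, 1 - x$p)), max(pmin(x$p, 1 - x$p))))
  invisible(x)
}

# Draw n haplotypes directly from a fitted model (no pooling).
draw_model_haplotypes <- function(model, n) {
  M <- length(model$p)
  if (n == 0L) return(matrix(0L, 0L, M))
  Z <- matrix(rnorm(n * M), nrow = n) %*% model$chol
  matrix(as.integer(Z < rep(model$q, each = n)), nrow = n)
}

#' Serialize a haplotype model to a portable JSON archive
#'
#' Stores variant metadata (including positions), allele frequencies `p` and
#' the latent correlation matrix `R`; the thresholds and Cholesky factor are
#' recomputed on load, so the archive is portable across platforms.
#'
#' @param model a `HaplotypeModel`.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_haplotype_model <- function(model, path) {
  stopifnot(inherits(model, "HaplotypeModel"))
  jsonlite::write_json(list(p = model$p, R = model$R,
                            variants = model$variants),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_haplotype_model
#' @return for `read_haplotype_model`, the restored `HaplotypeModel`.
#' @export
read_haplotype_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- as.matrix(x$R)
  dimnames(R) <- NULL
  structure(list(p = x$p, q = qnorm(x$p), R = R, chol = chol(R),
                 variants = as.data.frame(x$variants)),
            class = "HaplotypeModel")
}

#' Create a haplotype pool
#'
#' Simulated haplotypes are produced in batches: a first batch of
#' `batch_size` haplotypes is generated immediately, and whenever the buffer
#' is exhausted another full batch of `batch_size` is generated.
#'
#' @param model a fitted `HaplotypeModel`.
#' @param batch_size haplotypes generated per batch (default 1000).
#' @return an environment of class `HaplotypePool`.
#' @export
haplotype_pool <- function(model, batch_size = 1000L) {
  stopifnot(inherits(model, "HaplotypeModel"), batch_size >= 1L)
  pool <- new.env(parent = emptyenv())
  pool$model <- model
  pool$batch_size <- as.integer(batch_size)
  pool$buffer <- draw_model_haplotypes(model, batch_size)
  pool$cursor <- 0L
  pool$batches_generated <- 1L
  pool$next_origin <- 1L
  class(pool) <- "HaplotypePool"
  pool
}

#' Number of haplotype batches generated so far
#' @param pool a `HaplotypePool`.
#' @return integer batch count.
#' @export
pool_batches <- function(pool) pool$batches_generated

# Draw n haplotype rows from the pool, regenerating batches as needed.
pool_draw <- function(pool, n) {
  stopifnot(inherits(pool, "HaplotypePool"), n >= 0)
  M <- length(pool$model$p)
  out <- matrix(0L, n, M)
  got <- 0L
  while (got < n) {
    avail <- nrow(pool$buffer) - pool$cursor
    if (avail == 0L) {
      pool$buffer <- draw_model_haplotypes(pool$model, pool$batch_size)
      pool$cursor <- 0L
      pool$batches_generated <- pool$batches_generated + 1L
      avail <- pool$batch_size
    }
    take <- min(avail, n - got)
    out[got + seq_len(take), ] <- pool$buffer[pool$cursor + seq_len(take), ,
                                              drop = FALSE]
    pool$cursor <- pool$cursor + take
    got <- got + take
  }
  out
}

#' Generate haplotypes from a pool
#'
#' @param pool a `HaplotypePool`.
#' @param n number of haplotypes to draw.
#' @param sample_prefix prefix used to label the `n/2` pseudo-samples of the
#'   returned matrix.
#' @return a `HaplotypeMatrix` of `n` haplotypes (`n` must be even; two
#'   consecutive rows form one pseudo-sample).
#' @export
generate_haplotypes <- function(pool, n, sample_prefix = "sim") {
  if (n %% 2L != 0L) stop("n must be even (two haplotypes per sample)")
  A <- pool_draw(pool, n)
  ids <- sprintf("%s%d", sample_prefix, seq_len(max(n / 2, 0)))
  if (n == 0L) ids <- character(0)
  new_haplotype_matrix(A, ids, pool$model$variants)
}

#' Binned LD decay (mean r-squared versus distance)
#'
#' Computes squared Pearson correlation between all variant pairs of a
#' haplotype matrix and averages it within inter-variant distance bins; used
#' to compare the LD structure of simulated and input data.
#'
#' @param haps a `HaplotypeMatrix`.
#' @param breaks distance bin edges in bp.
#' @return data frame with columns `bin`, `mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(haps, breaks = seq(0, 1e6, by = 1e5)) {
  A <- haps$alleles
  keep <- apply(A, 2L, function(x) var(x) > 0)
  A <- A[, keep, drop = FALSE]
  pos <- haps$variants$pos[keep]
  C <- suppressWarnings(cor(A))
  iu <- which(upper.tri(C), arr.ind = TRUE)
  r2 <- C[iu]^2
  d <- abs(pos[iu[, 2]] - pos[iu[, 1]])
  bin <- cut(d, breaks = breaks, include.lowest = TRUE)
  ok <- !is.na(bin) & !is.na(r2)
  agg <- tapply(r2[ok], bin[ok], mean)
  cnt <- tapply(r2[ok], bin[ok], length)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  data.frame(bin = levels(bin), mid = mids,
             mean_r2 = as.numeric(agg[levels(bin)]),
             n_pairs = as.integer(ifelse(is.na(cnt[levels(bin)]), 0,
                                         cnt[levels(bin)])))
}

#' @importFrom stats var cor
#' @importFrom utils head tail
NULL
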