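# Synthetic phased-VCF fixtures with known ground truth.
#
# Fixtures are drawn from the same latent-Gaussian mechanism the haplotype
# engine fits, with chosen allele frequencies and latent correlation
# structure (AR-1 decay or blocks), so oracle tests can compare fitted
# models against the generating truth recorded in the manifest.

# Latent correlation matrix for a fixture.
fixture_latent_R <- function(n_variants, ld) {
  if (is.null(ld) || is.null(ld$type) || ld$type == "none")
    return(diag(n_variants))
  if (ld$type == "ar1") {
    rho <- ld$rho
    return(rho^abs(outer(seq_len(n_variants), seq_len(n_variants), "-")))
  }
  if (ld$type == "block") {
    blk <- (seq_len(n_variants) - 1L) %/% ld$size
    R <- ifelse(outer(blk, blk, "=="), ld$rho, 0)
    diag(R) <- 1
    return(R)
  }
  stop("unknown ld type: ", ld$type)
}

#' Generate a synthetic phased-VCF fixture with known truth
#'
#' Writes a phased VCF of `n_samples` diploid samples whose haplotypes are
#' drawn from a latent-Gaussian model with ALT frequencies uniform on
#' `maf_range` and a chosen latent correlation structure, a matching uniform
#' 1 cM/Mb genetic-map file, and a JSON manifest recording the generating
#' truth (`p`, latent `R`, seed, positions). The same spec and seed always
#' produce byte-identical files.
#'
#' @param path_prefix output prefix; files `<prefix>.vcf`, `<prefix>.map`,
#'   `<prefix>.manifest.json` are written.
#' @param n_variants,n_samples fixture dimensions.
#' @param maf_range range the true ALT frequencies are drawn from
#'   (sub-interval of (0, 0.5]).
#' @param ld `list(type = "ar1", rho =)`, `list(type = "block", size =,
#'   rho =)`, or `list(type = "none")`.
#' @param chrom chromosome label.
#' @param start_bp,span_bp region origin and span; positions are distinct,
#'   sorted draws within the span.
#' @param seed fixture seed.
#' @return invisibly, a list with `vcf`, `map`, `manifest` paths and the
#'   manifest content.
#' @export
make_fixture <- function(path_prefix, n_variants = 100L, n_samples = 500L,
                         maf_range = c(0.05, 0.5),
                         ld = list(type = "ar1", rho = 0.8), chrom = "1",
                         start_bp = 1e6, span_bp = 1e6, seed = 1L) {
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] &&
        maf_range[2] <= 0.5))
    stop("degenerate maf_range; need 0 < min <= max <= 0.5")
  res <- with_seed(seed, {
    p <- runif(n_variants, maf_range[1], maf_range[2])
    pos <- sort(sample.int(span_bp, n_variants)) + start_bp
    R <- fixture_latent_R(n_variants, ld)
    ch <- chol(R)
    Z <- matrix(rnorm(2L * n_samples * n_variants),
                nrow = 2L * n_samples) %*% ch
    A <- matrix(as.integer(Z < rep(qnorm(p), each = 2L * n_samples)),
                nrow = 2L * n_samples)
    list(p = p, pos = pos, R = R, A = A)
  })
  variants <- data.frame(chrom = chrom, pos = res$pos,
                         id = sprintf("fx%d", seq_len(n_variants)),
                         ref = "A", alt = "G",
                         maf = maf_from_alleles(res$A),
                         stringsAsFactors = FALSE)
  haps <- new_haplotype_matrix(res$A, sprintf("s%d", seq_len(n_samples)),
                               variants)
  vcf_path <- paste0(path_prefix, ".vcf")
  map_path <- paste0(path_prefix, ".map")
  man_path <- paste0(path_prefix, ".manifest.json")
  write_phased_vcf(haps, vcf_path)
  nodes_bp <- seq(start_bp, start_bp + span_bp, length.out = 11)
  write_genetic_map(genetic_map(chrom, nodes_bp, nodes_bp / 1e6), map_path)
  manifest <- list(seed = seed, n_variants = n_variants,
                   n_samples = n_samples, maf_range = maf_range, ld = ld,
                   chrom = chrom, pos = res$pos, p = res$p, R = res$R)
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf_path, map = map_path, manifest_path = man_path,
                 manifest = manifest, haplotypes = haps))
}
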