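# Phased-VCF input/output and pedigree file handling.
#
# Coordinates are VCF 1-based inclusive throughout. Alleles are abstract 0/1
# (REF/ALT); the haplotype matrix always stores ALT-allele indicators, and the
# minor-allele frequency is derived separately, so phase semantics are stable
# when REF/ALT frequencies tie at 0.5.

#' Variant filter specification
#'
#' Filters are applied in a fixed order when reading a VCF: genomic region,
#' then biallelic/genotype validity, then MAF range, then `max_variants`
#' (keeping the left-most variants in position order).
#'
#' @param maf_min,maf_max closed MAF interval, `0 <= maf_min <= maf_max <= 0.5`.
#'   A variant whose MAF ties at 0.5 is retained by any `maf_max >= 0.5`.
#' @param max_variants maximum number of variants kept (`Inf` = unlimited).
#' @param region optional `list(chrom =, start =, end =)`, 1-based inclusive.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(maf_min = 0, maf_max = 0.5, max_variants = Inf,
                        region = NULL) {
  if (!(maf_min >= 0 && maf_min <= maf_max && maf_max <= 0.5))
    stop("need 0 <= maf_min <= maf_max <= 0.5")
  if (!is.null(region))
    stopifnot(is.list(region), all(c("chrom", "start", "end") %in% names(region)))
  structure(list(maf_min = maf_min, maf_max = maf_max,
                 max_variants = max_variants, region = region),
            class = "filter_spec")
}

new_haplotype_matrix <- function(alleles, sample_ids, variants) {
  stopifnot(nrow(alleles) == 2L * length(sample_ids),
            ncol(alleles) == nrow(variants))
  structure(list(alleles = alleles, sample_ids = sample_ids,
                 variants = variants),
            class = "HaplotypeMatrix")
}

#' @exportS3Method base::print
print.HaplotypeMatrix <- function(x, ...) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes (%d samples) x %d variants\n",
              nrow(x$alleles), length(x$sample_ids), nrow(x$variants)))
  invisible(x)
}

#' Number of samples / variants of a HaplotypeMatrix
#' @param x a `HaplotypeMatrix`.
#' @return integer count.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

# MAF from an ALT-allele indicator matrix (rows = haplotypes).
maf_from_alleles <- function(alleles) {
  af <- colMeans(alleles)
  pmin(af, 1 - af)
}

parse_gt_field <- function(gt) sub(":.*$", "", gt)

#' Read a phased VCF into a haplotype matrix
#'
#' Reads a VCF 4.x file with phased GT fields (`a|b`), extracts the two
#' haplotypes of every sample (rows `2i - 1` and `2i` for sample `i`), computes
#' per-variant MAF from the haplotypes and applies the filters of a
#' [filter_spec()]. Multiallelic records and records with missing, haploid or
#' half-missing genotypes are dropped with a logged count; an *unphased*
#' genotype (`/` separator) is a hard error naming the offending record.
#'
#' @param path path to a (plain or gzipped) VCF file.
#' @param filter a [filter_spec()].
#' @return a `HaplotypeMatrix`; its `variants` data frame has columns
#'   `chrom, pos, id, ref, alt, maf`.
#' @export
read_phased_vcf <- function(path, filter = filter_spec()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no genotype columns")
  sample_ids <- colnames(gt)[-1L]
  chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  id <- fix[, "ID"]; ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- rep(TRUE, length(pos))

  f <- filter
  if (!is.null(f$region)) {
    keep <- keep & chrom == f$region$chrom & pos >= f$region$start &
      pos <= f$region$end
    if (!any(keep)) stop("no variants in requested region")
  }
  multi <- keep & (is.na(alt) | grepl(",", alt) | alt == "." | alt == "")
  if (any(multi)) {
    vs_log(sum(multi), " multiallelic/invalid-ALT record(s) dropped")
    keep <- keep & !multi
  }

  gts <- parse_gt_field(gt[, -1L, drop = FALSE])
  if (is.null(dim(gts))) gts <- matrix(gts, nrow = length(pos))
  unphased <- matrix(grepl("/", gts, fixed = TRUE), nrow = nrow(gts)) & keep
  if (any(unphased)) {
    bad <- which(rowSums(unphased) > 0)[1]
    stop(sprintf("unphased genotype at record %s:%s (%s): phased `|` GT required",
                 chrom[bad], format(pos[bad], scientific = FALSE), id[bad]))
  }
  ok_gt <- !is.na(gts) &
    (gts == "0|0" | gts == "0|1" | gts == "1|0" | gts == "1|1")
  bad_rec <- keep & rowSums(!ok_gt) > 0
  if (any(bad_rec)) {
    vs_log(sum(bad_rec),
           " record(s) with missing/haploid/non-biallelic GT dropped")
    keep <- keep & !bad_rec
  }
  if (!any(keep)) stop("zero variants after genotype validation")

  idx <- which(keep)
  gts <- gts[idx, , drop = FALSE]
  M <- length(idx); N <- length(sample_ids)
  # 2N x M ALT-indicator matrix; rows 2i-1, 2i are sample i's haplotypes
  a1 <- substr(gts, 1L, 1L) == "1"
  a2 <- substr(gts, 3L, 3L) == "1"
  alleles <- matrix(0L, nrow = 2L * N, ncol = M)
  alleles[seq(1L, 2L * N, by = 2L), ] <- t(matrix(as.integer(a1), nrow = M))
  alleles[seq(2L, 2L * N, by = 2L), ] <- t(matrix(as.integer(a2), nrow = M))

  maf <- maf_from_alleles(alleles)
  sel <- maf >= f$maf_min & maf <= f$maf_max
  if (!any(sel)) stop("zero variants after MAF filtering")
  if (sum(sel) > f$max_variants) {
    vs_log("max_variants: keeping first ", f$max_variants, " of ", sum(sel),
           " variants in position order")
    sel[which(sel)[-seq_len(f$max_variants)]] <- FALSE
  }

  variants <- data.frame(chrom = chrom[idx][sel], pos = pos[idx][sel],
                         id = id[idx][sel], ref = ref[idx][sel],
                         alt = alt[idx][sel], maf = maf[sel],
                         stringsAsFactors = FALSE)
  if (is.unsorted(variants$pos)) {
    o <- order(variants$pos)
    variants <- variants[o, , drop = FALSE]
    alleles <- alleles[, sel, drop = FALSE][, o, drop = FALSE]
  } else {
    alleles <- alleles[, sel, drop = FALSE]
  }
  rownames(variants) <- NULL
  new_haplotype_matrix(alleles, sample_ids, variants)
}

#' Write a haplotype matrix as a phased VCF 4.2 file
#'
#' Emits a minimal plain-text VCF with a GT-only FORMAT column. Reading the
#' file back with [read_phased_vcf()] reproduces positions and alleles exactly.
#'
#' @param haps a `HaplotypeMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(haps, path) {
  stopifnot(inherits(haps, "HaplotypeMatrix"))
  A <- haps$alleles; v <- haps$variants
  if (length(haps$sample_ids) == 0L) stop("empty sample set")
  if (nrow(A) != 2L * length(haps$sample_ids) || ncol(A) != nrow(v))
    stop("dimension mismatch between alleles, samples and variants")
  N <- length(haps$sample_ids)
  h1 <- t(A[seq(1L, 2L * N, 2L), , drop = FALSE])
  h2 <- t(A[seq(2L, 2L * N, 2L), , drop = FALSE])
  gt <- matrix(paste0(h1, "|", h2), nrow = nrow(v))
  lines <- c("##fileformat=VCFv4.2",
             "##source=famvarsim",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", haps$sample_ids), collapse = "\t"))
  body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE), v$id,
                v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a PED-like pedigree file
#'
#' Whitespace-delimited columns: family id, individual id, father id, mother
#' id, sex; `0` (or `NA`) marks a missing parent and both parents must be
#' missing (founder) or both present. Parents of any non-founder must exist in
#' the same family and no individual may be its own ancestor. Rows may appear
#' in any order; a parent-before-child topological order is attached as
#' attribute `"topo_order"`.
#'
#' @param path path to the pedigree file.
#' @return a data frame with columns `fam, id, father, mother, sex`.
#' @export
read_pedigree <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fam", "id", "father", "mother", "sex"))
  validate_pedigree(tab)
}

#' Validate a pedigree table and compute its topological order
#' @param tab data frame with columns `fam, id, father, mother, sex`.
#' @return the validated table with attribute `"topo_order"` (row indices).
#' @export
validate_pedigree <- function(tab) {
  stopifnot(all(c("fam", "id", "father", "mother", "sex") %in% names(tab)))
  tab$fam <- as.character(tab$fam); tab$id <- as.character(tab$id)
  tab$father <- as.character(tab$father); tab$mother <- as.character(tab$mother)
  tab$father[is.na(tab$father)] <- "0"; tab$mother[is.na(tab$mother)] <- "0"
  if (anyDuplicated(paste(tab$fam, tab$id)))
    stop("duplicated individual id within a family")
  founder <- tab$father == "0" & tab$mother == "0"
  half <- xor(tab$father == "0", tab$mother == "0")
  if (any(half)) stop("individual ", tab$id[which(half)[1]],
                      " has exactly one recorded parent")
  for (i in which(!founder)) {
    fam_ids <- tab$id[tab$fam == tab$fam[i]]
    if (!(tab$father[i] %in% fam_ids))
      stop("missing father '", tab$father[i], "' for individual ", tab$id[i])
    if (!(tab$mother[i] %in% fam_ids))
      stop("missing mother '", tab$mother[i], "' for individual ", tab$id[i])
  }
  # Kahn's algorithm over parent -> child edges, per family
  key <- paste(tab$fam, tab$id, sep = "\r")
  fkey <- ifelse(tab$father == "0", NA, paste(tab$fam, tab$father, sep = "\r"))
  mkey <- ifelse(tab$mother == "0", NA, paste(tab$fam, tab$mother, sep = "\r"))
  indeg <- (!is.na(fkey)) + (!is.na(mkey))
  order_out <- integer(0)
  ready <- which(indeg == 0)
  placed <- rep(FALSE, nrow(tab))
  while (length(ready)) {
    i <- ready[1]; ready <- ready[-1]
    placed[i] <- TRUE
    order_out <- c(order_out, i)
    kids <- which(!placed & (
      (!is.na(fkey) & fkey == key[i]) | (!is.na(mkey) & mkey == key[i])))
    for (k in kids) {
      indeg[k] <- indeg[k] - sum(c(fkey[k], mkey[k]) == key[i], na.rm = TRUE)
      if (indeg[k] == 0) ready <- c(ready, k)
    }
  }
  if (length(order_out) < nrow(tab))
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  attr(tab, "topo_order") <- order_out
  tab
}
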