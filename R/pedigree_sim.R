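# Cohort generation (unrelated individuals and pedigrees) and exact IBD.
#
# Founders receive globally unique origin identifiers at draw time; gene
# dropping preserves those identifiers through the origin tracks, so IBD
# sharing between any two individuals is read off exactly from the tracks,
# weighted by genetic (cM) segment length.

region_from_variants <- function(variant_cms) {
  r <- range(variant_cms)
  if (diff(r) <= 0) r[2] <- r[1] + 1e-6   # degenerate single-point region
  r
}

new_cohort <- function(individuals, variants, variant_cms, region,
                       founder_count, pedigree = NULL) {
  structure(list(individuals = individuals, variants = variants,
                 variant_cms = variant_cms, region = region,
                 founder_count = founder_count, pedigree = pedigree),
            class = "Cohort")
}

#' @exportS3Method base::print
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals (%d founders), %d variants, %.3f cM\n",
              length(x$individuals), x$founder_count, nrow(x$variants),
              diff(x$region)))
  invisible(x)
}

# Draw one founder individual from the pool, assigning fresh origin ids.
draw_founder <- function(pool, variant_cms, region, id = NA_character_) {
  H <- pool_draw(pool, 2L)
  o1 <- pool$next_origin; o2 <- o1 + 1L
  pool$next_origin <- o1 + 2L
  new_individual(id,
                 gamete1 = as.integer(H[1L, ]), gamete2 = as.integer(H[2L, ]),
                 track1 = new_track(region, numeric(0), o1),
                 track2 = new_track(region, numeric(0), o2))
}

#' Generate a cohort of unrelated individuals
#'
#' Each individual receives two fresh haplotypes from the pool, unique origin
#' identifiers and single-segment origin tracks.
#'
#' @param pool a [haplotype_pool()].
#' @param n number of individuals.
#' @param map optional [genetic_map()] (`NULL`: uniform 1 cM/Mb fallback).
#' @return a `Cohort`.
#' @export
generate_unrelated <- function(pool, n, map = NULL) {
  cms <- bp_to_cm(map, pool$model$variants$pos)
  region <- region_from_variants(cms)
  inds <- vector("list", n)
  for (i in seq_len(n))
    inds[[i]] <- draw_founder(pool, cms, region, id = sprintf("U%d", i))
  new_cohort(inds, pool$model$variants, cms, region, founder_count = n)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders (rows with both parents missing) are drawn from the haplotype
#' pool; non-founders are produced by [mate()] in topological order.
#'
#' @param ped a pedigree table from [read_pedigree()]/[validate_pedigree()].
#' @param pool a [haplotype_pool()].
#' @param params a [recomb_params()].
#' @param map optional [genetic_map()] (`NULL`: uniform fallback).
#' @return a `Cohort`; individuals are in pedigree row order and carry
#'   `<fam>:<id>` identifiers.
#' @export
simulate_pedigree <- function(ped, pool, params = recomb_params(),
                              map = NULL) {
  if (is.null(attr(ped, "topo_order"))) ped <- validate_pedigree(ped)
  cms <- bp_to_cm(map, pool$model$variants$pos)
  region <- region_from_variants(cms)
  inds <- vector("list", nrow(ped))
  lookup <- new.env(parent = emptyenv())
  n_founder <- 0L
  for (i in attr(ped, "topo_order")) {
    key <- paste(ped$fam[i], ped$id[i], sep = ":")
    if (ped$father[i] == "0") {
      inds[[i]] <- draw_founder(pool, cms, region, id = key)
      n_founder <- n_founder + 1L
    } else {
      fa <- get(paste(ped$fam[i], ped$father[i], sep = ":"), envir = lookup)
      mo <- get(paste(ped$fam[i], ped$mother[i], sep = ":"), envir = lookup)
      inds[[i]] <- mate(inds[[fa]], inds[[mo]], cms, params, id = key)
    }
    assign(key, i, envir = lookup)
  }
  new_cohort(inds, pool$model$variants, cms, region,
             founder_count = n_founder, pedigree = ped)
}

#' Exact IBD1/IBD2 sharing proportions for a pair of individuals
#'
#' Overlays the four origin tracks of the pair; within each refined segment
#' the number of founder-haplotype identifiers shared between the two
#' individuals (0, 1 or 2, counting the best pairing of gametes) is
#' determined, and the proportions are genetic-length (cM) weighted.
#' `mean_ibd` is the kinship-scaled summary `ibd2 + ibd1 / 2`.
#'
#' @param a,b `Individual`s over the same region.
#' @return an object of class `IBDResult`: list with `ibd0`, `ibd1`, `ibd2`,
#'   `mean_ibd`.
#' @export
compute_pair_ibd12 <- function(a, b) {
  ba <- a$track1$bounds; bb <- b$track1$bounds
  if (any(abs(ba - bb) > 1e-9)) stop("individuals cover different regions")
  pts <- sort(unique(c(ba, a$track1$breaks, a$track2$breaks,
                       b$track1$breaks, b$track2$breaks)))
  mid <- (pts[-1L] + pts[-length(pts)]) / 2
  w <- diff(pts)
  a1 <- track_source_at(a$track1, mid); a2 <- track_source_at(a$track2, mid)
  b1 <- track_source_at(b$track1, mid); b2 <- track_source_at(b$track2, mid)
  n1 <- (a1 == b1) + (a2 == b2)
  n2 <- (a1 == b2) + (a2 == b1)
  ibd <- pmax(n1, n2)
  tot <- sum(w)
  res <- list(ibd0 = sum(w[ibd == 0L]) / tot,
              ibd1 = sum(w[ibd == 1L]) / tot,
              ibd2 = sum(w[ibd == 2L]) / tot)
  res$mean_ibd <- res$ibd2 + res$ibd1 / 2
  structure(res, class = "IBDResult")
}

#' @exportS3Method base::print
print.IBDResult <- function(x, ...) {
  cat(sprintf("IBD0 %.4f | IBD1 %.4f | IBD2 %.4f | mean IBD %.4f\n",
              x$ibd0, x$ibd1, x$ibd2, x$mean_ibd))
  invisible(x)
}

#' Pairwise IBD table for a cohort
#'
#' @param cohort a `Cohort`.
#' @return data frame with one row per unordered pair: `id1, id2, ibd0, ibd1,
#'   ibd2, mean_ibd`.
#' @export
compute_cohort_ibd <- function(cohort) {
  n <- length(cohort$individuals)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- data.frame(id1 = character(0), id2 = character(0), ibd0 = numeric(0),
                    ibd1 = numeric(0), ibd2 = numeric(0),
                    mean_ibd = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(out)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ib <- compute_pair_ibd12(cohort$individuals[[i]], cohort$individuals[[j]])
    data.frame(id1 = cohort$individuals[[i]]$id,
               id2 = cohort$individuals[[j]]$id,
               ibd0 = ib$ibd0, ibd1 = ib$ibd1, ibd2 = ib$ibd2,
               mean_ibd = ib$mean_ibd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Additive-dosage genotype matrix of a cohort
#' @param cohort a `Cohort`.
#' @return integer matrix, individuals x variants, entries 0/1/2.
#' @export
cohort_dosages <- function(cohort) {
  G <- t(vapply(cohort$individuals, dosage,
                integer(nrow(cohort$variants))))
  rownames(G) <- vapply(cohort$individuals, function(x) as.character(x$id), "")
  G
}

#' Convert a cohort to a HaplotypeMatrix
#'
#' Stacks each individual's two gametes as consecutive rows, so the cohort
#' can be written back out with [write_phased_vcf()].
#'
#' @param cohort a `Cohort`.
#' @return a `HaplotypeMatrix`.
#' @export
cohort_to_haplotypes <- function(cohort) {
  n <- length(cohort$individuals)
  M <- nrow(cohort$variants)
  A <- matrix(0L, 2L * n, M)
  for (i in seq_len(n)) {
    A[2L * i - 1L, ] <- cohort$individuals[[i]]$gamete1
    A[2L * i, ] <- cohort$individuals[[i]]$gamete2
  }
  ids <- vapply(cohort$individuals, function(x) as.character(x$id), "")
  ids[is.na(ids) | ids == ""] <- sprintf("S%d", which(is.na(ids) | ids == ""))
  new_haplotype_matrix(A, make.unique(ids), cohort$variants)
}
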