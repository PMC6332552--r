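# Physical (bp) to genetic (cM) coordinate mapping.
#
# A single sex-averaged map per chromosome (autosomes only). When no map is
# available a uniform 1 cM/Mb rate - the genome-wide human average - is used
# so pedigree simulation works on synthetic fixtures.

#' Construct a genetic map from (bp, cM) nodes
#'
#' @param chrom chromosome label.
#' @param bp strictly increasing physical positions.
#' @param cm non-decreasing cumulative genetic positions (centimorgans).
#' @return an object of class `GeneticMap`.
#' @export
genetic_map <- function(chrom, bp, cm) {
  bp <- as.numeric(bp); cm <- as.numeric(cm)
  if (length(bp) < 2L) stop("a genetic map needs at least 2 nodes")
  if (any(diff(bp) <= 0)) stop("bp positions must be strictly increasing")
  if (any(diff(cm) < 0)) stop("cumulative cM must be non-decreasing")
  structure(list(chrom = as.character(chrom)[1], bp = bp, cm = cm),
            class = "GeneticMap")
}

#' Uniform-rate genetic map
#'
#' Fallback map with a constant recombination rate (default 1 cM/Mb).
#'
#' @param rate_cm_per_mb constant rate in cM per Mb.
#' @param chrom chromosome label.
#' @return a `GeneticMap` covering positions 0 to 300 Mb (extrapolated
#'   linearly beyond).
#' @export
uniform_genetic_map <- function(rate_cm_per_mb = 1, chrom = "NA") {
  genetic_map(chrom, c(0, 3e8), c(0, 300 * rate_cm_per_mb))
}

#' Load a genetic map from a 3-column text file
#'
#' Columns: chromosome, bp position, cumulative cM; whitespace- or
#' comma-delimited, header optional. When a rate column is also present in
#' source files the cumulative cM column is authoritative; only the first
#' three columns are read.
#'
#' @param path path to the map file.
#' @return a `GeneticMap`.
#' @export
load_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[ \t]+")[[1]]
  header <- length(probe) >= 2L && is.na(suppressWarnings(as.numeric(probe[2])))
  tab <- read.table(path, header = header, sep = sep,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("genetic map needs 3 columns: chrom, bp, cM")
  chr <- unique(as.character(tab[[1]]))
  if (length(chr) != 1L)
    stop("genetic map must cover a single chromosome, found: ",
         paste(chr, collapse = ", "))
  o <- order(as.numeric(tab[[2]]))
  genetic_map(chr, as.numeric(tab[[2]])[o], as.numeric(tab[[3]])[o])
}

#' Write a genetic map as a 3-column text file
#' @param map a `GeneticMap`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "GeneticMap"))
  writeLines(c("chr position_bp map_cm",
               paste(map$chrom,
                     format(map$bp, scientific = FALSE, trim = TRUE),
                     formatC(map$cm, digits = 15, format = "g"))), path)
  invisible(path)
}

#' Convert physical positions to genetic positions
#'
#' Linear interpolation between flanking map nodes; positions beyond either
#' end are extrapolated with the terminal segment's rate. Exact at nodes and
#' non-decreasing in `pos_bp`. With `map = NULL` the uniform 1 cM/Mb fallback
#' is used.
#'
#' @param map a `GeneticMap`, or `NULL` for the uniform fallback.
#' @param pos_bp vector of physical positions (bp).
#' @return vector of genetic positions (cM).
#' @export
bp_to_cm <- function(map, pos_bp) {
  if (is.null(map)) return(as.numeric(pos_bp) / 1e6)
  stopifnot(inherits(map, "GeneticMap"))
  pos_bp <- as.numeric(pos_bp)
  k <- length(map$bp)
  i <- findInterval(pos_bp, map$bp)
  i <- pmin(pmax(i, 1L), k - 1L)       # clamp => terminal-rate extrapolation
  slope <- (map$cm[i + 1L] - map$cm[i]) / (map$bp[i + 1L] - map$bp[i])
  map$cm[i] + slope * (pos_bp - map$bp[i])
}
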