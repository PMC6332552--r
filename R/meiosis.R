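# Meiosis: crossover placement and gamete formation with ancestral-origin
# tracking.
#
# Crossovers live in genetic (cM) coordinates; physical positions enter only
# through bp_to_cm. Each gamete of an individual carries an origin track: a
# partition of the simulated region into segments, each labelled with the
# founder-haplotype identifier it descends from. Tracks make exact IBD
# computation possible without any genotype-based inference.

#' Recombination model parameters
#'
#' Two models are supported: `"no_interference"` (crossovers form a Poisson
#' process of rate 1 per Morgan on the gamete) and `"chi_squared"`, the
#' two-pathway crossover-interference model: chiasmata of the interfering
#' pathway are every (m+1)-th event of a Poisson process of rate
#' `2 (m+1) (1 - p_escape)` per Morgan on the four-strand bundle (a gamma
#' renewal process, made stationary by an equilibrium initial phase), each
#' chiasma passed to the gamete independently with probability 1/2, while a
#' non-interfering escape pathway adds Poisson crossovers of rate `p_escape`
#' per Morgan directly on the gamete. Either `m = 0` or `p_escape = 1`
#' reduces the model to the Poisson model. Expected crossovers per gamete is
#' 1 per Morgan under both models.
#'
#' Defaults `m = 4`, `p_escape = 0.05` are human-scale interference values.
#'
#' @param model `"chi_squared"` or `"no_interference"`.
#' @param m non-negative integer interference parameter.
#' @param p_escape proportion of non-interfering crossovers in `[0, 1]`.
#' @return an object of class `recomb_params`.
#' @export
recomb_params <- function(model = c("chi_squared", "no_interference"),
                          m = 4L, p_escape = 0.05) {
  model <- match.arg(model)
  m <- as.integer(m)
  stopifnot(m >= 0L, p_escape >= 0, p_escape <= 1)
  structure(list(model = model, m = m, p_escape = p_escape),
            class = "recomb_params")
}

#' Crossover positions under the no-interference model
#'
#' @param L_morgan region length in Morgans.
#' @return sorted crossover positions in `[0, L_morgan]` (Morgans).
#' @export
crossovers_poisson <- function(L_morgan) {
  stopifnot(L_morgan >= 0)
  if (L_morgan == 0) return(numeric(0))
  n <- rpois(1L, L_morgan)
  sort(runif(n, 0, L_morgan))
}

#' Crossover positions under the chi-squared interference model
#'
#' See [recomb_params()] for the construction. The interfering gamma renewal
#' process is stationarized exactly: keeping every (m+1)-th event of a
#' Poisson stream starting at the region boundary, with the index of the
#' first kept event uniform on `{1, ..., m+1}`, gives the equilibrium forward
#' recurrence distribution of an Erlang(m+1) renewal process.
#'
#' @param L_morgan region length in Morgans.
#' @param params a [recomb_params()].
#' @return sorted crossover positions on the gamete in `[0, L_morgan]`.
#' @export
crossovers_chisq <- function(L_morgan, params = recomb_params()) {
  stopifnot(L_morgan >= 0, inherits(params, "recomb_params"))
  if (L_morgan == 0) return(numeric(0))
  m <- params$m; p <- params$p_escape
  if (m == 0L || p >= 1) {
    # exact reduction to the Poisson model (total gamete rate 1/Morgan)
    return(crossovers_poisson(L_morgan))
  }
  xo <- numeric(0)
  rate <- 2 * (m + 1) * (1 - p)
  if (rate > 0) {
    nev <- rpois(1L, rate * L_morgan)
    if (nev > 0) {
      ev <- sort(runif(nev, 0, L_morgan))
      first <- sample.int(m + 1L, 1L)       # equilibrium initial phase
      if (first <= nev) {
        chi <- ev[seq(first, nev, by = m + 1L)]
        # each chiasma involves the gamete with probability 1/2
        chi <- chi[runif(length(chi)) < 0.5]
        xo <- c(xo, chi)
      }
    }
  }
  if (p > 0) {
    ne <- rpois(1L, p * L_morgan)
    if (ne > 0) xo <- c(xo, runif(ne, 0, L_morgan))
  }
  sort(xo)
}

draw_crossovers <- function(L_morgan, params) {
  if (params$model == "no_interference") crossovers_poisson(L_morgan)
  else crossovers_chisq(L_morgan, params)
}

# ---- origin tracks ---------------------------------------------------------

# A track partitions [bounds[1], bounds[2]] (cM) into length(src) segments
# separated by `breaks` (sorted, strictly inside the bounds).
new_track <- function(bounds, breaks, src) {
  list(bounds = bounds, breaks = breaks, src = src)
}

# Source identifier of track t at each position (vectorized).
track_source_at <- function(t, pos_cm) {
  t$src[findInterval(pos_cm, t$breaks) + 1L]
}

# Restrict track t to [a, b] (sub-partition, sources preserved).
track_slice <- function(t, a, b) {
  inside <- t$breaks > a & t$breaks < b
  brk <- t$breaks[inside]
  first <- findInterval(a, t$breaks) + 1L
  last <- findInterval(b, t$breaks, left.open = TRUE) + 1L
  new_track(c(a, b), brk, t$src[first:last])
}

# Merge adjacent segments with identical sources.
track_simplify <- function(t) {
  if (length(t$src) <= 1L) return(t)
  same <- t$src[-1L] == t$src[-length(t$src)]
  if (!any(same)) return(t)
  keep <- !same
  new_track(t$bounds, t$breaks[keep], t$src[c(TRUE, keep)])
}

# Splice two parental tracks at crossover positions, starting from
# track `start_phase`.
splice_tracks <- function(t1, t2, crossovers, start_phase) {
  bounds <- t1$bounds
  crossovers <- crossovers[crossovers > bounds[1] & crossovers < bounds[2]]
  if (length(crossovers) == 0L)
    return(if (start_phase == 1L) t1 else t2)
  pts <- c(bounds[1], crossovers, bounds[2])
  tracks <- list(t1, t2)
  phase <- start_phase
  breaks <- numeric(0); src <- integer(0)
  for (i in seq_len(length(pts) - 1L)) {
    piece <- track_slice(tracks[[phase]], pts[i], pts[i + 1L])
    if (i > 1L) breaks <- c(breaks, pts[i])
    breaks <- c(breaks, piece$breaks)
    src <- c(src, piece$src)
    phase <- 3L - phase
  }
  track_simplify(new_track(bounds, breaks, src))
}

# ---- individuals -----------------------------------------------------------

new_individual <- function(id, gamete1, gamete2, track1, track2) {
  structure(list(id = id, gamete1 = gamete1, gamete2 = gamete2,
                 track1 = track1, track2 = track2),
            class = "Individual")
}

#' @exportS3Method base::print
print.Individual <- function(x, ...) {
  cat(sprintf(
    "Individual %s: %d variants, region [%.3f, %.3f] cM, %d+%d segments\n",
    x$id, length(x$gamete1), x$track1$bounds[1], x$track1$bounds[2],
    length(x$track1$src), length(x$track2$src)))
  invisible(x)
}

#' Genotype dosages of an individual
#' @param ind an `Individual`.
#' @return integer vector of ALT-allele dosages (0/1/2) per variant.
#' @export
dosage <- function(ind) ind$gamete1 + ind$gamete2

#' Form one gamete from a parent
#'
#' Copies the parent's gamete `start_phase` up to the first crossover and
#' alternates parental gametes after each crossover. The returned origin
#' track is the corresponding splice of the parent's two tracks, so that the
#' allele at every variant equals the founder-haplotype allele named by the
#' track at that variant's position.
#'
#' @param parent an `Individual`.
#' @param crossovers sorted crossover positions (cM) inside the region.
#' @param start_phase 1 or 2: which parental gamete the new gamete starts on.
#' @param variant_cms genetic positions (cM) of the variants.
#' @return list with elements `alleles` and `track`.
#' @export
make_gamete <- function(parent, crossovers, start_phase, variant_cms) {
  stopifnot(inherits(parent, "Individual"), start_phase %in% c(1L, 2L))
  if (is.unsorted(crossovers)) stop("crossovers must be sorted")
  bounds <- parent$track1$bounds
  crossovers <- crossovers[crossovers > bounds[1] & crossovers < bounds[2]]
  # phase at each variant: start_phase, switching at every crossover
  nswitch <- findInterval(variant_cms, crossovers)
  phase <- ifelse(nswitch %% 2L == 0L, start_phase, 3L - start_phase)
  alleles <- ifelse(phase == 1L, parent$gamete1, parent$gamete2)
  track <- splice_tracks(parent$track1, parent$track2, crossovers,
                         as.integer(start_phase))
  list(alleles = as.integer(alleles), track = track)
}

#' Mate two individuals
#'
#' Performs one independent meiosis per parent (crossovers drawn under
#' `params`, uniformly random start phase) and assembles the offspring:
#' gamete 1 from the father, gamete 2 from the mother. RNG draw order is
#' father crossovers, father phase, mother crossovers, mother phase.
#'
#' @param father,mother `Individual`s defined over the same variant set.
#' @param variant_cms genetic positions (cM) of the variants.
#' @param params a [recomb_params()].
#' @param id identifier for the offspring.
#' @return the offspring `Individual`.
#' @export
mate <- function(father, mother, variant_cms, params = recomb_params(),
                 id = NA_character_) {
  if (length(father$gamete1) != length(mother$gamete1))
    stop("parents are defined over different variant sets")
  if (any(abs(father$track1$bounds - mother$track1$bounds) > 1e-9))
    stop("parents are defined over different regions")
  bounds <- father$track1$bounds
  L <- (bounds[2] - bounds[1]) / 100     # cM -> Morgans
  xo_f <- bounds[1] + 100 * draw_crossovers(L, params)
  ph_f <- sample.int(2L, 1L)
  gam_f <- make_gamete(father, xo_f, ph_f, variant_cms)
  xo_m <- bounds[1] + 100 * draw_crossovers(L, params)
  ph_m <- sample.int(2L, 1L)
  gam_m <- make_gamete(mother, xo_m, ph_m, variant_cms)
  new_individual(id, gam_f$alleles, gam_m$alleles, gam_f$track, gam_m$track)
}
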