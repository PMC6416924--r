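#' Recombination-protection intervals and chromosome coverage
#'
#' Inversion breakpoints suppress meiotic recombination over roughly 2 Mbp
#' on each side (the D. melanogaster estimate, applied genome-agnostically).
#' Each cut at 0-based position c therefore protects the interval
#' \[max(0, c - flank), min(L, c + flank)); overlapping windows from nearby
#' cuts are merged, and coverage is the protected fraction of the
#' chromosome. Windows are clipped at chromosome ends: a cut at position 0
#' protects only \code{flank} bp.
#'
#' Interval union goes through [IRanges::reduce]; the package also ships an
#' independent per-basepair mask implementation ([maskCoverage()]) used as a
#' cross-check.
#'
#' @param cutPositions 0-based cut coordinates (any order, duplicates
#'   allowed).
#' @param chromLength chromosome length in bp (> 0).
#' @param flank protection half-window in bp, default 2,000,000.
#' @param chrom chromosome id recorded in the profile.
#' @return a [CoverageProfile-class].
#' @examples
#' p <- protectedIntervals(2e6, 4e6)        # one cut dead-center
#' coverageFraction(p)                       # 1.0
#' coverageFraction(protectedIntervals(c(1e6, 1.1e6), 1e7))  # 0.31
#' @export
protectedIntervals <- function(cutPositions, chromLength, flank = 2e6,
                               chrom = NA_character_) {
  if (chromLength <= 0)
    gbStop("gb_bad_interval", "chromosome length must be positive")
  cuts <- sort(unique(as.numeric(cutPositions)))
  if (length(cuts) && (min(cuts) < 0 || max(cuts) >= chromLength))
    gbStop("gb_cut_out_of_bounds",
           "cut position outside [0, %d)", as.integer(chromLength))
  if (length(cuts) == 0L) {
    return(new("CoverageProfile", chrom = chrom, chromLength = chromLength,
               cuts = numeric(0), ranges = IRanges::IRanges(),
               coverage = 0, flank = flank))
  }
  lo <- pmax(0, cuts - flank)            # 0-based half-open [lo, hi)
  hi <- pmin(chromLength, cuts + flank)
  r <- IRanges::reduce(IRanges::IRanges(start = lo + 1, end = hi))
  new("CoverageProfile", chrom = chrom, chromLength = chromLength,
      cuts = cuts, ranges = r,
      coverage = sum(IRanges::width(r)) / chromLength, flank = flank)
}

#' Ideal cut count for a chromosome
#'
#' With 4 Mbp protected around each breakpoint (2 Mbp per side), the fewest
#' cuts that could protect an L-bp chromosome is \code{ceiling(L / window)}.
#' This is used as an upper bound when filtering bins -- more cuts than the
#' ideal cannot improve full-coverage spacing and inflate off-target
#' exposure -- and is the count at which perfectly even spacing reaches
#' coverage 1.
#'
#' @param chromLength chromosome length in bp (> 0).
#' @param window total protected span per breakpoint, default 4,000,000 bp.
#' @return integer cut count.
#' @examples
#' idealCutCount(4e6)    # 1
#' idealCutCount(15e6)   # 4
#' @export
idealCutCount <- function(chromLength, window = 4e6) {
  if (chromLength <= 0)
    gbStop("gb_bad_interval", "chromosome length must be positive")
  as.integer(ceiling(chromLength / window))
}

#' Filter seed bins by cut count and coverage
#'
#' A bin survives iff its merged cut count does not exceed the ideal cut
#' count of its chromosome AND its coverage is at least
#' \code{minCoverage}. Both thresholds are inclusive-\code{>=} for
#' survival; strict excess over the ideal count rejects. Rejection tallies
#' are attached as attributes \code{"rejected_cut_count"} and
#' \code{"rejected_coverage"}.
#'
#' @param bins seed bins (see [buildSeedBins()]).
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param flank protection half-window in bp, default 2,000,000.
#' @param window per-breakpoint span for [idealCutCount()]; defaults to
#'   \code{2 * flank} so scaled test genomes stay self-consistent.
#' @param minCoverage minimum coverage fraction, default 0.70.
#' @return surviving bins with added columns \code{n_cuts} and
#'   \code{coverage}.
#' @export
filterBinsByCoverage <- function(bins, chromLengths, flank = 2e6,
                                 window = NULL, minCoverage = 0.70) {
  if (is.null(window)) window <- 2 * flank
  if (nrow(bins) == 0L) {
    bins$n_cuts <- integer(0); bins$coverage <- numeric(0)
    attr(bins, "rejected_cut_count") <- 0L
    attr(bins, "rejected_coverage") <- 0L
    return(bins)
  }
  missing <- setdiff(unique(bins$chrom), names(chromLengths))
  if (length(missing))
    gbStop("gb_unknown_chrom", "no length for chromosome(s): %s",
           paste(missing, collapse = ", "))
  nCuts <- vapply(bins$cut_positions, length, integer(1))
  maxCuts <- vapply(bins$chrom, function(ch)
    idealCutCount(chromLengths[[ch]], window), integer(1))
  okCuts <- nCuts <= maxCuts
  # coverage is only needed for bins passing the cut-count bound; the
  # ubiquitous single-cut case collapses to clipped-window arithmetic
  cov <- rep(NA_real_, nrow(bins))
  lens <- unname(chromLengths[bins$chrom])
  one <- okCuts & nCuts == 1L
  if (any(one)) {
    c0 <- vapply(bins$cut_positions[one], `[`, numeric(1), 1L)
    cov[one] <- (pmin(lens[one], c0 + flank) - pmax(0, c0 - flank)) /
      lens[one]
  }
  for (i in which(okCuts & nCuts > 1L)) {
    cov[i] <- coverageFraction(protectedIntervals(
      bins$cut_positions[[i]], lens[i], flank = flank,
      chrom = bins$chrom[i]))
  }
  bins$n_cuts <- nCuts
  bins$coverage <- cov
  okCov <- !is.na(cov) & cov >= minCoverage
  surviving <- bins[okCuts & okCov, ]
  attr(surviving, "rejected_cut_count") <- sum(!okCuts)
  attr(surviving, "rejected_coverage") <- sum(okCuts & !okCov)
  message(sprintf("coverage filter: %d bin(s) over ideal cut count, %d below coverage %.2f",
                  sum(!okCuts), sum(okCuts & !okCov), minCoverage))
  surviving
}
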