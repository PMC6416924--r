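#' Extract the PAM-proximal seed of a protospacer
#'
#' The seed is the \code{seedLength} nucleotides of the 20-nt protospacer
#' closest to the PAM (default 18, i.e. the protospacer minus its two
#' PAM-distal bases). Mismatch tolerance of Cas9 decreases toward the PAM,
#' so sites sharing this seed are treated as cut-equivalent: they are binned
#' together on their own chromosome and any exact recurrence of the seed on
#' another chromosome disqualifies the guide.
#'
#' @param protospacer 20-nt protospacer sequence(s), 5'->3'.
#' @param seedLength number of PAM-proximal bases, in 1..20 (default 18).
#' @return character vector of seeds.
#' @examples
#' extractSeed("TTTAACCCACGGTATACCGC")       # "TAACCCACGGTATACCGC"
#' extractSeed("TTTAACCCACGGTATACCGC", 20)   # whole protospacer
#' @export
extractSeed <- function(protospacer, seedLength = 18L) {
  if (seedLength > 20L || seedLength < 1L)
    gbStop("gb_bad_seed_length", "seedLength must be in 1..20, got %s",
           seedLength)
  substr(protospacer, 21L - seedLength, 20L)
}

#' Group target sites into per-chromosome seed bins
#'
#' One bin per (chromosome, seed) pair. Each bin merges the cut locations of
#' all member sites (sorted, unique) and carries a representative 23-mer:
#' the most frequent full site among members, ties broken lexicographically.
#' Member 30-mer contexts are retained for on-target scoring.
#'
#' @param sites a [SiteStore-class] or site data.frame.
#' @param seedLength seed length passed to [extractSeed()].
#' @return a [data.table::data.table] with columns chrom, seed, n_sites,
#'   representative, cut_positions (list of sorted 0-based integers),
#'   contexts (list of member 30-mers, NA where unscorable), sorted by
#'   chrom then seed.
#' @export
buildSeedBins <- function(sites, seedLength = 18L) {
  df <- if (is(sites, "SiteStore")) siteFrame(sites) else sites
  dt <- data.table::as.data.table(df)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      chrom = character(0), seed = character(0), n_sites = integer(0),
      representative = character(0), cut_positions = list(),
      contexts = list()))
  }
  dt[, seed := extractSeed(substr(full_site, 1L, 20L), seedLength)]
  bins <- dt[, .(
    n_sites = .N,
    cut_positions = list(sort(unique(cut_position))),
    contexts = list(context_30mer)
  ), by = .(chrom, seed)]
  # representative = most frequent full 23-mer, ties lexicographic; picked
  # vectorized (first row per bin after ordering by count then sequence)
  cnt <- dt[, .N, by = .(chrom, seed, full_site)]
  data.table::setorder(cnt, chrom, seed, -N, full_site)
  rep1 <- cnt[cnt[, .I[1L], by = .(chrom, seed)]$V1,
              .(chrom, seed, representative = full_site)]
  bins <- rep1[bins, on = c("chrom", "seed")]
  data.table::setorder(bins, chrom, seed)
  data.table::setcolorder(bins, c("chrom", "seed", "n_sites",
                                  "representative", "cut_positions",
                                  "contexts"))
  bins[]
}

#' Build a genome-wide seed index
#'
#' Single-pass index over all scanned sites: for every seed, the
#' chromosomes, cut positions and strands at which it occurs. The total
#' occurrence count equals the scanned site count.
#'
#' @inheritParams buildSeedBins
#' @return a [SeedIndex-class].
#' @export
buildSeedIndex <- function(sites, seedLength = 18L) {
  df <- if (is(sites, "SiteStore")) siteFrame(sites) else sites
  dt <- data.table::as.data.table(df)
  if (nrow(dt) == 0L) {
    occ <- data.table::data.table(seed = character(0), chrom = character(0),
                                  cut_position = integer(0),
                                  strand = character(0))
  } else {
    occ <- dt[, .(seed = extractSeed(substr(full_site, 1L, 20L), seedLength),
                  chrom, cut_position, strand)]
  }
  data.table::setkey(occ, seed)
  new("SeedIndex", occurrences = occ, nsites = nrow(occ))
}

#' Reject bins whose seed recurs on another chromosome
#'
#' A guide whose 18-bp seed occurs exactly on a different chromosome would
#' cut there regardless of its PAM-distal bases, so the whole bin is
#' discarded. Rejection is exact-match only; near matches are handled later
#' by CFD off-target scoring. Per-chromosome rejection tallies are logged
#' and attached as the \code{"rejected_by_chrom"} attribute.
#'
#' @param bins seed bins from [buildSeedBins()].
#' @param index a [SeedIndex-class] built over the whole genome.
#' @return the surviving bins.
#' @export
rejectCrossChromosomeBins <- function(bins, index) {
  if (nrow(bins) == 0L) {
    attr(bins, "rejected_by_chrom") <- integer(0)
    return(bins)
  }
  occ <- index@occurrences
  chromsPerSeed <- occ[, .(nchrom = data.table::uniqueN(chrom)), by = seed]
  multi <- chromsPerSeed[nchrom > 1L, seed]
  rejected <- bins[bins$seed %in% multi, ]
  surviving <- bins[!bins$seed %in% multi, ]
  tally <- if (nrow(rejected))
    vapply(split(rejected$seed, rejected$chrom), length, integer(1))
  else integer(0)
  for (ch in names(tally))
    message(sprintf("seed rejection: %s: %d bin(s) with cross-chromosome seeds",
                    ch, tally[[ch]]))
  attr(surviving, "rejected_by_chrom") <- tally
  surviving
}
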