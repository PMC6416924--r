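#' @import methods
#' @importFrom stats plogis setNames runif rnorm
#' @importFrom utils head read.delim write.table
NULL

SITE_COLUMNS <- c("chrom", "strand", "genomic_start", "cut_position",
                  "full_site", "context_30mer")
SITESTORE_VERSION <- "guideBalancer SiteStore v1"

#' SiteStore: all scanned Cas9 target sites, in memory or spilled to disk
#'
#' Holds every potential target sequence (PTS) found by the PAM scanner: a
#' 20-nt protospacer followed by an NGG PAM, on either strand, with its
#' 0-based plus-strand start, blunt-cut coordinate and 30-nt scoring context.
#' When the number of sites exceeds the configured in-memory budget the store
#' transparently spills to a documented tab-delimited temporary file (header
#' line \code{# guideBalancer SiteStore v1}) so that whole-genome scans are
#' not bounded by RAM.
#'
#' @slot frame data.frame of sites, or NULL when file-backed.
#' @slot path path of the on-disk spill file ("" when in memory).
#' @slot n total number of sites.
#' @slot chroms chromosome ids present, in scan order.
#'
#' @seealso [scanGenome()], [spillSites()], [siteFrame()]
#' @export
setClass("SiteStore",
  representation(frame = "ANY", path = "character", n = "integer",
                 chroms = "character"))

setValidity("SiteStore", function(object) {
  if (nzchar(object@path) && !file.exists(object@path))
    return("spill file does not exist")
  if (!nzchar(object@path) && !is.data.frame(object@frame))
    return("in-memory store requires a data.frame")
  if (is.data.frame(object@frame) &&
      !all(SITE_COLUMNS %in% names(object@frame)))
    return("site frame is missing canonical columns")
  TRUE
})

#' SeedIndex: genome-wide lookup of 18-bp seed occurrences
#'
#' Maps every seed (the PAM-proximal 18 nt of a protospacer) to its
#' occurrences across all chromosomes. Used to reject guides whose seed
#' recurs outside the target chromosome, since such sites would be cut
#' regardless of PAM-distal mismatches.
#'
#' @slot occurrences data.table with columns seed, chrom, cut_position,
#'   strand, keyed by seed.
#' @slot nsites total number of occurrences (equals the scanned site count).
#' @export
setClass("SeedIndex",
  representation(occurrences = "ANY", nsites = "integer"))

setValidity("SeedIndex", function(object) {
  occ <- object@occurrences
  if (!is.data.frame(occ)) return("occurrences must be a data frame")
  if (nrow(occ) != object@nsites) return("occurrence count mismatch")
  TRUE
})

#' CoverageProfile: recombination-protection intervals for one chromosome
#'
#' Each predicted cut suppresses recombination within a flank (default 2 Mbp)
#' on each side; overlapping windows are merged and clipped to the chromosome.
#' Coverage is the protected fraction of the chromosome and is the numerator
#' of the SSV ranking metric.
#'
#' @slot chrom chromosome id.
#' @slot chromLength chromosome length in bp.
#' @slot cuts sorted 0-based cut coordinates.
#' @slot ranges merged protected intervals as an [IRanges::IRanges]
#'   (1-based closed, the Bioconductor convention).
#' @slot coverage protected fraction in [0, 1].
#' @slot flank protection half-window in bp.
#' @export
setClass("CoverageProfile",
  representation(chrom = "character", chromLength = "numeric",
                 cuts = "numeric", ranges = "ANY", coverage = "numeric",
                 flank = "numeric"))

setValidity("CoverageProfile", function(object) {
  r <- object@ranges
  if (length(r)) {
    if (is.unsorted(IRanges::start(r))) return("intervals not sorted")
    if (length(r) > 1L &&
        any(IRanges::start(r)[-1L] <= IRanges::end(r)[-length(r)]))
      return("intervals not disjoint")
    if (min(IRanges::start(r)) < 1L ||
        max(IRanges::end(r)) > object@chromLength)
      return("intervals exceed chromosome bounds")
  }
  if (object@coverage < 0 || object@coverage > 1)
    return("coverage outside [0, 1]")
  if (length(object@cuts) == 0L && object@coverage != 0)
    return("coverage must be 0 with no cuts")
  TRUE
})

#' ScoreTables: CFD mismatch penalties, PAM penalties and on-target weights
#'
#' Bundles the three lookup tables the scoring stage needs: per-position,
#' per-base-pair CFD mismatch penalties over the 20-nt spacer (positions
#' counted 1-20 from the PAM-distal end), penalties for the PAM bases at
#' positions 2-3 (GG = 1), and the logistic position-weight coefficients of
#' the on-target model. Matched bases always score 1; all penalties lie in
#' [0, 1].
#'
#' @slot cfd named numeric; names are "pos|guide|target", e.g. "17|A|G".
#' @slot pam named numeric over the 16 PAM 2-mers.
#' @slot weights named numeric of on-target coefficients: "(Intercept)",
#'   "gc_count", and positional terms "p<i>_<base>" over the 30-mer context.
#' @slot origin character tag describing where the tables came from.
#' @export
setClass("ScoreTables",
  representation(cfd = "numeric", pam = "numeric", weights = "numeric",
                 origin = "character"))

setValidity("ScoreTables", function(object) {
  if (any(object@cfd < 0 | object@cfd > 1)) return("CFD penalties outside [0, 1]")
  if (any(object@pam < 0 | object@pam > 1)) return("PAM penalties outside [0, 1]")
  if (!is.na(object@pam["GG"]) && object@pam["GG"] != 1)
    return("GG PAM penalty must be 1")
  TRUE
})

#' BalancerRun: results of one end-to-end guide-design run
#'
#' Container returned by [runBalancerDesign()]: the ranked guide reports, a
#' manifest recording every stage's input/output counts and all effective
#' parameters, and the configuration used. Reruns with identical inputs and
#' configuration are bit-identical.
#'
#' @slot reports data.frame of ranked guides (one row per reported sgRNA).
#' @slot manifest list of stage counts and effective parameters.
#' @slot config the [balancerConfig()] list used.
#' @export
setClass("BalancerRun",
  representation(reports = "data.frame", manifest = "list", config = "list"))
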