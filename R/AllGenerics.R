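#' @rdname SiteStore-class
#' @param object,x a \code{SiteStore}.
#' @export
setGeneric("siteCount", function(x) standardGeneric("siteCount"))

#' @rdname SiteStore-class
#' @export
setMethod("siteCount", "SiteStore", function(x) x@n)

#' Materialize sites from a store
#'
#' Returns the canonical site data.frame (columns chrom, strand,
#' genomic_start, cut_position, full_site, context_30mer), reading the spill
#' file when the store is file-backed. Coordinates are 0-based.
#'
#' @param x a [SiteStore-class].
#' @param chrom optional chromosome id(s) to restrict to.
#' @return data.frame of sites in original scan order.
#' @export
setGeneric("siteFrame", function(x, chrom = NULL) standardGeneric("siteFrame"))

#' @rdname siteFrame
#' @export
setMethod("siteFrame", "SiteStore", function(x, chrom = NULL) {
  df <- if (nzchar(x@path)) {
    as.data.frame(data.table::fread(
      x@path, sep = "\t", header = TRUE, skip = 1L,
      colClasses = list(character = c("chrom", "strand", "full_site",
                                      "context_30mer"),
                        integer = c("genomic_start", "cut_position")),
      na.strings = "NA"))
  } else {
    x@frame
  }
  if (!is.null(chrom)) df <- df[df$chrom %in% chrom, , drop = FALSE]
  rownames(df) <- NULL
  df
})

setMethod("show", "SiteStore", function(object) {
  backing <- if (nzchar(object@path)) sprintf("on disk (%s)", object@path)
             else "in memory"
  cat(sprintf("SiteStore: %d sites on %d chromosome(s), %s\n",
              object@n, length(object@chroms), backing))
})

#' Look up all genomic occurrences of a seed
#'
#' @param x a [SeedIndex-class].
#' @param seed 18-nt seed sequence(s).
#' @return data.frame of occurrences (seed, chrom, cut_position, strand).
#' @export
setGeneric("lookupSeed", function(x, seed) standardGeneric("lookupSeed"))

#' @rdname lookupSeed
#' @export
setMethod("lookupSeed", "SeedIndex", function(x, seed) {
  occ <- x@occurrences
  sel <- occ[["seed"]] %in% seed   # plain vector: avoids data.table NSE capture
  as.data.frame(occ[sel, , drop = FALSE])
})

setMethod("show", "SeedIndex", function(object) {
  cat(sprintf("SeedIndex: %d occurrences of %d distinct seeds\n",
              object@nsites, length(unique(object@occurrences$seed))))
})

#' @rdname CoverageProfile-class
#' @param x a \code{CoverageProfile}.
#' @export
setGeneric("coverageFraction", function(x) standardGeneric("coverageFraction"))

#' @rdname CoverageProfile-class
#' @export
setMethod("coverageFraction", "CoverageProfile", function(x) x@coverage)

#' @rdname CoverageProfile-class
#' @export
setGeneric("protectedRanges", function(x) standardGeneric("protectedRanges"))

#' @rdname CoverageProfile-class
#' @export
setMethod("protectedRanges", "CoverageProfile", function(x) x@ranges)

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf(
    "CoverageProfile of %s (%d bp): %d cut(s), %d protected interval(s), coverage %.1f%%\n",
    object@chrom, as.integer(object@chromLength), length(object@cuts),
    length(object@ranges), 100 * object@coverage))
})

setMethod("show", "ScoreTables", function(object) {
  cat(sprintf(
    "ScoreTables [%s]: %d CFD mismatch penalties, %d PAM penalties, %d on-target coefficients\n",
    object@origin, length(object@cfd), length(object@pam),
    length(object@weights)))
})

#' @rdname BalancerRun-class
#' @param x a \code{BalancerRun}.
#' @export
setGeneric("guideReports", function(x) standardGeneric("guideReports"))

#' @rdname BalancerRun-class
#' @export
setMethod("guideReports", "BalancerRun", function(x) x@reports)

#' @rdname BalancerRun-class
#' @export
setGeneric("runManifest", function(x) standardGeneric("runManifest"))

#' @rdname BalancerRun-class
#' @export
setMethod("runManifest", "BalancerRun", function(x) x@manifest)

setMethod("show", "BalancerRun", function(object) {
  counts <- object@manifest$counts
  cat("BalancerRun\n")
  cat(sprintf("  sites scanned: %d | seed bins: %d | reported guides: %d\n",
              counts$sites_scanned, counts$bins_formed,
              counts$reports_emitted))
  if (nrow(object@reports)) {
    top <- object@reports[1L, ]
    cat(sprintf("  top guide: %s on %s (SSV %.3f, coverage %.0f%%)\n",
                top$sgrna_23mer, top$chrom, top$ssv, 100 * top$coverage))
  }
})
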