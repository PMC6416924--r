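#' Build a validated run configuration
#'
#' Collects every tunable parameter of the design pipeline with its
#' default. All threshold comparisons downstream are \code{>=}-inclusive
#' for survival. The per-breakpoint protection window used for the ideal
#' cut count is \code{2 * flank}, so scaled-down genomes (e.g. flank 2 kb)
#' stay geometrically self-consistent.
#'
#' @param genome path to the genome FASTA, or a
#'   [Biostrings::DNAStringSet] already loaded.
#' @param genes optional path to a BED3+ gene-interval file (annotation
#'   only; never affects scoring or rank), or a
#'   [GenomicRanges::GRanges].
#' @param pam degenerate PAM 3-mer, default "NGG".
#' @param seedLength PAM-proximal seed length, default 18.
#' @param flank recombination-protection half-window in bp, default
#'   2,000,000.
#' @param coverageThreshold minimum chromosome coverage, default 0.70.
#' @param onTargetThreshold minimum bin-average on-target score, default
#'   0.5.
#' @param cfdThreshold minimum off-target CFD counted into soCFD, default
#'   0.2.
#' @param maxMismatches maximum spacer mismatches in the off-target search,
#'   default 4.
#' @param topN guides reported per chromosome, default 5.
#' @param includeOffTargets when FALSE, SSV reduces to coverage.
#' @param scoreTables a [ScoreTables-class]; default
#'   [defaultScoreTables()].
#' @param neutralOnTarget score for unscorable (end-truncated) sites.
#' @param tmpdir directory for site spill files.
#' @param memoryBudgetSites maximum sites held in memory before spilling.
#' @return a classed list of validated parameters.
#' @export
balancerConfig <- function(genome, genes = NULL, pam = "NGG",
                           seedLength = 18L, flank = 2e6,
                           coverageThreshold = 0.70,
                           onTargetThreshold = 0.5, cfdThreshold = 0.2,
                           maxMismatches = 4L, topN = 5L,
                           includeOffTargets = TRUE,
                           scoreTables = defaultScoreTables(),
                           neutralOnTarget = 0.5, tmpdir = tempdir(),
                           memoryBudgetSites = Inf) {
  pam <- validatePam(pam)
  for (thr in c(coverageThreshold, onTargetThreshold, cfdThreshold))
    if (thr < 0 || thr > 1)
      gbStop("gb_bad_config", "thresholds must lie in [0, 1]")
  if (flank <= 0 || seedLength < 1L || seedLength > 20L || topN < 1L ||
      maxMismatches < 0L)
    gbStop("gb_bad_config", "invalid flank/seedLength/topN/maxMismatches")
  structure(list(
    genome = genome, genes = genes, pam = pam,
    seedLength = as.integer(seedLength), flank = flank,
    window = 2 * flank, coverageThreshold = coverageThreshold,
    onTargetThreshold = onTargetThreshold, cfdThreshold = cfdThreshold,
    maxMismatches = as.integer(maxMismatches), topN = as.integer(topN),
    includeOffTargets = isTRUE(includeOffTargets),
    scoreTables = scoreTables, neutralOnTarget = neutralOnTarget,
    tmpdir = tmpdir, memoryBudgetSites = memoryBudgetSites),
    class = "BalancerConfig")
}

#' Run the full guide-design pipeline
#'
#' Executes the whole cascade: scan every chromosome for NGG sites (spilling
#' to disk past the memory budget), bin sites by 18-bp seed, reject bins
#' whose seed recurs on another chromosome, filter by cut count and
#' coverage, filter by average on-target score, score remaining bins'
#' off-targets with CFD, and rank by SSV. The returned
#' [BalancerRun-class] carries the ranked reports and a manifest with
#' every stage's input/output counts and all effective parameters, from
#' which the whole filtering funnel can be re-derived. The pipeline is
#' deterministic: reruns with identical inputs and configuration are
#' bit-identical.
#'
#' @param config a [balancerConfig()].
#' @param quiet suppress stage messages.
#' @return a [BalancerRun-class].
#' @export
runBalancerDesign <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "BalancerConfig"))
  run <- function(expr) if (quiet) suppressMessages(expr) else expr

  genome <- if (is.character(config$genome)) readGenome(config$genome)
            else config$genome
  chromLengths <- setNames(as.numeric(Biostrings::width(genome)),
                           names(genome))

  store <- run(scanGenome(genome, pam = config$pam,
                          budget = config$memoryBudgetSites,
                          tmpdir = config$tmpdir))
  bins <- buildSeedBins(store, seedLength = config$seedLength)
  index <- buildSeedIndex(store, seedLength = config$seedLength)
  kept <- run(rejectCrossChromosomeBins(bins, index))
  nCross <- sum(attr(kept, "rejected_by_chrom"))

  covKept <- run(filterBinsByCoverage(
    kept, chromLengths, flank = config$flank, window = config$window,
    minCoverage = config$coverageThreshold))
  onKept <- run(filterBinsOnTarget(
    covKept, config$scoreTables, minAvg = config$onTargetThreshold,
    neutral = config$neutralOnTarget))

  siteDf <- siteFrame(store)
  nHits <- 0L
  reports <- if (nrow(onKept)) {
    rows <- lapply(seq_len(nrow(onKept)), function(i) {
      b <- onKept[i, ]
      guide <- substr(b$representative, 1L, 20L)
      socfd <- setNames(numeric(0), character(0))
      if (config$includeOffTargets) {
        hits <- findOffTargets(guide, b$chrom, siteDf,
                               tables = config$scoreTables,
                               maxMismatches = config$maxMismatches)
        nHits <<- nHits + nrow(hits)
        socfd <- soCfdSums(hits, cfdThreshold = config$cfdThreshold,
                           chromosomes = setdiff(names(genome), b$chrom))
      }
      denom <- 1 + sum(socfd)
      data.frame(
        chrom = b$chrom, sgrna_23mer = b$representative, seed = b$seed,
        ssv = ssvScore(b$coverage, socfd,
                       includeOffTargets = config$includeOffTargets),
        avg_on_target = b$avg_on_target,
        off_target_denominator = if (config$includeOffTargets) denom else 1,
        n_cuts = b$n_cuts, coverage = b$coverage,
        cut_positions = I(b$cut_positions),
        genic_breakpoints = NA_integer_, stringsAsFactors = FALSE)
    })
    rankGuides(do.call(rbind, rows), topN = config$topN,
               chromOrder = names(genome))
  } else {
    warning("no guides survived filtering; report is empty")
    r <- data.frame(chrom = character(0), sgrna_23mer = character(0),
                    seed = character(0), ssv = numeric(0),
                    avg_on_target = numeric(0),
                    off_target_denominator = numeric(0),
                    n_cuts = integer(0), coverage = numeric(0),
                    cut_positions = I(list()),
                    genic_breakpoints = integer(0))
    r$rank <- integer(0)
    r
  }

  if (!is.null(config$genes)) {
    genesGr <- if (is.character(config$genes))
      readGeneIntervals(config$genes, genome) else config$genes
    reports <- annotateBreakpoints(reports, genesGr)
  }

  manifest <- list(
    parameters = list(
      pam = config$pam, seed_length = config$seedLength,
      flank_bp = config$flank, window_bp = config$window,
      coverage_threshold = config$coverageThreshold,
      on_target_threshold = config$onTargetThreshold,
      cfd_threshold = config$cfdThreshold,
      max_mismatches = config$maxMismatches, top_n = config$topN,
      include_offtargets = config$includeOffTargets,
      score_tables = config$scoreTables@origin),
    chromosomes = lapply(seq_along(chromLengths), function(i)
      list(id = names(chromLengths)[i], length = chromLengths[[i]],
           ideal_cut_count = idealCutCount(chromLengths[[i]],
                                           config$window))),
    counts = list(
      sites_scanned = siteCount(store),
      bins_formed = nrow(bins),
      bins_rejected_cross_chromosome = nCross,
      bins_rejected_cut_count = attr(covKept, "rejected_cut_count"),
      bins_rejected_coverage = attr(covKept, "rejected_coverage"),
      bins_rejected_on_target = attr(onKept, "rejected_on_target"),
      offtarget_hits_scored = nHits,
      reports_emitted = nrow(reports)))

  new("BalancerRun", reports = reports, manifest = manifest,
      config = unclass(config)["genome" != names(unclass(config))])
}

#' Annotate reported breakpoints as genic or intergenic
#'
#' Counts, for each reported guide, how many of its cut positions fall
#' inside any gene interval. Annotation only: SSV and ranking are never
#' altered.
#'
#' @param reports guide report data.frame with a \code{cut_positions} list
#'   column (0-based).
#' @param genes a [GenomicRanges::GRanges] of gene intervals (from
#'   [readGeneIntervals()]).
#' @return the reports with \code{genic_breakpoints} filled in.
#' @export
annotateBreakpoints <- function(reports, genes) {
  if (nrow(reports) == 0L) return(reports)
  reports$genic_breakpoints <- vapply(seq_len(nrow(reports)), function(i) {
    cuts <- reports$cut_positions[[i]]
    if (length(cuts) == 0L) return(0L)
    gr <- GenomicRanges::GRanges(
      reports$chrom[i], IRanges::IRanges(start = cuts + 1L, width = 1L))
    sum(IRanges::overlapsAny(gr, genes))
  }, integer(1))
  reports
}
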