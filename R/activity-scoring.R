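#' On-target efficiency score of a 30-mer context
#'
#' Pluggable on-target model; the default is a logistic position-weight
#' model over the 30-nt context (4 nt upstream + protospacer + PAM + 3 nt
#' downstream) plus a GC-count feature over the protospacer (context
#' positions 5-24):
#' score = logistic(intercept + sum_i w(i, base_i) + w_gc * GC count).
#' Sites flagged unscorable (NA context, e.g. near chromosome ends) receive
#' the neutral score. Deterministic, in [0, 1], and a function of the
#' context and tables only.
#'
#' @param context character vector of 30-mers (NA allowed).
#' @param tables a [ScoreTables-class].
#' @param neutral score assigned to unscorable sites, default 0.5.
#' @return numeric scores in [0, 1].
#' @export
onTargetScore <- function(context, tables = defaultScoreTables(),
                          neutral = 0.5) {
  scores <- rep(neutral, length(context))
  ok <- !is.na(context)
  if (!any(ok)) return(scores)
  if (any(nchar(context[ok]) != 30L))
    gbStop("gb_bad_context", "on-target context must be 30 nt")
  w <- tables@weights
  ctx <- context[ok]
  chars <- matrix(unlist(strsplit(ctx, "")), nrow = 30L)
  keys <- matrix(paste0("p", seq_len(30L), "_", chars), nrow = 30L)
  coef <- matrix(w[keys], nrow = 30L)
  coef[is.na(coef)] <- 0
  lin <- colSums(coef)
  intercept <- if ("(Intercept)" %in% names(w)) w[["(Intercept)"]] else 0
  gcW <- if ("gc_count" %in% names(w)) w[["gc_count"]] else 0
  if (gcW != 0) {
    proto <- chars[5:24, , drop = FALSE]
    lin <- lin + gcW * colSums(proto == "G" | proto == "C")
  }
  scores[ok] <- plogis(intercept + lin)
  scores
}

#' Filter seed bins by average on-target efficiency
#'
#' The bin average is the arithmetic mean of its member sites' on-target
#' scores; bins with average below \code{minAvg} are removed (survival is
#' \code{>=}-inclusive). The rejection tally is attached as attribute
#' \code{"rejected_on_target"}.
#'
#' @param bins seed bins carrying member \code{contexts}.
#' @param tables a [ScoreTables-class].
#' @param minAvg minimum average score, default 0.5.
#' @param neutral neutral score for unscorable members.
#' @return surviving bins with added column \code{avg_on_target}.
#' @export
filterBinsOnTarget <- function(bins, tables = defaultScoreTables(),
                               minAvg = 0.5, neutral = 0.5) {
  if (nrow(bins) == 0L) {
    bins$avg_on_target <- numeric(0)
    attr(bins, "rejected_on_target") <- 0L
    return(bins)
  }
  avg <- vapply(bins$contexts, function(ctx)
    mean(onTargetScore(ctx, tables, neutral = neutral)), numeric(1))
  bins$avg_on_target <- avg
  surviving <- bins[avg >= minAvg, ]
  attr(surviving, "rejected_on_target") <- sum(avg < minAvg)
  message(sprintf("on-target filter: %d bin(s) below average %.2f",
                  sum(avg < minAvg), minAvg))
  surviving
}

#' CFD score of a guide against a near-match target
#'
#' Cutting Frequency Determination: the product over mismatched spacer
#' positions of the penalty for (position, guide base, target base), times
#' the penalty for the target PAM bases 2-3. Positions are counted 1-20
#' from the PAM-distal end, so position 20 abuts the PAM. 1 means the
#' target is cut as efficiently as a perfect match (identical sequences
#' with a GG PAM), 0 means no predicted activity.
#'
#' @param guide 20-nt guide protospacer.
#' @param target 20-nt target protospacer(s); vectorized.
#' @param pam2 target PAM 2-mer(s) (bases 2-3), default "GG"; recycled.
#' @param tables a [ScoreTables-class]; must cover every mismatch queried.
#' @return numeric CFD scores in [0, 1].
#' @examples
#' t <- makeScoreTables("uniform", penalty = 0.5)
#' cfdScore("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT", tables = t)  # 1
#' cfdScore("ACGTACGTACGTACGTACGT", "CCGTACGTACGTACGTACGT", tables = t)  # 0.5
#' @export
cfdScore <- function(guide, target, pam2 = "GG",
                     tables = defaultScoreTables()) {
  stopifnot(length(guide) == 1L)
  if (nchar(guide) != 20L || any(nchar(target) != 20L))
    gbStop("gb_bad_context", "guide and target must be 20 nt")
  pam2 <- rep_len(pam2, length(target))
  g <- strsplit(guide, "")[[1]]
  tmat <- matrix(unlist(strsplit(target, "")), nrow = 20L)
  vapply(seq_along(target), function(i) {
    mm <- which(tmat[, i] != g)
    p <- 1
    if (length(mm)) {
      keys <- cfdKey(mm, g[mm], tmat[mm, i])
      pen <- tables@cfd[keys]
      if (anyNA(pen))
        gbStop("gb_missing_cfd_entry", "no CFD penalty for %s",
               paste(keys[is.na(pen)], collapse = ", "))
      p <- prod(pen)
    }
    pamPen <- tables@pam[pam2[i]]
    if (is.na(pamPen))
      gbStop("gb_missing_cfd_entry", "no PAM penalty for %s", pam2[i])
    unname(p * pamPen)
  }, numeric(1))
}

#' Find off-target sites of a guide on other chromosomes
#'
#' Compares the guide protospacer against every scanned PTS on chromosomes
#' other than the guide's own (the candidate space is NGG sites, mirroring
#' the PTS-vs-PTS comparison) and emits each site with at most
#' \code{maxMismatches} spacer mismatches, together with its mismatch list
#' and CFD score. Same-chromosome sites are never emitted.
#'
#' @param guide 20-nt guide protospacer (a bin's representative spacer).
#' @param chrom the guide's own chromosome id.
#' @param sites a [SiteStore-class] or site data.frame covering the genome.
#' @param tables a [ScoreTables-class].
#' @param maxMismatches maximum spacer mismatches, default 4.
#' @return data.frame of hits: chrom, strand, genomic_start, cut_position,
#'   protospacer, pam_2mer, n_mismatches, mismatches (comma-joined
#'   "pos:guide>target"), cfd; ordered by chrom then coordinate.
#' @export
findOffTargets <- function(guide, chrom, sites,
                           tables = defaultScoreTables(),
                           maxMismatches = 4L) {
  df <- if (is(sites, "SiteStore")) siteFrame(sites) else sites
  df <- df[df$chrom != chrom, , drop = FALSE]
  empty <- data.frame(chrom = character(0), strand = character(0),
                      genomic_start = integer(0), cut_position = integer(0),
                      protospacer = character(0), pam_2mer = character(0),
                      n_mismatches = integer(0), mismatches = character(0),
                      cfd = numeric(0), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty)
  proto <- substr(df$full_site, 1L, 20L)
  g <- strsplit(guide, "")[[1]]
  if (length(g) != 20L)
    gbStop("gb_bad_context", "guide must be 20 nt")
  tmat <- matrix(unlist(strsplit(proto, "")), nrow = 20L)
  nmm <- colSums(tmat != g)
  keep <- which(nmm <= maxMismatches)
  if (length(keep) == 0L) return(empty)
  pam2 <- substr(df$full_site[keep], 22L, 23L)
  hits <- data.frame(
    chrom = df$chrom[keep], strand = df$strand[keep],
    genomic_start = df$genomic_start[keep],
    cut_position = df$cut_position[keep],
    protospacer = proto[keep], pam_2mer = pam2,
    n_mismatches = as.integer(nmm[keep]),
    mismatches = vapply(keep, function(i) {
      mm <- which(tmat[, i] != g)
      paste(sprintf("%d:%s>%s", mm, g[mm], tmat[mm, i]), collapse = ",")
    }, character(1)),
    cfd = cfdScore(guide, proto[keep], pam2, tables),
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$chrom, hits$genomic_start, hits$strand == "-"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-chromosome sums of off-target CFD scores (soCFD)
#'
#' For one guide, sums the CFD scores of its off-target hits per
#' chromosome, counting only hits at or above \code{cfdThreshold}.
#' Chromosomes with no qualifying hit map to 0.
#'
#' @param hits off-target hits from [findOffTargets()].
#' @param cfdThreshold minimum CFD counted, default 0.2 (inclusive).
#' @param chromosomes chromosome ids to report (zeros included); defaults
#'   to those present in \code{hits}.
#' @return named numeric vector of per-chromosome sums.
#' @export
soCfdSums <- function(hits, cfdThreshold = 0.2, chromosomes = NULL) {
  if (is.null(chromosomes)) chromosomes <- unique(hits$chrom)
  sums <- setNames(numeric(length(chromosomes)), chromosomes)
  if (nrow(hits)) {
    q <- hits[hits$cfd >= cfdThreshold, , drop = FALSE]
    if (nrow(q)) {
      agg <- tapply(q$cfd, q$chrom, sum)
      sums[names(agg)] <- agg
    }
  }
  sums
}

#' sgRNA Sequence Value (SSV)
#'
#' The ranking metric: SSV = Coverage_i / (1 + sum_{j != i} soCFD_j), where
#' i is the target chromosome and soCFD_j the summed off-target CFD burden
#' on chromosome j. SSV equals coverage when there is no off-target burden
#' and shrinks as burden accumulates; users may opt out of off-target
#' consideration, which forces the denominator to 1.
#'
#' @param coverage coverage fraction of the target chromosome, in [0, 1].
#' @param socfd per-chromosome soCFD sums (named numeric) or their total.
#' @param includeOffTargets when FALSE, return coverage unchanged.
#' @return the SSV, in [0, coverage].
#' @examples
#' ssvScore(0.75, 0.3)   # 0.5769...
#' ssvScore(1.00, 1.6)   # 0.3846...
#' @export
ssvScore <- function(coverage, socfd = 0, includeOffTargets = TRUE) {
  if (any(coverage < 0 | coverage > 1))
    gbStop("gb_bad_interval", "coverage must lie in [0, 1]")
  total <- sum(unlist(socfd))
  if (total < 0) gbStop("gb_bad_interval", "soCFD sums must be >= 0")
  if (!includeOffTargets) return(coverage)
  coverage / (1 + total)
}

#' Rank annotated guides per chromosome
#'
#' Sorts candidates within each chromosome by SSV (descending), breaking
#' ties by higher coverage, then higher average on-target score, then
#' lexicographic 23-mer; the top \code{topN} per chromosome are returned.
#' The ordering is a total order, so the output is invariant under input
#' permutation.
#'
#' @param reports guide report data.frame (columns chrom, sgrna_23mer, ssv,
#'   coverage, avg_on_target, ...).
#' @param topN guides reported per chromosome, default 5.
#' @param chromOrder chromosome output order; defaults to order of first
#'   appearance.
#' @return the ranked, truncated data.frame with a \code{rank} column.
#' @export
rankGuides <- function(reports, topN = 5L, chromOrder = NULL) {
  if (nrow(reports) == 0L) {
    reports$rank <- integer(0)
    return(reports)
  }
  if (is.null(chromOrder)) chromOrder <- unique(reports$chrom)
  o <- order(match(reports$chrom, chromOrder), -reports$ssv,
             -reports$coverage, -reports$avg_on_target,
             reports$sgrna_23mer)
  reports <- reports[o, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(reports)), reports$chrom)[
    unique(reports$chrom)], head, topN), use.names = FALSE)
  reports <- reports[sort(keep), , drop = FALSE]
  reports$rank <- unlist(lapply(split(reports$chrom, reports$chrom)[
    unique(reports$chrom)], seq_along), use.names = FALSE)
  rownames(reports) <- NULL
  reports
}
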