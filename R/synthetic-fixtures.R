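#' Per-basepair mask coverage (independent cross-check)
#'
#' Computes protected coverage by literally marking every protected
#' basepair in a logical mask, one entry per position. Deliberately
#' independent of the interval-union arithmetic in
#' [protectedIntervals()] so the two can cross-validate each other; also
#' used to compute the coverage ground truth of synthetic fixtures.
#'
#' @param cutPositions 0-based cut coordinates.
#' @param chromLength chromosome length in bp.
#' @param flank protection half-window in bp.
#' @return protected fraction in [0, 1].
#' @export
maskCoverage <- function(cutPositions, chromLength, flank = 2e6) {
  mask <- logical(chromLength)
  for (c0 in cutPositions) {
    lo <- max(0, c0 - flank)           # 0-based half-open [lo, hi)
    hi <- min(chromLength, c0 + flank)
    if (hi > lo) mask[(lo + 1):hi] <- TRUE
  }
  mean(mask)
}

#' Generate a synthetic genome with planted guides and ground truth
#'
#' Builds a random-background genome and plants 23-mer guide sites (and
#' optionally mismatched off-target sites and gene intervals) at exact
#' positions, then returns machine-readable ground truth for every planted
#' element. Background windows that accidentally contain a planted guide's
#' 18-bp seed (or its reverse complement) are re-drawn, so seed-level
#' expectations are exact by construction rather than probabilistic; the
#' scrub is bounded and logged. Identical seeds give byte-identical output.
#'
#' Planted positions are 0-based plus-strand starts of the 23-mer window;
#' minus-strand plants write the reverse complement of protospacer+PAM at
#' that window.
#'
#' @param chromLengths named (or auto-named chr1..chrN) integer lengths,
#'   each >= 23.
#' @param gc background GC fraction, default 0.4.
#' @param guides list of planted guides; each a list with fields
#'   \code{chrom}, \code{protospacer} (20 nt), \code{pam} (3 nt, NGG),
#'   \code{positions} (0-based starts), \code{strands} ("+"/"-", recycled).
#' @param offtargets list of planted off-target sites; each a list with
#'   fields \code{guide} (index into \code{guides}), \code{chrom},
#'   \code{position}, \code{strand}, \code{edits} (list of c(pos, base)
#'   protospacer substitutions, positions 1-20 PAM-distal to proximal),
#'   \code{pam} (default the source guide's PAM).
#' @param genes data.frame of planted gene intervals (chrom, start, end,
#'   name), 0-based half-open.
#' @param seed RNG seed.
#' @param alphabet "ACGT" for full background or "AT" for a background that
#'   cannot form any NGG/CCN PAM.
#' @param path optional FASTA output path (written when non-NULL).
#' @param genesPath optional BED output path for planted genes.
#' @return list with elements \code{genome} ([Biostrings::DNAStringSet]),
#'   \code{truth} (planted site/bin/off-target expectations), \code{path},
#'   \code{genesPath}.
#' @export
simulateGenome <- function(chromLengths, gc = 0.4, guides = list(),
                           offtargets = list(), genes = NULL, seed = 1L,
                           alphabet = c("ACGT", "AT"), path = NULL,
                           genesPath = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  if (any(chromLengths < 23L))
    gbStop("gb_fixture_bounds", "chromosomes must be >= 23 bp")
  set.seed(seed)
  letters <- if (alphabet == "ACGT") BASES else c("A", "T")
  probs <- if (alphabet == "ACGT")
    c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2) else c(0.5, 0.5)
  seqs <- lapply(chromLengths, function(L)
    sample(letters, L, replace = TRUE, prob = probs))

  # resolve planted 23-mers and their footprints
  plants <- list()
  for (gi in seq_along(guides)) {
    g <- guides[[gi]]
    strands <- rep_len(if (is.null(g$strands)) "+" else g$strands,
                       length(g$positions))
    for (k in seq_along(g$positions)) {
      plants[[length(plants) + 1L]] <- list(
        kind = "guide", guide = gi, chrom = g$chrom,
        pos = g$positions[[k]], strand = strands[[k]],
        site = paste0(g$protospacer, g$pam))
    }
  }
  for (oi in seq_along(offtargets)) {
    ot <- offtargets[[oi]]
    src <- guides[[ot$guide]]
    proto <- strsplit(src$protospacer, "")[[1]]
    for (e in ot$edits) proto[as.integer(e[[1]])] <- e[[2]]
    pam <- if (is.null(ot$pam)) src$pam else ot$pam
    plants[[length(plants) + 1L]] <- list(
      kind = "offtarget", guide = ot$guide, chrom = ot$chrom,
      pos = ot$position,
      strand = if (is.null(ot$strand)) "+" else ot$strand,
      site = paste0(paste(proto, collapse = ""), pam))
  }

  occupied <- lapply(chromLengths, function(L) integer(0))
  for (p in plants) {
    if (!p$chrom %in% names(chromLengths))
      gbStop("gb_fixture_bounds", "unknown chromosome: %s", p$chrom)
    L <- chromLengths[[p$chrom]]
    if (p$pos < 0L || p$pos + 23L > L)
      gbStop("gb_fixture_bounds", "planted element out of bounds on %s",
             p$chrom)
    span <- (p$pos + 1L):(p$pos + 23L)
    if (length(intersect(span, occupied[[p$chrom]])))
      gbStop("gb_fixture_overlap", "planted elements overlap on %s", p$chrom)
    occupied[[p$chrom]] <- c(occupied[[p$chrom]], span)
    written <- if (p$strand == "+") p$site else revComp(p$site)
    seqs[[p$chrom]][span] <- strsplit(written, "")[[1]]
  }

  # scrub accidental exact-seed collisions with planted guides from the
  # background (planted footprints are protected)
  seedSet <- unique(unlist(lapply(guides, function(g)
    extractSeed(g$protospacer))))
  patterns <- unique(c(seedSet, revComp(seedSet)))
  nScrubbed <- 0L
  if (length(patterns) && alphabet == "ACGT") {
    for (ch in names(seqs)) {
      for (iter in seq_len(25L)) {
        s <- paste(seqs[[ch]], collapse = "")
        hit <- FALSE
        for (pat in patterns) {
          starts <- regexStarts(s, paste0("(?=", pat, ")"))
          for (st in starts) {
            span <- st:(st + nchar(pat) - 1L)
            free <- setdiff(span, occupied[[ch]])
            if (length(free) == 0L) next   # fully inside a planted footprint
            seqs[[ch]][free] <- sample(letters, length(free), replace = TRUE,
                                       prob = probs)
            nScrubbed <- nScrubbed + 1L
            hit <- TRUE
          }
        }
        if (!hit) break
      }
    }
  }
  if (nScrubbed > 0L)
    message(sprintf("fixture scrub: re-drew %d accidental seed window(s)",
                    nScrubbed))

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(chromLengths)

  truth <- fixtureTruth(plants, guides, chromLengths)
  if (!is.null(path))
    Biostrings::writeXStringSet(genome, path, format = "fasta")
  if (!is.null(genes) && !is.null(genesPath)) {
    bed <- data.frame(genes$chrom, genes$start, genes$end, genes$name)
    write.table(bed, genesPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  list(genome = genome, truth = truth, path = path, genesPath = genesPath,
       genes = genes)
}

# expectations implied by the planted elements, in scanner conventions
fixtureTruth <- function(plants, guides, chromLengths) {
  if (length(plants) == 0L) {
    sites <- data.frame(kind = character(0), guide = integer(0),
                        chrom = character(0), strand = character(0),
                        genomic_start = integer(0), cut_position = integer(0),
                        full_site = character(0), stringsAsFactors = FALSE)
  } else {
    sites <- do.call(rbind, lapply(plants, function(p) {
      data.frame(kind = p$kind, guide = p$guide, chrom = p$chrom,
                 strand = p$strand, genomic_start = p$pos,
                 cut_position = cutCoordinate(p$pos, p$strand),
                 full_site = p$site, stringsAsFactors = FALSE)
    }))
  }
  bins <- lapply(seq_along(guides), function(gi) {
    g <- guides[[gi]]
    mine <- sites[sites$guide == gi & sites$kind == "guide", , drop = FALSE]
    list(chrom = g$chrom, seed = extractSeed(g$protospacer),
         protospacer = g$protospacer,
         cut_positions = sort(unique(mine$cut_position)))
  })
  list(sites = sites, bins = bins, chromLengths = chromLengths)
}
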