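#' Scan one chromosome for Cas9 target sites
#'
#' Enumerates every potential target sequence (PTS) -- a 20-nt protospacer
#' immediately followed by a PAM matching \code{pam} (default 5'-NGG-3' for
#' SpCas9) -- on both strands. Any 23-mer containing N is skipped. Sites are
#' returned in non-decreasing plus-strand coordinate order, plus strand
#' before minus at ties. Overlapping sites (e.g. an NGGG run yielding two
#' PAMs) are all reported.
#'
#' Coordinates are 0-based: \code{genomic_start} is the plus-strand start of
#' the protospacer for + sites and of the PAM complement (the CCN triplet)
#' for - sites, so records on both strands sort on a common axis.
#' \code{cut_position} is the plus-strand coordinate of the base immediately
#' 3' of the blunt cut, which SpCas9 places 3 bp 5' of the PAM:
#' \code{start + 17} for + sites and \code{start + 6} for - sites (see
#' [cutCoordinate()]).
#'
#' \code{context_30mer} is the 30-nt scoring context on the protospacer
#' strand (4 nt upstream + 23-mer + 3 nt downstream); it is NA when the site
#' is too close to a chromosome end or the flanks contain N, and such sites
#' are given a neutral on-target score downstream.
#'
#' @param chromSeq chromosome sequence: a [Biostrings::DNAString] or
#'   character scalar (uppercase ACGTN).
#' @param chrom chromosome id to record.
#' @param pam degenerate 3-mer PAM pattern (IUPAC letters), default "NGG".
#' @return data.frame with columns chrom, strand, genomic_start,
#'   cut_position, full_site, context_30mer.
#' @examples
#' scanChromosome("TTTAACCCACGGTATACCGCGGG", "chr1")
#' @export
scanChromosome <- function(chromSeq, chrom, pam = "NGG") {
  pam <- validatePam(pam)
  seq <- toupper(as.character(chromSeq))
  L <- nchar(seq)
  if (L < 23L) {
    message(sprintf("chromosome %s shorter than 23 bp; no sites", chrom))
    return(emptySiteFrame())
  }
  pamChars <- strsplit(pam, "")[[1]]

  # plus strand: PAM occupies [s+20, s+22] (1-based s = protospacer start)
  plusRe <- paste0("(?=", paste(vapply(pamChars, iupacClass, character(1)),
                                collapse = ""), ")")
  pamStarts <- regexStarts(seq, plusRe)
  s <- pamStarts - 20L
  s <- s[s >= 1L & s + 22L <= L]
  plus <- if (length(s)) {
    win <- substring(seq, s, s + 22L)
    keep <- !grepl("[^ACGT]", win)
    s <- s[keep]; win <- win[keep]
    data.frame(chrom = chrom, strand = "+", genomic_start = s - 1L,
               cut_position = s + 16L, full_site = win,
               context_30mer = contextAt(seq, s - 4L, s + 25L, L, minus = FALSE),
               stringsAsFactors = FALSE)
  } else emptySiteFrame()

  # minus strand: plus-strand triplet at [p, p+2] is the reverse complement
  # of the PAM; for NGG that is CCN
  rcChars <- rev(complementBase(pamChars))
  minusRe <- paste0("(?=", paste(vapply(rcChars, iupacClass, character(1)),
                                 collapse = ""), ")")
  p <- regexStarts(seq, minusRe)
  p <- p[p + 22L <= L]
  minus <- if (length(p)) {
    win <- substring(seq, p, p + 22L)
    keep <- !grepl("[^ACGT]", win)
    p <- p[keep]; win <- win[keep]
    data.frame(chrom = chrom, strand = "-", genomic_start = p - 1L,
               cut_position = p + 5L, full_site = revComp(win),
               context_30mer = contextAt(seq, p - 3L, p + 26L, L, minus = TRUE),
               stringsAsFactors = FALSE)
  } else emptySiteFrame()

  sites <- rbind(plus, minus)
  if (nrow(sites) == 0L) return(emptySiteFrame())
  sites <- sites[order(sites$genomic_start, sites$strand == "-"), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

validatePam <- function(pam) {
  pam <- toupper(pam)
  if (nchar(pam) != 3L)
    gbStop("gb_bad_pam", "PAM pattern must be 3 characters, got '%s'", pam)
  chars <- strsplit(pam, "")[[1]]
  if (!all(chars %in% names(IUPAC_SETS)))
    gbStop("gb_bad_pam", "invalid PAM characters in '%s'", pam)
  pam
}

# all (overlapping) 1-based match starts of a lookahead regex
regexStarts <- function(seq, re) {
  m <- gregexpr(re, seq, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# 30-mer context on the protospacer strand, NA when truncated or ambiguous
contextAt <- function(seq, from, to, L, minus) {
  ok <- from >= 1L & to <= L
  ctx <- rep(NA_character_, length(from))
  if (any(ok)) {
    w <- substring(seq, from[ok], to[ok])
    w[grepl("[^ACGT]", w)] <- NA_character_
    if (minus) w <- revComp(w)
    ctx[ok] <- w
  }
  ctx
}

emptySiteFrame <- function() {
  data.frame(chrom = character(0), strand = character(0),
             genomic_start = integer(0), cut_position = integer(0),
             full_site = character(0), context_30mer = character(0),
             stringsAsFactors = FALSE)
}

#' Blunt-cut coordinate of a target site
#'
#' SpCas9 cuts bluntly between protospacer positions 17 and 18 (3 bp 5' of
#' the PAM). The cut coordinate is reported as the 0-based plus-strand
#' position of the base immediately 3' of the cut on the plus strand:
#' \code{start + 17} for a plus-strand site whose protospacer begins at
#' \code{start}, and \code{start + 6} for a minus-strand site whose PAM
#' complement begins at \code{start}. The two cases are mirror-symmetric on
#' a palindromic site.
#'
#' @param genomicStart 0-based site anchor(s), as in [scanChromosome()].
#' @param strand "+" or "-", recycled.
#' @return integer cut coordinate(s).
#' @examples
#' cutCoordinate(100, "+")  # 117
#' cutCoordinate(100, "-")  # 106
#' @export
cutCoordinate <- function(genomicStart, strand) {
  strand <- rep_len(strand, length(genomicStart))
  ifelse(strand == "+", genomicStart + 17L, genomicStart + 6L)
}

#' Scan a whole genome into a SiteStore
#'
#' Runs [scanChromosome()] over every chromosome and collects the sites into
#' a [SiteStore-class], spilling to a temporary file when the total exceeds
#' \code{budget} (see [spillSites()]).
#'
#' @param genome [Biostrings::DNAStringSet] from [readGenome()].
#' @param pam degenerate PAM pattern, default "NGG".
#' @param budget maximum number of sites held in memory.
#' @param tmpdir directory for the spill file.
#' @return a [SiteStore-class].
#' @export
scanGenome <- function(genome, pam = "NGG", budget = Inf,
                       tmpdir = tempdir()) {
  chunks <- lapply(names(genome), function(id)
    scanChromosome(genome[[id]], id, pam = pam))
  spillSites(chunks, budget = budget, tmpdir = tmpdir,
             chroms = names(genome))
}

#' Spill scanned sites to bounded-memory storage
#'
#' Keeps the scanned site stream in memory when it fits in \code{budget}
#' rows; otherwise writes it chunk-by-chunk to a tab-delimited temporary
#' file (documented, versioned header line) so that peak in-memory site
#' count never exceeds the budget. Iterating the resulting store reproduces
#' the input stream exactly once, in order.
#'
#' @param sites a site data.frame or a list of per-chromosome site
#'   data.frames (chunks are written incrementally).
#' @param budget maximum in-memory site count; default unlimited.
#' @param tmpdir directory for the spill file.
#' @param chroms chromosome ids in scan order (defaults to those observed).
#' @return a [SiteStore-class].
#' @export
spillSites <- function(sites, budget = Inf, tmpdir = tempdir(),
                       chroms = NULL) {
  if (is.data.frame(sites)) sites <- list(sites)
  total <- sum(vapply(sites, nrow, integer(1)))
  if (is.null(chroms))
    chroms <- unique(unlist(lapply(sites, function(df) unique(df$chrom))))
  if (total <= budget) {
    frame <- if (length(sites)) do.call(rbind, sites) else emptySiteFrame()
    rownames(frame) <- NULL
    return(new("SiteStore", frame = frame, path = "", n = as.integer(total),
               chroms = as.character(chroms)))
  }
  if (!dir.exists(tmpdir) || file.access(tmpdir, 2L) != 0L)
    gbStop("gb_unwritable", "tmpdir not writable: %s", tmpdir)
  path <- tempfile("sitestore_", tmpdir = tmpdir, fileext = ".tsv")
  con <- file(path, "w")
  writeLines(paste0("# ", SITESTORE_VERSION), con)
  writeLines(paste(SITE_COLUMNS, collapse = "\t"), con)
  close(con)
  for (chunk in sites) {
    if (nrow(chunk) == 0L) next
    # honor the budget even within one oversized chromosome chunk
    starts <- seq(1L, nrow(chunk), by = max(1L, as.integer(min(budget, nrow(chunk)))))
    for (s in starts) {
      e <- min(nrow(chunk), s + max(1L, as.integer(min(budget, nrow(chunk)))) - 1L)
      data.table::fwrite(chunk[s:e, SITE_COLUMNS, drop = FALSE], path,
                         sep = "\t", append = TRUE, col.names = FALSE,
                         na = "NA", quote = FALSE)
    }
  }
  new("SiteStore", frame = NULL, path = path, n = as.integer(total),
      chroms = as.character(chroms))
}
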