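#' Read a genome from a FASTA file
#'
#' Loads a multi-record FASTA (plain or gzip-compressed), one record per
#' chromosome. Record ids are the first whitespace-delimited token of each
#' header. Sequences are normalized to uppercase and every IUPAC ambiguity
#' code other than A/C/G/T is mapped to N; windows containing N are later
#' excluded from PAM scanning, which is the conservative choice.
#'
#' @param path path to the FASTA file.
#' @return a [Biostrings::DNAStringSet], one entry per chromosome, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 description", "acgGGtNN", ">chr2", "GGCC"), fa)
#' g <- readGenome(fa)
#' names(g)                     # "chr1" "chr2"
#' seqWindow(g, "chr1", 0, 6)   # "ACGGGT"
#' @export
readGenome <- function(path) {
  if (!file.exists(path))
    gbStop("gb_missing_file", "genome file not found: %s", path)
  firstLines <- tryCatch(readLines(path, n = 50L), error = function(e) character(0))
  nonBlank <- firstLines[nzchar(trimws(firstLines))]
  if (length(nonBlank) && !startsWith(nonBlank[1L], ">"))
    gbStop("gb_bad_fasta", "not FASTA: first non-blank line is not a header")
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) gbStop("gb_bad_fasta", "FASTA parse failure: %s",
                               conditionMessage(e)))
  if (length(genome) == 0L)
    gbStop("gb_empty_genome", "FASTA file contains no records: %s", path)
  ids <- vapply(strsplit(names(genome), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    gbStop("gb_duplicate_ids", "duplicate record ids: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genome) <- ids
  # map every non-ACGT code (IUPAC ambiguity letters) to N
  Biostrings::replaceAmbiguities(genome, new = "N")
}

#' Extract a sequence window in 0-based half-open coordinates
#'
#' Internal coordinates throughout the scanning pipeline are 0-based
#' half-open; this accessor makes that convention explicit at the sequence
#' boundary.
#'
#' @param genome a [Biostrings::DNAStringSet] from [readGenome()].
#' @param chrom chromosome id.
#' @param start,end window as 0-based half-open \[start, end).
#' @return uppercase character string of length \code{end - start}.
#' @export
seqWindow <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    gbStop("gb_unknown_chrom", "unknown chromosome: %s", chrom)
  L <- length(genome[[chrom]])
  if (start < 0 || end > L || start > end)
    gbStop("gb_bad_interval", "window [%d, %d) outside [0, %d)", start, end, L)
  as.character(Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end))
}

#' Read gene intervals from a BED file
#'
#' Gene locations are accepted as standard BED3+ (0-based half-open on disk).
#' They are used only to annotate reported breakpoints as genic or
#' intergenic; they never affect guide scoring or ranking.
#'
#' @param path path to a BED3+ file.
#' @param genome optional [Biostrings::DNAStringSet]; when given, intervals
#'   on chromosomes absent from the genome are retained but flagged FALSE in
#'   the \code{known_chrom} metadata column.
#' @return a [GenomicRanges::GRanges] (1-based closed, the Bioconductor
#'   convention) with metadata columns \code{name} and \code{known_chrom}.
#' @export
readGeneIntervals <- function(path, genome = NULL) {
  if (!file.exists(path))
    gbStop("gb_missing_file", "gene interval file not found: %s", path)
  if (length(readLines(path, n = 1L)) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character(0)
    S4Vectors::mcols(gr)$known_chrom <- logical(0)
    return(gr)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) gbStop("gb_bad_interval", "BED parse failure: %s",
                               conditionMessage(e)))
  if (any(GenomicRanges::width(gr) < 1L))
    gbStop("gb_bad_interval", "interval with start >= end in %s", path)
  if (is.null(S4Vectors::mcols(gr)$name))
    S4Vectors::mcols(gr)$name <- NA_character_
  S4Vectors::mcols(gr)$known_chrom <-
    if (is.null(genome)) NA else
      as.vector(GenomicRanges::seqnames(gr)) %in% names(genome)
  if (!is.null(genome)) {
    known <- S4Vectors::mcols(gr)$known_chrom
    if (any(known)) {
      widths <- setNames(Biostrings::width(genome), names(genome))
      lens <- widths[as.vector(GenomicRanges::seqnames(gr))[known]]
      if (any(GenomicRanges::end(gr)[known] > lens))
        gbStop("gb_bad_interval", "interval extends past chromosome end")
    }
  }
  gr
}

#' Write ranked guide reports
#'
#' Emits the final report as TSV or JSON. Columns: chromosome, sgrna_23mer,
#' ssv, avg_on_target, off_target_denominator (1 + sum of per-chromosome
#' soCFD), n_cuts, coverage_pct, cut_positions (semicolon-joined, 1-based
#' inclusive), genic_breakpoints (empty when no gene file was given). SSV,
#' on-target and denominator are printed to 3 decimals and coverage as an
#' integer percentage; JSON mirrors the same fields and rounding.
#'
#' @param reports guide report data.frame (from [guideReports()]) or a
#'   [BalancerRun-class].
#' @param path output file path.
#' @param format "tsv" or "json".
#' @return invisibly, the formatted data.frame that was written.
#' @export
writeGuideReports <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is(reports, "BalancerRun")) reports <- guideReports(reports)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    gbStop("gb_unwritable", "cannot write to: %s", path)
  out <- formatGuideReports(reports)
  if (format == "tsv") {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(out)
}

# Rounded, 1-based presentation of the internal report frame.
formatGuideReports <- function(reports) {
  if (nrow(reports) == 0L) {
    return(data.frame(chromosome = character(0), sgrna_23mer = character(0),
                      ssv = numeric(0), avg_on_target = numeric(0),
                      off_target_denominator = numeric(0),
                      n_cuts = integer(0), coverage_pct = integer(0),
                      cut_positions = character(0),
                      genic_breakpoints = integer(0)))
  }
  data.frame(
    chromosome = reports$chrom,
    sgrna_23mer = reports$sgrna_23mer,
    ssv = round(reports$ssv, 3L),
    avg_on_target = round(reports$avg_on_target, 3L),
    off_target_denominator = round(reports$off_target_denominator, 3L),
    n_cuts = reports$n_cuts,
    coverage_pct = as.integer(round(100 * reports$coverage)),
    cut_positions = vapply(reports$cut_positions, function(p)
      paste(p + 1L, collapse = ";"), character(1)),
    genic_breakpoints = if ("genic_breakpoints" %in% names(reports))
      reports$genic_breakpoints else NA_integer_,
    stringsAsFactors = FALSE)
}
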