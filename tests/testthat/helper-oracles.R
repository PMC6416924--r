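# Independent oracles and small fixture builders shared across tests.
# Deliberately written without reusing the package's scanning / interval /
# comparison code paths.

# string reverse complement, self-contained
rc_str <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive-substring scanner oracle: enumerates every 23-bp window of the
# sequence (plus strand) and of its reverse complement (mapped back to plus
# coordinates), keeping windows that end in GG at PAM positions 2-3 and
# contain no N. Returns the same column layout as scanChromosome().
oracle_scan <- function(seq, chrom = "chr") {
  seq <- toupper(seq)
  L <- nchar(seq)
  plus_pass <- function(s) {
    n <- nchar(s)
    if (n < 23L) return(NULL)
    starts <- 1:(n - 22L)
    w <- substring(s, starts, starts + 22L)
    keep <- substr(w, 22L, 23L) == "GG" & !grepl("[^ACGT]", w)
    list(start1 = starts[keep], site = w[keep])
  }
  fwd <- plus_pass(seq)
  rev_ <- plus_pass(rc_str(seq))
  rows <- list()
  if (!is.null(fwd) && length(fwd$start1)) {
    rows[[1]] <- data.frame(
      chrom = chrom, strand = "+", genomic_start = fwd$start1 - 1L,
      cut_position = fwd$start1 + 16L, full_site = fwd$site,
      stringsAsFactors = FALSE)
  }
  if (!is.null(rev_) && length(rev_$start1)) {
    # window [s', s'+22] of rc(seq) occupies plus window starting L - s' - 21
    p <- L - rev_$start1 - 21L
    rows[[2]] <- data.frame(
      chrom = chrom, strand = "-", genomic_start = p - 1L,
      cut_position = p + 5L, full_site = rev_$site,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      genomic_start = integer(0), cut_position = integer(0),
                      full_site = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$genomic_start, out$strand == "-"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-basepair boolean-mask coverage oracle
mask_cov <- function(cuts0, L, flank) {
  mask <- logical(L)
  for (c0 in cuts0) {
    lo <- max(0L, c0 - flank)
    hi <- min(L, c0 + flank)
    if (hi > lo) mask[(lo + 1):hi] <- TRUE
  }
  mean(mask)
}

# quadratic brute-force off-target oracle: re-scans with oracle_scan and
# compares the guide to every other-chromosome protospacer base by base,
# recomputing each CFD as an explicit penalty product from the table slots
oracle_offtargets <- function(guide, guide_chrom, genome_chars,
                              tables, max_mm) {
  g <- strsplit(guide, "")[[1]]
  hits <- list()
  for (ch in names(genome_chars)) {
    if (ch == guide_chrom) next
    sites <- oracle_scan(genome_chars[[ch]], ch)
    for (i in seq_len(nrow(sites))) {
      t <- strsplit(substr(sites$full_site[i], 1L, 20L), "")[[1]]
      mm <- which(t != g)
      if (length(mm) > max_mm) next
      p <- 1
      for (j in mm) p <- p * tables@cfd[[paste(j, g[j], t[j], sep = "|")]]
      p <- p * tables@pam[[substr(sites$full_site[i], 22L, 23L)]]
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = ch, strand = sites$strand[i],
        genomic_start = sites$genomic_start[i],
        cut_position = sites$cut_position[i],
        protospacer = substr(sites$full_site[i], 1L, 20L),
        n_mismatches = length(mm),
        mismatches = paste(sprintf("%d:%s>%s", mm, g[mm], t[mm]),
                           collapse = ","),
        cfd = p, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      genomic_start = integer(0), cut_position = integer(0),
                      protospacer = character(0), n_mismatches = integer(0),
                      mismatches = character(0), cfd = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$genomic_start, out$strand == "-"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random sequence with optional embedded N runs and a palindromic insert
random_test_seq <- function(len, gc = 0.5, with_n = FALSE,
                            with_palindrome = FALSE) {
  s <- random_dna(len, gc)
  if (with_n) {
    at <- sample(seq_len(len - 30L), 2L)
    for (a in at) substr(s, a, a + sample(3:12, 1L)) <-
        strrep("N", 13L)
  }
  if (with_palindrome) {
    half <- random_dna(15L)
    pal <- paste0(half, rc_str(half))
    at <- sample(seq_len(len - nchar(pal)), 1L)
    substr(s, at, at + nchar(pal) - 1L) <- pal
  }
  s
}

# 20-mer with no G (and no C complement trouble) so planted sites stay the
# only NGG matches in AT-rich backgrounds when needed
PROTO_A <- "TTTAACCCACGGTATACCGC"   # A. thaliana chr2 report spacer
PROTO_B <- "ATGCATTCAGGATCCGATAC"
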