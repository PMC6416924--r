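make_ctx <- function(n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) random_dna(30), character(1))
}

test_that("the logistic position-weight on-target model behaves", {
  zero <- makeScoreTables("uniform")     # all-zero weights, intercept 0
  ctx <- make_ctx(5)
  expect_identical(onTargetScore(ctx, zero), rep(0.5, 5))

  # a +10 weight on one (position, base): contexts with that base dominate
  w <- data.frame(feature = c("(Intercept)", "p1_G"), coefficient = c(0, 10))
  tb <- scoreTables(data.frame(position = 1L, guide_base = "A",
                               target_base = "C", penalty = 0.5),
                    data.frame(pam_2mer = "GG", penalty = 1), w)
  withG <- paste0("G", substr(ctx, 2, 30))
  withoutG <- paste0("A", substr(ctx, 2, 30))
  expect_true(all(onTargetScore(withG, tb) > onTargetScore(withoutG, tb)))

  # unscorable contexts get the neutral score
  expect_identical(onTargetScore(NA_character_, zero, neutral = 0.25), 0.25)
  expect_error(onTargetScore("ACGT", zero), class = "gb_bad_context")
})

test_that("on-target scores match a straight-line recomputation", {
  tb <- makeScoreTables("random", seed = 99L)
  ctx <- make_ctx(100, seed = 7)
  got <- onTargetScore(ctx, tb)
  w <- tb@weights
  want <- vapply(ctx, function(cx) {
    chars <- strsplit(cx, "")[[1]]
    lin <- w[["(Intercept)"]]
    for (i in 1:30) {
      key <- paste0("p", i, "_", chars[i])
      if (key %in% names(w)) lin <- lin + w[[key]]
    }
    gc <- sum(chars[5:24] %in% c("G", "C"))
    1 / (1 + exp(-(lin + w[["gc_count"]] * gc)))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("bins are filtered by mean on-target score with inclusive boundary", {
  tb <- makeScoreTables("uniform")       # every context scores exactly 0.5
  bins <- data.frame(chrom = "c1", seed = c("s1", "s2"),
                     n_sites = c(2L, 1L), representative = "x",
                     cut_positions = I(list(1L, 2L)),
                     contexts = I(list(make_ctx(2), make_ctx(1))))
  out <- suppressMessages(filterBinsOnTarget(bins, tb, minAvg = 0.5))
  expect_identical(nrow(out), 2L)        # score == threshold survives
  expect_identical(out$avg_on_target, c(0.5, 0.5))
  out0 <- suppressMessages(filterBinsOnTarget(bins, tb, minAvg = 0))
  expect_identical(nrow(out0), 2L)
  gone <- suppressMessages(filterBinsOnTarget(bins, tb, minAvg = 0.51))
  expect_identical(nrow(gone), 0L)
  expect_identical(attr(gone, "rejected_on_target"), 2L)

  # mixed member scores average arithmetically: {~0.2, ~0.9}-style bin
  w <- data.frame(feature = c("(Intercept)", "p1_G"),
                  coefficient = c(qlogis(0.2), qlogis(0.9) - qlogis(0.2)))
  tb2 <- scoreTables(data.frame(position = 1L, guide_base = "A",
                                target_base = "C", penalty = 1),
                     data.frame(pam_2mer = "GG", penalty = 1), w)
  ctx <- c(paste0("G", random_dna(29)), paste0("A", random_dna(29)))
  bin <- data.frame(chrom = "c1", seed = "s", n_sites = 2L,
                    representative = "x", cut_positions = I(list(1L)),
                    contexts = I(list(ctx)))
  avg <- mean(onTargetScore(ctx, tb2))
  expect_equal(avg, 0.55, tolerance = 1e-12)
  expect_identical(nrow(suppressMessages(
    filterBinsOnTarget(bin, tb2, minAvg = 0.5))), 1L)
  expect_identical(nrow(suppressMessages(
    filterBinsOnTarget(bin, tb2, minAvg = 0.6))), 0L)
})

test_that("CFD is a penalty product over mismatches times the PAM penalty", {
  tb <- makeScoreTables("random", seed = 5L)
  g <- "ACGTACGTACGTACGTACGT"
  expect_identical(cfdScore(g, g, "GG", tb), 1)

  # single mismatch: exactly the table entry
  for (pos in c(1L, 7L, 20L)) {
    t <- g
    gbase <- substr(g, pos, pos)
    tbase <- setdiff(c("A", "C", "G", "T"), gbase)[2]
    substr(t, pos, pos) <- tbase
    expect_equal(cfdScore(g, t, "GG", tb),
                 unname(tb@cfd[paste(pos, gbase, tbase, sep = "|")]),
                 tolerance = 1e-15)
  }

  # exhaustive 2-mismatch patterns factorize into 1-mismatch products
  singles <- function(pos, tbase) {
    t <- g; substr(t, pos, pos) <- tbase
    cfdScore(g, t, "GG", tb)
  }
  for (p1 in 1:19) for (p2 in (p1 + 1):20) {
    t1 <- setdiff(c("A", "C", "G", "T"), substr(g, p1, p1))[1]
    t2 <- setdiff(c("A", "C", "G", "T"), substr(g, p2, p2))[3]
    t <- g
    substr(t, p1, p1) <- t1
    substr(t, p2, p2) <- t2
    expect_equal(cfdScore(g, t, "GG", tb), singles(p1, t1) * singles(p2, t2),
                 tolerance = 1e-12)
  }

  # non-GG PAM multiplies in its penalty; missing entries are named errors
  expect_equal(cfdScore(g, g, "AG", tb), unname(tb@pam[["AG"]]),
               tolerance = 1e-15)
  tiny <- scoreTables(data.frame(position = 1L, guide_base = "A",
                                 target_base = "C", penalty = 0.5),
                      data.frame(pam_2mer = "GG", penalty = 1),
                      data.frame(feature = "(Intercept)", coefficient = 0))
  t <- g; substr(t, 5, 5) <- "T"
  expect_error(cfdScore(g, t, "GG", tiny), class = "gb_missing_cfd_entry")
  expect_error(cfdScore(g, g, "AT", tiny), class = "gb_missing_cfd_entry")

  # perfect match with GG PAM is 1 for any guide
  set.seed(2)
  for (i in 1:10) {
    p <- random_dna(20)
    expect_identical(cfdScore(p, p, "GG", tb), 1)
  }
})

test_that("off-target search equals the quadratic brute-force oracle", {
  tb <- makeScoreTables("random", seed = 13L)
  guide <- list(chrom = "chr1", protospacer = PROTO_A, pam = "TGG",
                positions = c(5000L, 15000L))
  planted_ot <- list(guide = 1L, chrom = "chr2", position = 8000L,
                     edits = list(c(4L, "G"), c(11L, "A")))
  fx <- simulateGenome(c(chr1 = 30000L, chr2 = 30000L, chr3 = 20000L),
                       guides = list(guide), offtargets = list(planted_ot),
                       seed = 99L)
  store <- scanGenome(fx$genome)

  # single-chromosome genome: nothing to hit
  solo <- scanChromosome(fx$genome[["chr1"]], "chr1")
  expect_identical(nrow(findOffTargets(PROTO_A, "chr1", solo, tb)), 0L)

  for (mm in 1:4) {
    got <- findOffTargets(PROTO_A, "chr1", store, tb, maxMismatches = mm)
    chars <- lapply(as.list(as.character(fx$genome)),
                    function(s) s)
    want <- oracle_offtargets(PROTO_A, "chr1", chars, tb, mm)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$cut_position, want$cut_position)
      expect_identical(got$mismatches, want$mismatches)
      expect_equal(got$cfd, want$cfd, tolerance = 1e-12)
    }
  }

  # the planted 2-mismatch site is recovered with its exact mismatch list
  got2 <- findOffTargets(PROTO_A, "chr1", store, tb, maxMismatches = 2)
  hit <- got2[got2$chrom == "chr2" & got2$genomic_start == 8000L, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$n_mismatches, 2L)
  expect_identical(hit$mismatches, "4:A>G,11:G>A")
  expect_identical(nrow(got2[got2$chrom == "chr1", ]), 0L)
})

test_that("soCFD sums per chromosome above the threshold, zeros included", {
  hits <- data.frame(chrom = c("c2", "c2", "c3"), cfd = c(0.5, 0.3, 0.1))
  expect_equal(soCfdSums(hits, 0.2, c("c2", "c3", "c4")),
               c(c2 = 0.8, c3 = 0, c4 = 0), tolerance = 1e-12)
  expect_identical(soCfdSums(hits[0, ], 0.2, "c2"), c(c2 = 0))
  expect_identical(soCfdSums(hits, 1.0, c("c2", "c3")), c(c2 = 0, c3 = 0))
  # threshold is >=-inclusive
  expect_identical(soCfdSums(data.frame(chrom = "c2", cfd = 0.2), 0.2, "c2"),
                   c(c2 = 0.2))
})

test_that("SSV is coverage over one plus the off-target burden", {
  expect_lt(abs(ssvScore(0.75, 0.3) - 0.577), 2e-3)
  expect_lt(abs(ssvScore(1.00, 1.6) - 0.385), 2e-3)
  expect_identical(ssvScore(0.9, 0), 0.9)
  expect_identical(ssvScore(0.4, c(a = 2, b = 1), includeOffTargets = FALSE),
                   0.4)
  s <- ssvScore(0.8, c(a = 0.5, b = 0.25))
  expect_equal(s, 0.8 / 1.75, tolerance = 1e-12)
  expect_true(s <= 0.8)
  expect_error(ssvScore(1.2, 0), class = "gb_bad_interval")
})

test_that("guide ranking is a deterministic total order", {
  mk <- function(chrom, seq, ssv, cov, ot) data.frame(
    chrom = chrom, sgrna_23mer = seq, ssv = ssv, coverage = cov,
    avg_on_target = ot, stringsAsFactors = FALSE)
  reports <- rbind(
    mk("c1", "AAAAAAAAAAAAAAAAAAAAAGG", 0.50, 0.8, 0.6),
    mk("c1", "CCCCCCCCCCCCCCCCCCCCAGG", 0.80, 0.8, 0.6),  # clean guide
    mk("c1", "GGGGGGGGGGGGGGGGGGGGTGG", 0.50, 0.9, 0.6),  # coverage tiebreak
    mk("c2", "TTTTTTTTTTTTTTTTTTTTCGG", 0.70, 0.7, 0.9))
  ranked <- rankGuides(reports, topN = 2L, chromOrder = c("c1", "c2"))
  expect_identical(ranked$sgrna_23mer[1:2],
                   c("CCCCCCCCCCCCCCCCCCCCAGG", "GGGGGGGGGGGGGGGGGGGGTGG"))
  expect_identical(ranked$rank, c(1L, 2L, 1L))

  # single candidate is rank 1; permutation invariance
  one <- rankGuides(reports[4, ], topN = 5L)
  expect_identical(one$rank, 1L)
  set.seed(1)
  for (i in 1:5) {
    perm <- rankGuides(reports[sample(nrow(reports)), ], topN = 2L,
                       chromOrder = c("c1", "c2"))
    expect_identical(perm, ranked)
  }
})
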