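test_that("seed extraction takes the PAM-proximal suffix", {
  expect_identical(extractSeed("TTTAACCCACGGTATACCGC"), "TAACCCACGGTATACCGC")
  expect_identical(extractSeed("TTTAACCCACGGTATACCGC", 20L),
                   "TTTAACCCACGGTATACCGC")
  expect_error(extractSeed("TTTAACCCACGGTATACCGC", 21L),
               class = "gb_bad_seed_length")
  set.seed(3)
  for (i in 1:20) {
    p <- random_dna(20)
    expect_true(endsWith(extractSeed(p, 20L), extractSeed(p, 18L)))
  }
})

test_that("bins merge cut locations of seed-sharing sites", {
  # two + sites, identical 18-nt seed, different PAM-distal dinucleotides
  proto1 <- paste0("AA", extractSeed(PROTO_A))
  proto2 <- paste0("GT", extractSeed(PROTO_A))
  sites <- rbind(
    scanChromosome(paste0("TTTT", proto1, "TGG", "TTTT"), "c1"),
    scanChromosome(paste0("TTTT", proto2, "AGG", "TTTT"), "c1"))
  sites$genomic_start <- c(4L, 304L)
  sites$cut_position <- c(21L, 321L)
  bins <- buildSeedBins(sites)
  expect_identical(nrow(bins), 1L)
  expect_identical(bins$cut_positions[[1]], c(21L, 321L))
  expect_identical(bins$n_sites, 2L)
  # representative: both 23-mers unique, lexicographic tie-break
  expect_identical(bins$representative,
                   sort(c(paste0(proto1, "TGG"), paste0(proto2, "AGG")))[1])

  # all-distinct seeds: one bin per site
  set.seed(8)
  rnd <- scanChromosome(random_dna(3000), "c2")
  b2 <- buildSeedBins(rnd)
  expect_identical(sum(b2$n_sites), nrow(rnd))   # conservation
  expect_lte(nrow(b2), nrow(rnd))
})

test_that("a guide planted at five positions (3 exact + 2 distal variants) forms one bin", {
  variants <- list(
    list(chrom = "chr1", protospacer = PROTO_A, pam = "TGG",
         positions = c(200L, 1400L, 2600L)),
    list(chrom = "chr1", protospacer = paste0("GA", substr(PROTO_A, 3, 20)),
         pam = "CGG", positions = 3600L),
    list(chrom = "chr1", protospacer = paste0("CT", substr(PROTO_A, 3, 20)),
         pam = "AGG", positions = 4400L))
  fx <- simulateGenome(c(chr1 = 5000L), guides = variants, seed = 21L)
  sites <- scanChromosome(fx$genome[["chr1"]], "chr1")
  bins <- buildSeedBins(sites)
  hit <- bins[bins$seed == extractSeed(PROTO_A), ]
  expect_identical(nrow(hit), 1L)
  expect_identical(length(hit$cut_positions[[1]]), 5L)
  expect_identical(hit$cut_positions[[1]],
                   cutCoordinate(c(200L, 1400L, 2600L, 3600L, 4400L), "+"))
  # majority representative: the thrice-planted exact 23-mer
  expect_identical(hit$representative, paste0(PROTO_A, "TGG"))
})

test_that("rebinning a bin's members reproduces the bin", {
  set.seed(12)
  sites <- scanChromosome(random_dna(4000), "cX")
  bins <- buildSeedBins(sites)
  i <- which.max(bins$n_sites)
  members <- sites[extractSeed(substr(sites$full_site, 1, 20)) ==
                     bins$seed[i], ]
  again <- buildSeedBins(members)
  expect_identical(again$seed, bins$seed[i])
  expect_identical(again$cut_positions[[1]], bins$cut_positions[[i]])
  expect_identical(again$representative, bins$representative[i])
})

test_that("the seed index conserves occurrences and finds planted seeds", {
  expect_identical(buildSeedIndex(list2DF(list()))@nsites, 0L)

  fx <- simulateGenome(c(chr1 = 8000L, chr2 = 6000L),
                       guides = list(list(chrom = "chr1",
                                          protospacer = PROTO_A,
                                          pam = "TGG",
                                          positions = c(1000L, 5000L))),
                       seed = 31L)
  store <- scanGenome(fx$genome)
  idx <- buildSeedIndex(store)
  expect_identical(idx@nsites, siteCount(store))
  occ <- lookupSeed(idx, extractSeed(PROTO_A))
  expect_identical(nrow(occ), 2L)                 # scrub removed imposters
  expect_identical(sort(occ$cut_position), cutCoordinate(c(1000L, 5000L), "+"))
})

test_that("cross-chromosome seed recurrence rejects bins, exact match only", {
  guide <- list(chrom = "chr1", protospacer = PROTO_A, pam = "TGG",
                positions = c(1000L, 3000L))

  # single chromosome: rejection is vacuous
  fx1 <- simulateGenome(c(chr1 = 5000L), guides = list(guide), seed = 41L)
  st1 <- scanGenome(fx1$genome)
  b1 <- buildSeedBins(st1)
  s1 <- suppressMessages(rejectCrossChromosomeBins(b1, buildSeedIndex(st1)))
  expect_identical(nrow(s1), nrow(b1))

  # exact seed copy on chr2: bin rejected
  twin <- list(chrom = "chr2", protospacer = PROTO_A, pam = "CGG",
               positions = 2000L)
  fx2 <- simulateGenome(c(chr1 = 5000L, chr2 = 5000L),
                        guides = list(guide, twin), seed = 41L)
  st2 <- scanGenome(fx2$genome)
  s2 <- suppressMessages(
    rejectCrossChromosomeBins(buildSeedBins(st2), buildSeedIndex(st2)))
  expect_false(extractSeed(PROTO_A) %in% s2$seed)

  # one PAM-proximal mismatch on chr2: near matches do NOT reject
  near <- list(chrom = "chr2",
               protospacer = paste0(substr(PROTO_A, 1, 19), "T"),
               pam = "CGG", positions = 2000L)
  fx3 <- simulateGenome(c(chr1 = 5000L, chr2 = 5000L),
                        guides = list(guide, near), seed = 41L)
  st3 <- scanGenome(fx3$genome)
  s3 <- suppressMessages(
    rejectCrossChromosomeBins(buildSeedBins(st3), buildSeedIndex(st3)))
  expect_true(extractSeed(PROTO_A) %in% s3$seed)

  # monotonicity: adding a chromosome never adds survivors on chr1
  surv_chr1_before <- sum(s1$chrom == "chr1")
  expect_lte(sum(s2$chrom == "chr1"), surv_chr1_before)
})
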