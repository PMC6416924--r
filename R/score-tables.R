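BASES <- c("A", "C", "G", "T")
PAM_2MERS <- as.vector(outer(BASES, BASES, paste0))

cfdKey <- function(pos, guide, target) paste(pos, guide, target, sep = "|")

mismatchGrid <- function() {
  g <- expand.grid(pos = 1:20, guide = BASES, target = BASES,
                   stringsAsFactors = FALSE)
  g[g$guide != g$target, ]
}

#' Assemble a ScoreTables object
#'
#' @param cfd data.frame with columns position (1-20, PAM-distal to
#'   PAM-proximal), guide_base, target_base, penalty; mismatch entries only
#'   (matched bases always score 1).
#' @param pam data.frame with columns pam_2mer (bases 2-3 of the PAM) and
#'   penalty; GG must score 1.
#' @param weights data.frame with columns feature, coefficient; features are
#'   "(Intercept)", "gc_count" and positional terms "p<i>_<base>" over the
#'   30-mer context.
#' @param origin descriptive tag.
#' @return a [ScoreTables-class].
#' @export
scoreTables <- function(cfd, pam, weights, origin = "user") {
  cfdVec <- setNames(as.numeric(cfd$penalty),
                     cfdKey(cfd$position, cfd$guide_base, cfd$target_base))
  pamVec <- setNames(as.numeric(pam$penalty), pam$pam_2mer)
  wVec <- setNames(as.numeric(weights$coefficient), weights$feature)
  new("ScoreTables", cfd = cfdVec, pam = pamVec, weights = wVec,
      origin = origin)
}

#' Default scoring tables (synthetic heuristic)
#'
#' The default CFD penalty matrix is a deterministic synthetic heuristic,
#' not the experimentally derived published matrix: penalties decay toward
#' the PAM (positions counted 1-20 PAM-distal to PAM-proximal), and
#' transition-like substitutions are tolerated more than transversions.
#' The PAM table scores GG = 1, single-G 2-mers moderately, and the rest
#' near zero. On-target weights define a mildly varying logistic
#' position-weight model centered above 0.5. All three tables are
#' replaceable assets: see [readScoreTables()] for the on-disk format.
#'
#' @return a [ScoreTables-class] with origin "synthetic-default".
#' @export
defaultScoreTables <- function() {
  mm <- mismatchGrid()
  tol <- 0.08 + 0.90 * exp(-0.18 * (mm$pos - 1))
  transition <- (mm$guide == "A" & mm$target == "G") |
    (mm$guide == "G" & mm$target == "A") |
    (mm$guide == "C" & mm$target == "T") |
    (mm$guide == "T" & mm$target == "C")
  pairFactor <- ifelse(transition, 1.0, 0.55)
  cfd <- data.frame(position = mm$pos, guide_base = mm$guide,
                    target_base = mm$target,
                    penalty = pmin(1, round(tol * pairFactor, 4L)))
  pam <- data.frame(
    pam_2mer = PAM_2MERS,
    penalty = ifelse(PAM_2MERS == "GG", 1,
                     ifelse(substr(PAM_2MERS, 2L, 2L) == "G", 0.25,
                            ifelse(substr(PAM_2MERS, 1L, 1L) == "G", 0.10,
                                   0.02))))
  posWeights <- expand.grid(pos = 1:30, base = BASES,
                            stringsAsFactors = FALSE)
  coefs <- round(0.01 * sin(posWeights$pos * match(posWeights$base, BASES)),
                 5L)
  weights <- rbind(
    data.frame(feature = "(Intercept)", coefficient = 0.4),
    data.frame(feature = "gc_count", coefficient = 0),
    data.frame(feature = paste0("p", posWeights$pos, "_", posWeights$base),
               coefficient = coefs))
  scoreTables(cfd, pam, weights, origin = "synthetic-default")
}

#' Synthetic score tables for testing
#'
#' \code{uniform} mode assigns one constant penalty to every spacer mismatch
#' and every non-GG PAM so CFD expectations have a closed form (e.g. with
#' penalty 0.5 any 2-mismatch hit scores 0.25); on-target weights are all
#' zero, so every context scores logistic(0) = 0.5. \code{random} mode
#' fills penalties in [0, 1] and weights reproducibly from \code{seed}.
#' Matched bases and the GG PAM always score 1.
#'
#' @param mode "uniform" or "random".
#' @param penalty constant mismatch penalty for uniform mode, default 0.5.
#' @param seed RNG seed for random mode.
#' @return a [ScoreTables-class].
#' @export
makeScoreTables <- function(mode = c("uniform", "random"), penalty = 0.5,
                            seed = 1L) {
  mode <- match.arg(mode)
  mm <- mismatchGrid()
  if (mode == "uniform") {
    pcfd <- rep(penalty, nrow(mm))
    ppam <- ifelse(PAM_2MERS == "GG", 1, penalty)
    w <- data.frame(feature = c("(Intercept)", "gc_count"),
                    coefficient = c(0, 0))
  } else {
    rng <- local({ set.seed(seed); list(cfd = runif(nrow(mm)),
                                        pam = runif(length(PAM_2MERS)),
                                        w = rnorm(31L, sd = 0.3)) })
    pcfd <- round(rng$cfd, 6L)
    ppam <- ifelse(PAM_2MERS == "GG", 1, round(rng$pam, 6L))
    w <- data.frame(
      feature = c("(Intercept)", "gc_count",
                  paste0("p", 1:29, "_", rep(BASES, length.out = 29L))),
      coefficient = round(rng$w, 6L))
  }
  scoreTables(
    data.frame(position = mm$pos, guide_base = mm$guide,
               target_base = mm$target, penalty = pcfd),
    data.frame(pam_2mer = PAM_2MERS, penalty = ppam),
    w, origin = paste0("synthetic-", mode))
}

#' Read scoring tables from delimited assets
#'
#' Tab-delimited with header rows: the CFD file has columns position,
#' guide_base, target_base, penalty; the PAM file pam_2mer, penalty; the
#' weights file feature, coefficient.
#'
#' @param cfdPath,pamPath,weightsPath asset file paths.
#' @param origin descriptive tag.
#' @return a [ScoreTables-class].
#' @export
readScoreTables <- function(cfdPath, pamPath, weightsPath,
                            origin = "asset") {
  for (p in c(cfdPath, pamPath, weightsPath))
    if (!file.exists(p))
      gbStop("gb_missing_file", "score table asset not found: %s", p)
  scoreTables(read.delim(cfdPath, stringsAsFactors = FALSE),
              read.delim(pamPath, stringsAsFactors = FALSE),
              read.delim(weightsPath, stringsAsFactors = FALSE),
              origin = origin)
}

#' Write scoring tables in the asset format
#'
#' @param tables a [ScoreTables-class].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the three file paths written.
#' @export
writeScoreTables <- function(tables, dir, prefix = "score") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- strsplit(names(tables@cfd), "|", fixed = TRUE)
  cfd <- data.frame(
    position = as.integer(vapply(parts, `[`, character(1), 1L)),
    guide_base = vapply(parts, `[`, character(1), 2L),
    target_base = vapply(parts, `[`, character(1), 3L),
    penalty = unname(tables@cfd))
  pam <- data.frame(pam_2mer = names(tables@pam),
                    penalty = unname(tables@pam))
  w <- data.frame(feature = names(tables@weights),
                  coefficient = unname(tables@weights))
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("cfd_penalties", "pam_penalties",
                                   "on_target_weights"), ".tsv"))
  write.table(cfd, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pam, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(w, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
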